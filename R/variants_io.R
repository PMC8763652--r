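## VCF serialization of variant calls. Internally calls are 0-based; the
## VCF body is 1-based, converted only here.

#' Construct a table of variant calls
#'
#' @param chrom,pos Contig and 0-based position.
#' @param ref,alt Reference and alternate base (single characters, unequal).
#' @param alt_count,depth Supporting and total consensus-read counts.
#' @return data.frame of class `variant_calls` with an `af` column in
#'   percent (`af = 100 * alt_count / depth`).
#' @export
variant_calls <- function(chrom, pos, ref, alt, alt_count, depth) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(ref), alt = toupper(alt),
                   alt_count = as.integer(alt_count), depth = as.integer(depth),
                   stringsAsFactors = FALSE)
  bad <- which(df$ref == df$alt)
  assert_that(length(bad) == 0L,
              "call %d: alt equals ref (%s) — not an SNV", bad[1], df$ref[bad[1]])
  assert_that(all(df$ref %in% c("A", "C", "G", "T")) &&
              all(df$alt %in% c("A", "C", "G", "T")),
              "ref/alt must be single bases A/C/G/T")
  assert_that(all(df$depth >= df$alt_count) && all(df$alt_count >= 0),
              "need 0 <= alt_count <= depth")
  df$af <- 100 * df$alt_count / df$depth
  class(df) <- unique(c("variant_calls", class(df)))
  df
}

#' Write variant calls to a VCF file
#'
#' Emits a minimal VCFv4.2 with `DP` (total depth), `AC` (alternate count)
#' and `AF` (alternate fraction) INFO fields; positions are converted to
#' the VCF's 1-based convention. `read_variants(write_variants(x))`
#' reproduces positions, alleles and counts exactly.
#'
#' @param calls A `variant_calls` data.frame (see [variant_calls()]).
#' @param path Output path.
#' @param reference Optional named sequence vector; when given, each call's
#'   ref base is checked against it.
#' @return `path`, invisibly.
#' @export
write_variants <- function(calls, path, reference = NULL) {
  req <- c("chrom", "pos", "ref", "alt", "alt_count", "depth")
  assert_that(all(req %in% names(calls)), "calls must have columns: %s",
              paste(req, collapse = ", "))
  calls <- variant_calls(calls$chrom, calls$pos, calls$ref, calls$alt,
                         calls$alt_count, calls$depth)
  if (!is.null(reference)) {
    obs <- ref_base_at(reference, calls$chrom, calls$pos)
    bad <- which(obs != calls$ref)
    assert_that(length(bad) == 0L,
                "call at %s:%d: ref '%s' disagrees with reference '%s'",
                calls$chrom[bad[1]], calls$pos[bad[1]], calls$ref[bad[1]],
                obs[bad[1]])
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mrdtrace",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total consensus depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternate consensus read count\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AC=%d;AF=%.6g",
                  calls$chrom, calls$pos + 1L, calls$ref, calls$alt,
                  calls$depth, calls$alt_count, calls$alt_count / calls$depth)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read variant calls from a VCF file
#'
#' Parses with `vcfR`; AF is recomputed from the exact `AC`/`DP` counts so
#' the round trip is lossless.
#'
#' @param path Path to a VCF file.
#' @return A `variant_calls` data.frame (0-based positions).
#' @export
read_variants <- function(path) {
  assert_that(file.exists(path), "VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(variant_calls(character(), integer(), character(), character(),
                         integer(), integer()))
  }
  dp <- as.integer(vcfR::extract.info(v, "DP"))
  ac <- as.integer(vcfR::extract.info(v, "AC"))
  assert_that(!anyNA(dp) && !anyNA(ac), "VCF records missing DP/AC INFO fields")
  variant_calls(fix$CHROM, as.integer(fix$POS) - 1L, fix$REF, fix$ALT, ac, dp)
}
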