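## Reference sequence handling (plain named character vector of upper-case
## DNA, one entry per contig).

#' Load a reference FASTA
#'
#' @param path FASTA file with one entry per panel contig.
#' @param panel Optional [panel_def()]; when given, every panel chrom must
#'   be present and long enough to contain its regions.
#' @return Named character vector of upper-cased sequences.
#' @export
load_reference <- function(path, panel = NULL) {
  assert_that(file.exists(path), "FASTA file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  ref <- toupper(as.character(ss))
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (!is.null(panel)) validate_reference(ref, panel)
  ref
}

#' Write a reference FASTA
#'
#' @param reference Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  assert_that(is.character(reference) && !is.null(names(reference)),
              "reference must be a named character vector")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Check that a reference covers a panel
#'
#' @param reference Named character vector.
#' @param panel A [panel_def()].
#' @return `TRUE` invisibly; errors listing missing/short contigs otherwise.
#' @export
validate_reference <- function(reference, panel) {
  r <- panel$regions
  missing <- setdiff(unique(r$chrom), names(reference))
  assert_that(length(missing) == 0L,
              "panel contigs missing from reference: %s",
              paste(missing, collapse = ", "))
  lens <- nchar(reference)[r$chrom]
  short <- which(r$end > lens)
  assert_that(length(short) == 0L,
              "panel region %s:[%d,%d) exceeds contig length %d",
              r$chrom[short[1]], r$start[short[1]], r$end[short[1]],
              lens[short[1]])
  invisible(TRUE)
}

## Base at 0-based positions (vectorized over chrom/pos).
ref_base_at <- function(reference, chrom, pos) {
  substring(reference[chrom], pos + 1L, pos + 1L)
}
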