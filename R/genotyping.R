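## Pileup construction and tumor genotyping. AF is defined throughout as
## 100 * (reads harboring the variant) / (total reads at the position),
## computed on consensus reads; N bases are excluded from both numerator
## and denominator.

#' Build a per-position base-count pileup from consensus reads
#'
#' @param consensus_reads data.frame with `chrom`, `start`, `seq` (equal
#'   length within the call).
#' @param panel A [panel_def()]; reads must lie inside single panel regions.
#' @param reference Named sequence vector for the ref base annotation.
#' @return data.frame of class `locus_pileup`: `chrom`, `pos` (0-based),
#'   `ref`, counts `A`/`C`/`G`/`T` and `depth` (sum of the four counts; `N`
#'   never counted), one row per covered panel position.
#' @export
pileup <- function(consensus_reads, panel, reference) {
  dt <- data.table::as.data.table(consensus_reads)
  assert_that(all(c("chrom", "start", "seq") %in% names(dt)),
              "consensus reads must have chrom/start/seq columns")
  if (nrow(dt) == 0L) return(empty_pileup())
  L <- nchar(dt$seq[1])
  assert_that(all(nchar(dt$seq) == L), "pileup requires equal-length reads")
  ok <- positions_in_panel(panel, dt$chrom, dt$start, dt$start + L)
  assert_that(all(ok), "read at %s:%d extends outside the panel",
              dt$chrom[!ok][1], dt$start[!ok][1])
  mat <- matrix(unlist(strsplit(dt$seq, "", fixed = TRUE), use.names = FALSE),
                nrow = nrow(dt), byrow = TRUE)
  long <- data.table::data.table(
    chrom = rep(dt$chrom, times = L),
    pos = rep(dt$start, times = L) + rep(seq_len(L) - 1L, each = nrow(dt)),
    base = as.vector(mat)
  )
  cnt <- long[base %in% c("A", "C", "G", "T"), .N, by = .(chrom, pos, base)]
  wide <- data.table::dcast(cnt, chrom + pos ~ base, value.var = "N", fill = 0L)
  for (b in c("A", "C", "G", "T")) if (!b %in% names(wide)) wide[, (b) := 0L]
  data.table::setcolorder(wide, c("chrom", "pos", "A", "C", "G", "T"))
  wide[, depth := A + C + G + T]
  wide[, ref := ref_base_at(reference, chrom, pos)]
  data.table::setorder(wide, chrom, pos)
  out <- as.data.frame(wide[, .(chrom, pos, ref, A, C, G, T, depth)])
  class(out) <- unique(c("locus_pileup", class(out)))
  out
}

empty_pileup <- function() {
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    A = integer(), C = integer(), G = integer(), T = integer(),
                    depth = integer(), stringsAsFactors = FALSE)
  class(out) <- unique(c("locus_pileup", class(out)))
  out
}

#' Call SNVs from a pileup
#'
#' Emits one call per (position, alternate base) with at least
#' `min_alt_count` supporting consensus reads at positions with depth at
#' least `min_depth`; AF is `100 * alt_count / depth`.
#'
#' @param pile A `locus_pileup` (see [pileup()]).
#' @param min_depth Minimum callable depth (default 50). Positions below it
#'   are uncallable and yield no calls.
#' @param min_alt_count Minimum supporting reads (default 1).
#' @return A `variant_calls` data.frame.
#' @export
call_snvs <- function(pile, min_depth = 50, min_alt_count = 1) {
  assert_that(is_count(min_depth), "min_depth must be a positive integer")
  dt <- data.table::as.data.table(pile)[depth >= min_depth]
  pieces <- lapply(c("A", "C", "G", "T"), function(b) {
    sub <- dt[ref != b & dt[[b]] >= min_alt_count]
    if (nrow(sub) == 0L) return(NULL)
    data.table::data.table(chrom = sub$chrom, pos = sub$pos, ref = sub$ref,
                           alt = b, alt_count = sub[[b]], depth = sub$depth)
  })
  res <- data.table::rbindlist(pieces)
  if (is.null(res) || nrow(res) == 0L) {
    return(variant_calls(character(), integer(), character(), character(),
                         integer(), integer()))
  }
  data.table::setorder(res, chrom, pos, alt)
  variant_calls(res$chrom, res$pos, res$ref, res$alt, res$alt_count, res$depth)
}

#' Remove germline variants from a tumor call set
#'
#' Tumor calls whose (chrom, pos, alt) matches a matched-normal call with
#' AF at or above `germline_af_cutoff` are discarded as constitutional
#' (SNPs); everything else is retained as somatic.
#'
#' @param tumor_calls,germline_calls `variant_calls` over the same panel.
#' @param germline_af_cutoff Percent AF in the normal marking a site as
#'   constitutional (default 5).
#' @return The somatic subset of `tumor_calls`.
#' @export
subtract_germline <- function(tumor_calls, germline_calls,
                              germline_af_cutoff = 5) {
  if (nrow(tumor_calls) == 0L) return(tumor_calls)
  gl <- germline_calls[germline_calls$af >= germline_af_cutoff, , drop = FALSE]
  key <- function(x) paste(x$chrom, x$pos, x$alt, sep = ":")
  keep <- !(key(tumor_calls) %in% key(gl))
  log_msg("genotype", "germline subtraction: %d of %d tumor calls removed",
          sum(!keep), nrow(tumor_calls))
  tumor_calls[keep, , drop = FALSE]
}

#' Select a patient's reporter variants
#'
#' Reporters are the somatic tumor-tissue SNVs with AF at or above the
#' genotyping threshold (inclusive; 18% by default). These are the variants
#' subsequently tracked in plasma.
#'
#' @param somatic_calls `variant_calls` after germline subtraction.
#' @param genotyping_af_threshold Percent AF threshold, default 18.
#' @param patient_id Identifier stored with the set.
#' @return Object of class `reporter_set`: list with `patient_id`,
#'   `reporters` (a `variant_calls`), and the `thresholds` used. An empty
#'   somatic set yields a valid empty reporter set (patient unmonitorable).
#' @export
select_reporters <- function(somatic_calls, genotyping_af_threshold = 18,
                             patient_id = NA_character_) {
  assert_that(genotyping_af_threshold > 0, "threshold must be positive")
  sel <- somatic_calls[somatic_calls$af >= genotyping_af_threshold, , drop = FALSE]
  rownames(sel) <- NULL
  if (nrow(sel) == 0L) {
    log_msg("genotype", "patient %s: no reporters at AF >= %g%% (unmonitorable)",
            patient_id, genotyping_af_threshold)
  } else {
    log_msg("genotype", "patient %s: %d reporters selected", patient_id, nrow(sel))
  }
  structure(list(patient_id = patient_id, reporters = sel,
                 thresholds = list(genotyping_af_threshold = genotyping_af_threshold)),
            class = "reporter_set")
}

#' @export
print.reporter_set <- function(x, ...) {
  cat(sprintf("Reporter set for %s: %d SNVs (AF >= %g%%)\n", x$patient_id,
              nrow(x$reporters), x$thresholds$genotyping_af_threshold))
  invisible(x)
}

#' Genotype one patient from tumor and germline reads
#'
#' Convenience wrapper chaining the production path: deduplicate tumor and
#' germline reads, pile up, call SNVs, subtract germline, select reporters.
#'
#' @param tumor_reads,germline_reads Raw UMI-tagged read data.frames.
#' @param panel,reference Panel and reference.
#' @param config An [run_config()].
#' @param patient_id Identifier for the resulting reporter set.
#' @return A `reporter_set`.
#' @export
genotype_patient <- function(tumor_reads, germline_reads, panel, reference,
                             config = run_config(),
                             patient_id = NA_character_) {
  tum <- deduplicate(tumor_reads, config)
  gl <- deduplicate(germline_reads, config)
  tum_calls <- call_snvs(pileup(tum$consensus, panel, reference),
                         min_depth = config$min_genotyping_depth)
  gl_calls <- call_snvs(pileup(gl$consensus, panel, reference),
                        min_depth = 1, min_alt_count = 1)
  somatic <- subtract_germline(tum_calls, gl_calls, config$germline_af_cutoff)
  select_reporters(somatic, config$genotyping_af_threshold, patient_id)
}
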