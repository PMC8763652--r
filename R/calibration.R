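## Assay calibration: spike-in dilution detection limit, the healthy-donor
## false-positive matrix, and threshold selection. Donor classification
## reuses the exact production monitoring path (quantify_reporters +
## classify_sample) so that calibration measures the real pipeline.

#' Quantify a spike-in dilution series
#'
#' Runs every spike-in sample through the production reporter
#' quantification path with the spiked variants as the reporter set.
#'
#' @param series Output of [simulate_spikein_series()] (or a list with the
#'   same shape built from real data).
#' @param detection_min_reads Reporter detection floor (default 1).
#' @return data.frame with one row per (nominal_af, replicate, variant):
#'   `nominal_af`, `replicate`, `variant_id`, `af`, `detected`, plus the
#'   per-sample `mean_af`.
#' @export
quantify_spikein_series <- function(series, detection_min_reads = 1) {
  vars <- series$variants
  rs <- structure(list(patient_id = "spikein",
                       reporters = variant_calls(vars$chrom, vars$pos,
                                                 vars$ref, vars$alt,
                                                 rep(1L, nrow(vars)),
                                                 rep(1L, nrow(vars))),
                       thresholds = list(genotyping_af_threshold = NA_real_)),
                  class = "reporter_set")
  rows <- lapply(series$samples, function(s) {
    m <- quantify_reporters(rs, s$pileup, detection_min_reads)
    res <- classify_sample(m)
    data.frame(nominal_af = s$nominal_af, replicate = s$replicate,
               variant_id = paste(m$chrom, m$pos, m$alt, sep = ":"),
               af = ifelse(is.na(m$af), 0, m$af), detected = m$detected,
               mean_af = res$mean_af, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spike-in sensitivity analysis and detection floor
#'
#' Tabulates the detected fraction of variant-replicates at each nominal
#' AF and reports the detection floor: the smallest nominal AF whose
#' detected fraction satisfies the robustness rule (default: all
#' variant-replicates detected).
#'
#' @param spikein_df Output of [quantify_spikein_series()].
#' @param robustness_rule `"all"` (every variant-replicate detected) or a
#'   numeric fraction in (0, 1] (e.g. 0.95).
#' @return list with `table` (per-AF `n_detected`, `n`, `detected_frac`,
#'   `mean_measured_af`), `detection_floor_af` (`NA` when no AF satisfies
#'   the rule) and `af_slope`, the least-squares slope of measured on
#'   nominal AF.
#' @export
run_spikein_analysis <- function(spikein_df, robustness_rule = "all") {
  assert_that(length(unique(spikein_df$nominal_af)) >= 2,
              "need at least two nominal AFs")
  need <- if (identical(robustness_rule, "all")) 1.0 else {
    assert_that(is.numeric(robustness_rule) && robustness_rule > 0 &&
                  robustness_rule <= 1, "robustness_rule must be 'all' or in (0,1]")
    robustness_rule
  }
  dt <- data.table::as.data.table(spikein_df)
  tab <- dt[, .(n_detected = sum(detected), n = .N,
                detected_frac = mean(detected),
                mean_measured_af = mean(af)),
            by = nominal_af]
  data.table::setorder(tab, nominal_af)
  qual <- tab[detected_frac >= need, nominal_af]
  floor_af <- if (length(qual)) min(qual) else NA_real_
  fit <- lm(af ~ nominal_af, data = spikein_df)
  list(table = as.data.frame(tab), detection_floor_af = floor_af,
       af_slope = unname(coef(fit)["nominal_af"]))
}

#' Healthy-donor false-positive matrix
#'
#' Monitors every patient's reporter set in every donor cfDNA sample and
#' classifies each (patient, donor) pair with the production positivity
#' rule. Patients with empty reporter sets are excluded (and logged),
#' mirroring unmonitorable patients.
#'
#' @param reporter_sets List of `reporter_set` objects.
#' @param donor_pileups Named list of donor `locus_pileup`s.
#' @param config An [run_config()].
#' @return Object of class `fp_matrix`: list with `entries` (data.frame:
#'   patient_id, donor_id, n_detected, mean_af, positive), `n_tests`,
#'   `n_positive`, `fp_rate`.
#' @export
build_fp_matrix <- function(reporter_sets, donor_pileups,
                            config = run_config()) {
  usable <- Filter(function(rs) nrow(rs$reporters) > 0, reporter_sets)
  if (length(usable) < length(reporter_sets)) {
    log_msg("calibrate", "%d patient(s) excluded from FP matrix (no reporters)",
            length(reporter_sets) - length(usable))
  }
  donor_ids <- names(donor_pileups) %||% sprintf("donor_%d", seq_along(donor_pileups))
  rows <- list()
  for (rs in usable) {
    for (d in seq_along(donor_pileups)) {
      m <- quantify_reporters(rs, donor_pileups[[d]],
                              config$detection_min_reads)
      res <- classify_sample(m, config)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = rs$patient_id, donor_id = donor_ids[d],
        n_detected = res$n_detected, mean_af = res$mean_af,
        positive = res$positive, stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  n_tests <- nrow(entries)
  n_positive <- sum(entries$positive)
  structure(list(entries = entries, n_tests = n_tests,
                 n_positive = n_positive, fp_rate = n_positive / n_tests),
            class = "fp_matrix")
}

#' @export
print.fp_matrix <- function(x, ...) {
  cat(sprintf("FP matrix: %d positives / %d tests = %.4f\n",
              x$n_positive, x$n_tests, x$fp_rate))
  invisible(x)
}

#' False-positive rate over a threshold grid
#'
#' Re-evaluates the donor FP matrix at every combination of tumor
#' genotyping AF threshold (which reselects each patient's reporters from
#' the supplied somatic call sets) and sample mean-AF threshold (which
#' reclassifies every patient-donor pair).
#'
#' @param somatic_calls Named list (by patient) of somatic `variant_calls`.
#' @param donor_pileups Named list of donor pileups.
#' @param genotyping_grid Percent AF thresholds for reporter selection.
#' @param mean_af_grid Percent mean-AF positivity thresholds.
#' @param config Base [run_config()].
#' @return data.frame with `genotyping_af_threshold`,
#'   `mrd_mean_af_threshold`, `n_tests`, `n_positive`, `fp_rate`.
#' @export
fp_rate_grid <- function(somatic_calls, donor_pileups,
                         genotyping_grid = c(10, 18, 25),
                         mean_af_grid = c(0.0005, 0.001, 0.01),
                         config = run_config()) {
  out <- list()
  for (g in genotyping_grid) {
    sets <- lapply(names(somatic_calls), function(id) {
      select_reporters(somatic_calls[[id]], g, id)
    })
    for (m in mean_af_grid) {
      cfg <- config
      cfg$genotyping_af_threshold <- g
      cfg$mrd_mean_af_threshold <- m
      fp <- build_fp_matrix(sets, donor_pileups, cfg)
      out[[length(out) + 1L]] <- data.frame(
        genotyping_af_threshold = g, mrd_mean_af_threshold = m,
        n_tests = fp$n_tests, n_positive = fp$n_positive,
        fp_rate = fp$fp_rate)
    }
  }
  do.call(rbind, out)
}

#' Select operating thresholds from a false-positive grid
#'
#' Chooses the least stringent qualifying pair — the smallest thresholds
#' whose FP rate is at or below the target — maximizing sensitivity at the
#' target specificity. Candidates are ordered by mean-AF threshold, then
#' genotyping threshold, ascending.
#'
#' @param grid data.frame as returned by [fp_rate_grid()] (columns
#'   `genotyping_af_threshold`, `mrd_mean_af_threshold`, `fp_rate`).
#' @param target_fp Target false-positive rate in (0, 1) (default 0.05).
#' @return list with `grid` (input, annotated with `meets_target`) and
#'   `selected` (one-row data.frame, or `NULL` when no pair qualifies).
#' @export
threshold_grid_search <- function(grid, target_fp = 0.05) {
  req <- c("genotyping_af_threshold", "mrd_mean_af_threshold", "fp_rate")
  assert_that(all(req %in% names(grid)), "grid must have columns: %s",
              paste(req, collapse = ", "))
  assert_that(is.numeric(target_fp) && target_fp > 0 && target_fp <= 1,
              "target_fp must be in (0, 1]")
  grid <- grid[order(grid$mrd_mean_af_threshold, grid$genotyping_af_threshold), ,
               drop = FALSE]
  grid$meets_target <- grid$fp_rate <= target_fp
  sel <- grid[grid$meets_target, , drop = FALSE]
  list(grid = grid,
       selected = if (nrow(sel)) sel[1, , drop = FALSE] else NULL)
}
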