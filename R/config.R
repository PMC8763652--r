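#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the MRD pipeline in one validated
#' object. The defaults are the production settings of the assay:
#'
#' * `consensus_freq = 0.90` — per-column base agreement a UMI family must
#'   reach for a consensus base (otherwise `N`);
#' * `min_family_size = 10` — minimum reads per UMI family; smaller families
#'   are discarded before consensus calling;
#' * `genotyping_af_threshold = 18` — percent AF a tumor-tissue somatic SNV
#'   must reach (inclusive) to become a plasma reporter;
#' * `mrd_mean_af_threshold = 0.001` — percent mean AF over detected
#'   reporters a plasma sample must reach (inclusive) to be called
#'   ctDNA-positive;
#' * `min_genotyping_depth = 50` — minimum consensus depth for a tumor locus
#'   to be callable;
#' * `germline_af_cutoff = 5` — percent AF in the matched normal above which
#'   a site is treated as constitutional and removed;
#' * `detection_min_reads = 1` — consensus reads supporting a reporter in
#'   plasma needed to count it as detected.
#'
#' Simulator defaults (`family_size_mean = 12`, `raw_error_rate = 1e-3`
#' substitutions per raw base, `consensus_residual_error = 1e-6` specific
#' alternate errors per consensus read) define the synthetic study
#' conditions; see the methods vignette.
#'
#' @param consensus_freq Consensus column agreement fraction in (0, 1].
#' @param min_family_size Positive integer family-size floor.
#' @param genotyping_af_threshold Reporter selection threshold, percent.
#' @param mrd_mean_af_threshold Sample positivity threshold, percent.
#' @param min_genotyping_depth Minimum callable consensus depth.
#' @param germline_af_cutoff Constitutional-site cutoff, percent.
#' @param detection_min_reads Reporter detection read floor.
#' @param include_undetected_in_mean Logical; if `TRUE` the sample mean AF
#'   averages over all reporters (undetected contribute 0) instead of the
#'   default detected-only mean. Exposed for sensitivity analyses.
#' @param family_size_mean Simulator: mean reads per UMI family.
#' @param raw_error_rate Simulator: substitution rate per raw read base.
#' @param consensus_residual_error Simulator: residual specific-alternate
#'   error rate per consensus read.
#' @param seed Optional integer seed recorded with the run.
#' @return An object of class `mrd_config` (a validated named list).
#' @examples
#' cfg <- run_config()
#' cfg$genotyping_af_threshold
#' @export
run_config <- function(consensus_freq = 0.90,
                       min_family_size = 10,
                       genotyping_af_threshold = 18,
                       mrd_mean_af_threshold = 0.001,
                       min_genotyping_depth = 50,
                       germline_af_cutoff = 5,
                       detection_min_reads = 1,
                       include_undetected_in_mean = FALSE,
                       family_size_mean = 12,
                       raw_error_rate = 1e-3,
                       consensus_residual_error = 1e-6,
                       seed = NULL) {
  assert_that(is_prob(consensus_freq), "consensus_freq must be in (0, 1]")
  assert_that(is_count(min_family_size), "min_family_size must be a positive integer")
  for (nm in c("genotyping_af_threshold", "mrd_mean_af_threshold",
               "germline_af_cutoff")) {
    v <- get(nm)
    assert_that(is.numeric(v) && length(v) == 1L && v > 0,
                "%s must be a single positive number", nm)
  }
  assert_that(is_count(min_genotyping_depth), "min_genotyping_depth must be a positive integer")
  assert_that(is_count(detection_min_reads), "detection_min_reads must be a positive integer")
  assert_that(is.numeric(family_size_mean) && family_size_mean >= 1,
              "family_size_mean must be >= 1")
  assert_that(is.numeric(raw_error_rate) && raw_error_rate >= 0 && raw_error_rate < 1,
              "raw_error_rate must be in [0, 1)")
  assert_that(is.numeric(consensus_residual_error) && consensus_residual_error >= 0,
              "consensus_residual_error must be non-negative")
  cfg <- list(
    consensus_freq = consensus_freq,
    min_family_size = as.integer(min_family_size),
    genotyping_af_threshold = genotyping_af_threshold,
    mrd_mean_af_threshold = mrd_mean_af_threshold,
    min_genotyping_depth = as.integer(min_genotyping_depth),
    germline_af_cutoff = germline_af_cutoff,
    detection_min_reads = as.integer(detection_min_reads),
    include_undetected_in_mean = isTRUE(include_undetected_in_mean),
    family_size_mean = family_size_mean,
    raw_error_rate = raw_error_rate,
    consensus_residual_error = consensus_residual_error,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  structure(cfg, class = "mrd_config")
}

#' @export
print.mrd_config <- function(x, ...) {
  cat("MRD pipeline configuration\n")
  cat(sprintf("  consensus: freq >= %.2f, family size >= %d\n",
              x$consensus_freq, x$min_family_size))
  cat(sprintf("  genotyping: AF >= %g%%, depth >= %d, germline cutoff %g%%\n",
              x$genotyping_af_threshold, x$min_genotyping_depth,
              x$germline_af_cutoff))
  cat(sprintf("  monitoring: >= %d read(s)/reporter, mean AF >= %g%%\n",
              x$detection_min_reads, x$mrd_mean_af_threshold))
  invisible(x)
}

#' Read or write a run configuration as JSON
#'
#' @param path File path.
#' @param config An `mrd_config` object.
#' @return `read_config` returns an `mrd_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "config file not found: %s", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(vals), names(formals(run_config)))
  do.call(run_config, vals[keep])
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  assert_that(inherits(config, "mrd_config"), "config must be an mrd_config")
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
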