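## End-to-end orchestration of a simulated (or identically-shaped real)
## cohort bundle through the production pipeline.

#' Run the full MRD pipeline on a cohort bundle
#'
#' Per patient: tumor/germline dedup + genotyping + reporter selection
#' (read-level tissue samples; when the bundle was generated with
#' `tissue_reads = FALSE`, reporter candidates are taken from the tissue
#' truth profile at an emulated genotyping depth instead), plasma reporter
#' quantification and MRD classification at every milestone, and course
#' assembly. Cohort-level: detection-rate tables, the donor FP matrix, and
#' landmark PFS/OS comparisons.
#'
#' @param bundle An `mrd_cohort` from [simulate_cohort()].
#' @param config An [run_config()].
#' @return list with `reporter_sets`, `results` (nested per patient),
#'   `courses`, `detection` (preresection/milestone/stage tables),
#'   `fp_matrix`, `endpoints` (pfs/os data), `comparisons` (pfs/os
#'   `survival_comparison`, `NULL` when a group is empty).
#' @export
run_cohort_pipeline <- function(bundle, config = run_config()) {
  assert_that(inherits(bundle, "mrd_cohort"), "bundle must be an mrd_cohort")
  ids <- names(bundle$profiles)
  reporter_sets <- lapply(ids, function(id) {
    if (!is.null(bundle$tissue_reads)) {
      genotype_patient(bundle$tissue_reads[[id]]$tumor,
                       bundle$tissue_reads[[id]]$germline,
                       bundle$panel, bundle$reference, config, id)
    } else {
      truth_reporter_set(bundle$profiles[[id]], config)
    }
  })
  names(reporter_sets) <- ids

  results <- lapply(ids, function(id) {
    ms_names <- names(bundle$plasma[[id]])
    res <- lapply(ms_names, function(ms) {
      m <- quantify_reporters(reporter_sets[[id]], bundle$plasma[[id]][[ms]],
                              config$detection_min_reads)
      classify_sample(m, config, sample_id = paste0(id, "_", ms),
                      milestone = ms)
    })
    names(res) <- ms_names
    res
  })
  names(results) <- ids

  courses <- lapply(ids, function(id) {
    assemble_course(unname(results[[id]]),
                    bundle$clinical[bundle$clinical$patient_id == id, ])
  })
  names(courses) <- ids

  detection <- list(
    preresection = cohort_detection_summary(courses, "preresection"),
    milestone = cohort_detection_summary(courses, "milestone"),
    stage = cohort_detection_summary(courses, "stage")
  )
  fp <- build_fp_matrix(reporter_sets, bundle$donors, config)

  endpoints <- list(pfs = compute_endpoints(bundle$clinical, courses, "pfs"),
                    os = compute_endpoints(bundle$clinical, courses, "os"))
  comparisons <- lapply(endpoints, function(ep) {
    if (length(unique(ep$group)) == 2) compare_survival(ep) else NULL
  })
  list(reporter_sets = reporter_sets, results = results, courses = courses,
       detection = detection, fp_matrix = fp, endpoints = endpoints,
       comparisons = comparisons)
}

## Reporter candidates straight from the tissue truth profile, emulating a
## noiseless deep genotyping run (used by fast-mode bundles).
truth_reporter_set <- function(profile, config = run_config()) {
  som <- profile$somatic
  depth <- 10000L
  calls <- variant_calls(som$chrom, som$pos, som$ref, som$alt,
                         round(som$tumor_af / 100 * depth), depth)
  select_reporters(calls, config$genotyping_af_threshold, profile$patient_id)
}
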