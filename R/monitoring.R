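## Plasma reporter monitoring. A plasma sample is ctDNA-positive when
## (a) at least one predefined reporter SNV is detected and (b) the mean AF
## over the detected reporters reaches the positivity threshold
## (0.001% by default). Both comparisons are inclusive.

#' Quantify a patient's reporters in a plasma pileup
#'
#' @param reporter_set A `reporter_set` from [select_reporters()].
#' @param plasma_pileup A `locus_pileup` of the plasma sample.
#' @param detection_min_reads Consensus reads needed to call a reporter
#'   detected (default 1).
#' @param panel Optional [panel_def()]; when supplied, reporters outside
#'   the panel raise an error.
#' @return data.frame with one row per reporter (order preserved): `chrom`,
#'   `pos`, `ref`, `alt`, `alt_count`, `depth`, `af` (percent; `NA` when
#'   depth is 0) and `detected`. Reporters absent from the pileup get
#'   depth 0 and `detected = FALSE`.
#' @export
quantify_reporters <- function(reporter_set, plasma_pileup,
                               detection_min_reads = 1, panel = NULL) {
  assert_that(inherits(reporter_set, "reporter_set"),
              "reporter_set must come from select_reporters()")
  rep_df <- reporter_set$reporters
  if (!is.null(panel) && nrow(rep_df)) {
    ok <- positions_in_panel(panel, rep_df$chrom, rep_df$pos, rep_df$pos + 1L)
    assert_that(all(ok), "reporter at %s:%d outside the panel",
                rep_df$chrom[!ok][1], rep_df$pos[!ok][1])
  }
  n <- nrow(rep_df)
  out <- data.frame(chrom = rep_df$chrom, pos = rep_df$pos,
                    ref = rep_df$ref, alt = rep_df$alt,
                    alt_count = integer(n), depth = integer(n),
                    af = rep(NA_real_, n), detected = logical(n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  pile <- data.table::as.data.table(plasma_pileup)
  idx <- match(paste(out$chrom, out$pos), paste(pile$chrom, pile$pos))
  hit <- !is.na(idx)
  if (any(hit)) {
    prow <- as.data.frame(pile[idx[hit]])
    out$depth[hit] <- prow$depth
    out$alt_count[hit] <- as.integer(as.matrix(prow[, c("A", "C", "G", "T")])[
      cbind(seq_len(nrow(prow)), match(out$alt[hit], c("A", "C", "G", "T")))])
  }
  pos_depth <- out$depth > 0
  out$af[pos_depth] <- 100 * out$alt_count[pos_depth] / out$depth[pos_depth]
  out$detected <- pos_depth & out$alt_count >= detection_min_reads
  out
}

#' Classify a plasma sample's MRD status
#'
#' Computes the sample mean AF as the arithmetic mean over *detected*
#' reporters (0 when none detected; undetected reporters do not contribute
#' zeros unless `config$include_undetected_in_mean` is set) and applies the
#' two-part positivity rule.
#'
#' @param measurements Output of [quantify_reporters()].
#' @param config An [run_config()] providing `mrd_mean_af_threshold`.
#' @param sample_id,milestone Identifiers carried into the result.
#' @return Object of class `mrd_result`: list with `sample_id`,
#'   `milestone`, `measurements`, `n_detected`, `mean_af` (percent),
#'   `positive`, `unmonitorable`.
#' @examples
#' rs <- select_reporters(
#'   variant_calls("c", 5, "A", "T", 30, 100), patient_id = "P1")
#' pile <- data.frame(chrom = "c", pos = 5, ref = "A",
#'                    A = 7998L, C = 0L, G = 0L, T = 2L, depth = 8000L)
#' classify_sample(quantify_reporters(rs, pile))$mean_af  # 0.025
#' @export
classify_sample <- function(measurements, config = run_config(),
                            sample_id = NA_character_,
                            milestone = NA_character_) {
  unmonitorable <- nrow(measurements) == 0L
  det <- measurements$detected
  n_detected <- sum(det)
  mean_af <- if (isTRUE(config$include_undetected_in_mean)) {
    if (nrow(measurements)) {
      af0 <- ifelse(det, measurements$af, 0)
      mean(af0)
    } else 0
  } else if (n_detected > 0) {
    mean(measurements$af[det])
  } else 0
  positive <- !unmonitorable && n_detected >= 1 &&
    mean_af >= config$mrd_mean_af_threshold
  structure(list(sample_id = sample_id, milestone = milestone,
                 measurements = measurements, n_detected = n_detected,
                 mean_af = mean_af, positive = positive,
                 unmonitorable = unmonitorable),
            class = "mrd_result")
}

#' @export
print.mrd_result <- function(x, ...) {
  cat(sprintf("MRD result %s [%s]: %d/%d reporters detected, mean AF %.5g%% -> %s\n",
              x$sample_id, x$milestone, x$n_detected, nrow(x$measurements),
              x$mean_af,
              if (x$unmonitorable) "unmonitorable" else if (x$positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' Assemble a patient's longitudinal MRD course
#'
#' Orders per-sample results by day, extracts the postsurgical landmark
#' status, and derives surveillance quantities: `conversion_day` (first
#' positive sample strictly after a negative one) and `lead_time_days`
#' (`relapse_day` minus the first *sustained* positive day, where sustained
#' means no later negative sample before relapse). Isolated positives
#' (positive samples with a later negative before relapse, or with no
#' relapse at all) are flagged as possible false positives.
#'
#' @param results List of `mrd_result` objects for one patient.
#' @param clinical_record One-row slice of a `clinical_table`, or a named
#'   list with `patient_id`, `relapse_day`, `death_day`,
#'   `last_followup_day`, `stage`.
#' @param days Numeric vector of sample days matching `results` (defaults
#'   to the milestone day columns in `clinical_record` looked up by each
#'   result's milestone).
#' @return Object of class `patient_course`: list with `patient_id`,
#'   `samples` (data.frame: day, milestone, n_detected, mean_af, positive),
#'   `landmark_status` ("positive"/"negative"/NA), `conversion_day`,
#'   `lead_time_days`, `suspect_fp_days`, `relapse_day`, `death_day`,
#'   `last_followup_day`, `stage`.
#' @export
assemble_course <- function(results, clinical_record, days = NULL) {
  assert_that(length(results) >= 1L, "need at least one MRD result")
  rec <- as.list(clinical_record)
  ms <- vapply(results, `[[`, "", "milestone")
  if (is.null(days)) {
    day_cols <- paste0("day_", ms)
    assert_that(all(day_cols %in% names(rec)),
                "no day recorded for milestone(s): %s",
                paste(ms[!day_cols %in% names(rec)], collapse = ", "))
    days <- as.numeric(unlist(rec[day_cols]))
  }
  assert_that(!anyDuplicated(days), "duplicate sample days for patient %s",
              rec$patient_id)
  ord <- order(days)
  results <- results[ord]
  days <- days[ord]
  ms <- ms[ord]
  samples <- data.frame(
    day = days, milestone = ms,
    n_detected = vapply(results, `[[`, 0L, "n_detected"),
    mean_af = vapply(results, `[[`, 0, "mean_af"),
    positive = vapply(results, `[[`, FALSE, "positive"),
    stringsAsFactors = FALSE
  )
  relapse_day <- as.numeric(rec$relapse_day %||% NA_real_)
  landmark <- samples$positive[samples$milestone == "postsurgery"]
  landmark_status <- if (length(landmark) == 0L) NA_character_
                     else if (landmark[1]) "positive" else "negative"

  pos <- samples$positive
  conversion_day <- NA_real_
  for (i in seq_len(nrow(samples))) {
    if (pos[i] && i > 1L && any(!pos[seq_len(i - 1L)])) {
      conversion_day <- samples$day[i]
      break
    }
  }
  horizon <- if (is.na(relapse_day)) Inf else relapse_day
  sustained_day <- NA_real_
  suspect_fp_days <- numeric(0)
  for (i in which(pos & samples$day <= horizon)) {
    later_neg <- any(!pos & samples$day > samples$day[i] & samples$day <= horizon)
    if (!later_neg && is.na(sustained_day) && is.finite(horizon)) {
      sustained_day <- samples$day[i]
    }
    if (later_neg) {
      suspect_fp_days <- c(suspect_fp_days, samples$day[i])
    }
  }
  lead_time_days <- if (!is.na(sustained_day) && !is.na(relapse_day)) {
    relapse_day - sustained_day
  } else NA_real_
  structure(list(patient_id = rec$patient_id, samples = samples,
                 landmark_status = landmark_status,
                 conversion_day = conversion_day,
                 lead_time_days = lead_time_days,
                 suspect_fp_days = suspect_fp_days,
                 relapse_day = relapse_day,
                 death_day = as.numeric(rec$death_day %||% NA_real_),
                 last_followup_day = as.numeric(rec$last_followup_day %||% NA_real_),
                 stage = rec$stage %||% NA_character_),
            class = "patient_course")
}

#' @export
print.patient_course <- function(x, ...) {
  cat(sprintf("Course %s: %d samples, landmark %s, relapse day %s, lead time %s\n",
              x$patient_id, nrow(x$samples), x$landmark_status %||% "NA",
              ifelse(is.na(x$relapse_day), "-", x$relapse_day),
              ifelse(is.na(x$lead_time_days), "-", x$lead_time_days)))
  invisible(x)
}

#' Build a patient course from a transcribed status table
#'
#' For tabulating published (or synthetic stand-in) per-patient ctDNA
#' status tables that record only positive/negative calls per milestone,
#' without underlying reporter measurements.
#'
#' @param patient_id Identifier.
#' @param status Named character vector milestone -> "positive"/"negative";
#'   missing or empty entries mean the sample was not collected.
#' @param days Named numeric vector milestone -> day (defaults:
#'   presurgery -7, intraoperative 0, postsurgery 10, followup_k 10 + 90k).
#' @param stage,relapse_day,death_day,last_followup_day Clinical fields.
#' @return A `patient_course` whose `mean_af` values are `NA` (only
#'   positivity is known).
#' @export
patient_course_from_status <- function(patient_id, status, days = NULL,
                                       stage = NA_character_,
                                       relapse_day = NA_real_,
                                       death_day = NA_real_,
                                       last_followup_day = NA_real_) {
  status <- status[!is.na(status) & nzchar(status)]
  assert_that(length(status) >= 1L, "patient %s: no sampled milestones", patient_id)
  assert_that(all(status %in% c("positive", "negative")),
              "status values must be 'positive'/'negative'")
  assert_that(all(grepl(.milestone_rx, names(status))),
              "unknown milestone in status for patient %s", patient_id)
  if (is.null(days)) {
    fu <- grep("^followup_", names(status), value = TRUE)
    days <- c(presurgery = -7, intraoperative = 0, postsurgery = 10,
              setNames(10 + 90 * as.numeric(sub("followup_", "", fu)), fu))
  }
  days <- days[names(status)]
  samples <- data.frame(day = unname(days), milestone = names(status),
                        n_detected = NA_integer_, mean_af = NA_real_,
                        positive = status == "positive",
                        stringsAsFactors = FALSE)
  samples <- samples[order(samples$day), , drop = FALSE]
  rownames(samples) <- NULL
  landmark <- samples$positive[samples$milestone == "postsurgery"]
  structure(list(patient_id = patient_id, samples = samples,
                 landmark_status = if (length(landmark) == 0L) NA_character_
                                   else if (landmark[1]) "positive" else "negative",
                 conversion_day = NA_real_, lead_time_days = NA_real_,
                 suspect_fp_days = numeric(0),
                 relapse_day = as.numeric(relapse_day),
                 death_day = as.numeric(death_day),
                 last_followup_day = as.numeric(last_followup_day),
                 stage = stage),
            class = "patient_course")
}

#' Cohort-level ctDNA detection rates
#'
#' Tabulates detection with numerators and denominators alongside
#' percentages. Groupings:
#' * `"preresection"` — patient-level: positive in the presurgery OR the
#'   intraoperative sample;
#' * `"milestone"` — sample-level rate per milestone;
#' * `"stage"` — patient-level pre-resection rate split by stage group
#'   (I--II vs III).
#'
#' @param courses List of `patient_course` objects.
#' @param grouping One of `"preresection"`, `"milestone"`, `"stage"`.
#' @return data.frame with `group`, `n_positive`, `n`, `rate_pct`.
#' @export
cohort_detection_summary <- function(courses,
                                     grouping = c("preresection", "milestone",
                                                  "stage")) {
  grouping <- match.arg(grouping)
  if (length(courses) == 0L) {
    return(data.frame(group = character(), n_positive = integer(),
                      n = integer(), rate_pct = numeric()))
  }
  pre_pos <- vapply(courses, function(cr) {
    s <- cr$samples
    any(s$positive[s$milestone %in% c("presurgery", "intraoperative")])
  }, FALSE)
  has_pre <- vapply(courses, function(cr) {
    any(cr$samples$milestone %in% c("presurgery", "intraoperative"))
  }, FALSE)
  if (grouping == "preresection") {
    n <- sum(has_pre)
    k <- sum(pre_pos[has_pre])
    out <- data.frame(group = "preresection", n_positive = k, n = n,
                      rate_pct = 100 * k / n)
  } else if (grouping == "milestone") {
    all_samples <- do.call(rbind, lapply(courses, `[[`, "samples"))
    ms <- ifelse(grepl("^followup", all_samples$milestone), "followup",
                 all_samples$milestone)
    agg <- aggregate(list(n_positive = all_samples$positive),
                     by = list(group = ms), FUN = sum)
    agg$n <- as.vector(table(ms)[agg$group])
    out <- data.frame(group = agg$group, n_positive = agg$n_positive,
                      n = agg$n, rate_pct = 100 * agg$n_positive / agg$n)
  } else {
    sg <- stage_group(vapply(courses, function(cr) cr$stage %||% NA_character_, ""))
    out <- do.call(rbind, lapply(unique(sg), function(g) {
      sel <- sg == g & has_pre
      data.frame(group = g, n_positive = sum(pre_pos[sel]), n = sum(sel),
                 rate_pct = 100 * sum(pre_pos[sel]) / sum(sel))
    }))
    out <- out[order(out$group), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
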