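## Clinical outcome statistics. Landmark analysis: time is measured from
## the postsurgical blood draw, groups are the MRD status at that draw.
## Standard estimators come from the survival package; hand and
## permutation oracles live in the test suite.

#' Construct survival endpoints from clinical records and MRD courses
#'
#' PFS events are the earliest of radiographic progression or death; OS
#' events are death. Times run from the landmark sample's day; censoring is
#' at last follow-up. Patients without the landmark sample (or with an
#' unmonitorable landmark result) are excluded with a log message.
#'
#' @param clinical A `clinical_table`.
#' @param courses List of `patient_course` objects (one per patient).
#' @param endpoint `"pfs"` or `"os"`.
#' @param landmark Milestone defining time zero and grouping
#'   (default `"postsurgery"`).
#' @return data.frame with `patient_id`, `time` (days), `event` (logical),
#'   `group` (`"MRD-positive"`/`"MRD-negative"`).
#' @export
compute_endpoints <- function(clinical, courses, endpoint = c("pfs", "os"),
                              landmark = "postsurgery") {
  endpoint <- match.arg(endpoint)
  rows <- list()
  for (cr in courses) {
    sel <- cr$samples$milestone == landmark
    if (!any(sel)) {
      log_msg("outcomes", "patient %s: no %s sample, excluded", cr$patient_id,
              landmark)
      next
    }
    lday <- cr$samples$day[sel][1]
    status <- if (cr$samples$positive[sel][1]) "MRD-positive" else "MRD-negative"
    rel <- cr$relapse_day
    dth <- cr$death_day
    lfu <- cr$last_followup_day
    if (endpoint == "pfs") {
      ev_day <- suppressWarnings(min(rel, dth, na.rm = TRUE))
      if (!is.finite(ev_day)) ev_day <- NA_real_
    } else {
      ev_day <- dth
    }
    event <- !is.na(ev_day)
    time <- (if (event) ev_day else lfu) - lday
    assert_that(time > 0, "patient %s: non-positive %s time %g", cr$patient_id,
                endpoint, time)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = cr$patient_id, time = time, event = event, group = status,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out %||% data.frame(patient_id = character(), time = numeric(),
                      event = logical(), group = character())
}

#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator (via `survival::survfit`); censored times
#' reduce the risk set without steps, the curve starts at 1 at time 0.
#'
#' @param data data.frame with `time` and `event` columns.
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv` (step
#'   function values, first row `time = 0, surv = 1`).
#' @export
km_estimate <- function(data) {
  assert_that(nrow(data) >= 1L, "need at least one observation")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  data.frame(time = c(0, fit$time), n_risk = c(fit$n, fit$n.risk),
             n_event = c(0, fit$n.event), surv = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic with a two-sided
#' chi-square p value (via `survival::survdiff`). When neither group has
#' any event the p value is undefined and flagged.
#'
#' @param groupA,groupB data.frames with `time` and `event` columns.
#' @return list with `chi2`, `p_value`, `defined` (FALSE when no events).
#' @export
logrank_test <- function(groupA, groupB) {
  assert_that(nrow(groupA) >= 1 && nrow(groupB) >= 1,
              "both groups must be non-empty")
  df <- rbind(cbind(groupA[, c("time", "event")], group = "A"),
              cbind(groupB[, c("time", "event")], group = "B"))
  if (sum(df$event) == 0) {
    return(list(chi2 = NA_real_, p_value = NA_real_, defined = FALSE))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(chi2 = unname(sd$chisq),
       p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       defined = TRUE)
}

#' Two-group hazard ratio
#'
#' Hazard of `groupA` relative to `groupB` from an unpenalized Cox
#' proportional-hazards fit with a binary group covariate, with a 95%
#' Wald CI. When the fit separates (a group with no events, or a
#' diverging coefficient), the Mantel-Haenszel (O/E ratio) estimate from
#' the log-rank table is reported instead and flagged.
#'
#' @param groupA,groupB data.frames with `time` and `event` columns.
#' @return list with `hr`, `ci_low`, `ci_high`, `method`
#'   (`"cox"`/`"mantel-haenszel"`), `defined` (FALSE when there are no
#'   events at all).
#' @export
hazard_ratio <- function(groupA, groupB) {
  assert_that(nrow(groupA) >= 1 && nrow(groupB) >= 1,
              "both groups must be non-empty")
  evA <- sum(groupA$event)
  evB <- sum(groupB$event)
  if (evA + evB == 0) {
    return(list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                method = "none", defined = FALSE))
  }
  df <- rbind(cbind(groupA[, c("time", "event")], group = 1L),
              cbind(groupB[, c("time", "event")], group = 0L))
  separated <- evA == 0 || evB == 0
  if (!separated) {
    fit <- tryCatch(
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ group,
                                       data = df)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      beta <- unname(coef(fit)[1])
      se <- sqrt(fit$var[1, 1])
      if (is.finite(beta) && is.finite(se) && abs(beta) < 15) {
        return(list(hr = exp(beta),
                    ci_low = exp(beta - qnorm(0.975) * se),
                    ci_high = exp(beta + qnorm(0.975) * se),
                    method = "cox", defined = TRUE))
      }
    }
  }
  ## Mantel-Haenszel fallback: (O_A/E_A)/(O_B/E_B) from the log-rank table
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  nm <- names(sd$n) %||% rownames(as.matrix(sd$n))
  grp1 <- which(nm == "group=1")
  if (length(grp1) != 1L) grp1 <- 2L
  O <- sd$obs
  E <- sd$exp
  hr <- (O[grp1] / E[grp1]) / (O[-grp1] / E[-grp1])
  se_log <- sqrt(1 / E[grp1] + 1 / E[-grp1])
  list(hr = unname(hr),
       ci_low = unname(exp(log(pmax(hr, 1e-12)) - qnorm(0.975) * se_log)),
       ci_high = unname(exp(log(pmax(hr, 1e-12)) + qnorm(0.975) * se_log)),
       method = "mantel-haenszel", defined = TRUE)
}

#' Landmark survival comparison between MRD groups
#'
#' Bundles KM curves, log-rank test and hazard ratio for the two MRD
#' groups of an endpoint table from [compute_endpoints()].
#'
#' @param endpoints data.frame with `time`, `event`, `group`.
#' @return list of class `survival_comparison` with `km` (named list of KM
#'   step data), `logrank`, `hazard_ratio` (MRD-positive vs MRD-negative),
#'   `n_per_group`.
#' @export
compare_survival <- function(endpoints) {
  pos <- endpoints[endpoints$group == "MRD-positive", , drop = FALSE]
  neg <- endpoints[endpoints$group == "MRD-negative", , drop = FALSE]
  assert_that(nrow(pos) >= 1 && nrow(neg) >= 1,
              "need patients in both MRD groups")
  structure(list(
    km = list("MRD-positive" = km_estimate(pos),
              "MRD-negative" = km_estimate(neg)),
    logrank = logrank_test(pos, neg),
    hazard_ratio = hazard_ratio(pos, neg),
    n_per_group = c("MRD-positive" = nrow(pos), "MRD-negative" = nrow(neg))
  ), class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  hr <- x$hazard_ratio
  cat(sprintf("Survival comparison (n+ = %d, n- = %d): log-rank chi2 %.3f, p %.4g; HR %.3g [%.3g, %.3g] (%s)\n",
              x$n_per_group[1], x$n_per_group[2], x$logrank$chi2,
              x$logrank$p_value, hr$hr, hr$ci_low, hr$ci_high, hr$method))
  invisible(x)
}

#' Two-group comparison tests
#'
#' Dispatches on input shape: two length-2 count vectors `(positive,
#' negative)` run Fisher's exact test on the 2x2 table; two numeric value
#' vectors run the two-sided Mann-Whitney U test.
#'
#' @param a,b Count pairs or numeric vectors.
#' @param type `"auto"`, `"fisher"` or `"mannwhitney"`.
#' @return list with `p_value` and `method`.
#' @examples
#' compare_groups(c(3, 13), c(11, 8))$method   # fisher
#' @export
compare_groups <- function(a, b, type = c("auto", "fisher", "mannwhitney")) {
  type <- match.arg(type)
  assert_that(length(a) > 0 && length(b) > 0, "empty input")
  if (type == "auto") {
    counts <- length(a) == 2 && length(b) == 2 &&
      all(c(a, b) >= 0) && all(c(a, b) == floor(c(a, b)))
    type <- if (counts) "fisher" else "mannwhitney"
  }
  if (type == "fisher") {
    assert_that(length(a) == 2 && length(b) == 2,
                "fisher requires two (positive, negative) count pairs")
    p <- fisher.test(rbind(a, b))$p.value
    list(p_value = p, method = "fisher")
  } else {
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    list(p_value = p, method = "mannwhitney")
  }
}
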