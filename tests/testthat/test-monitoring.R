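test_that("reporter quantification preserves order and handles zero depth", {
  vars <- data.frame(chrom = "c1", pos = c(5L, 9L, 50L), ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  rs <- make_reporter_set(vars)
  pile <- make_pileup(rep("c1", 2), c(5L, 9L), rep("A", 2),
                      list(list(A = 7998L, T = 2L), list(A = 1000L)))
  m <- quantify_reporters(rs, pile)
  expect_equal(nrow(m), 3L)
  expect_equal(m$pos, vars$pos)                  # order preserved
  ## 2 alt / 8000 -> af 0.025%, detected
  expect_equal(m$af[1], 0.025)
  expect_true(m$detected[1])
  ## 0 alt reads -> not detected
  expect_false(m$detected[2])
  ## reporter absent from pileup -> depth 0, af undefined, not detected
  expect_equal(m$depth[3], 0L)
  expect_true(is.na(m$af[3]))
  expect_false(m$detected[3])
})

test_that("the two-part positivity rule gates on detection AND mean AF", {
  cfg <- run_config()
  vars <- data.frame(chrom = "c1", pos = 1:2, ref = "A", alt = "T")
  rs <- make_reporter_set(vars)
  ## detected AFs 0.02% and 0.04% -> mean 0.03%, positive
  pile <- make_pileup(rep("c1", 2), 1:2, rep("A", 2),
                      list(list(A = 9998L, T = 2L), list(A = 9996L, T = 4L)))
  res <- classify_sample(quantify_reporters(rs, pile), cfg)
  expect_equal(res$mean_af, 0.03)
  expect_true(res$positive)

  ## one detected reporter below the 0.001% mean AF gate -> negative
  pile2 <- make_pileup(rep("c1", 2), 1:2, rep("A", 2),
                       list(list(A = 199999L, T = 1L), list(A = 200000L)))
  res2 <- classify_sample(quantify_reporters(rs, pile2), cfg)
  expect_equal(res2$n_detected, 1L)
  expect_equal(res2$mean_af, 0.0005)
  expect_false(res2$positive)

  ## zero detected -> mean 0, negative (rule a fails)
  pile3 <- make_pileup(rep("c1", 2), 1:2, rep("A", 2),
                       list(list(A = 1000L), list(A = 1000L)))
  res3 <- classify_sample(quantify_reporters(rs, pile3), cfg)
  expect_equal(res3$mean_af, 0)
  expect_false(res3$positive)

  ## single detected reporter: mean AF equals that reporter's AF exactly
  expect_equal(res2$mean_af,
               quantify_reporters(rs, pile2)$af[1])

  ## empty reporter set -> unmonitorable, never positive
  rs0 <- select_reporters(variant_calls(character(0), integer(0), character(0),
                                        character(0), integer(0), integer(0)),
                          patient_id = "P0")
  res0 <- classify_sample(quantify_reporters(rs0, pile), cfg)
  expect_true(res0$unmonitorable)
  expect_false(res0$positive)
})

test_that("positivity is monotone in alt reads and in the mean-AF threshold", {
  vars <- data.frame(chrom = "c1", pos = 1:3, ref = "A", alt = "T")
  rs <- make_reporter_set(vars)
  base_counts <- list(list(A = 5000L), list(A = 4999L, T = 1L), list(A = 5000L))
  classify_at <- function(counts, thr) {
    cfg <- run_config(mrd_mean_af_threshold = thr)
    classify_sample(quantify_reporters(rs, make_pileup(rep("c1", 3), 1:3,
                                                       rep("A", 3), counts)),
                    cfg)$positive
  }
  ## adding alt reads can never flip positive -> negative
  was_positive <- classify_at(base_counts, 0.001)
  more <- base_counts
  more[[3]] <- list(A = 4997L, T = 3L)
  expect_true(classify_at(more, 0.001) >= was_positive)
  ## raising the threshold can never create positives
  thresholds <- c(0.0005, 0.001, 0.01, 0.1)
  pos <- vapply(thresholds, function(t) classify_at(more, t), FALSE)
  expect_true(all(diff(as.integer(pos)) <= 0))
})

test_that("courses derive conversion, sustained positivity and lead time", {
  rec <- list(patient_id = "P20", relapse_day = 226, death_day = NA,
              last_followup_day = 500, stage = "IIB")
  mk <- function(ms, positive, mean_af = if (positive) 0.05 else 0) {
    structure(list(sample_id = ms, milestone = ms,
                   measurements = data.frame(detected = positive),
                   n_detected = as.integer(positive), mean_af = mean_af,
                   positive = positive, unmonitorable = FALSE),
              class = "mrd_result")
  }
  ## negative day 8, positive day 150, relapse 226 -> conversion 150, lead 76
  results <- list(mk("postsurgery", FALSE), mk("followup_1", TRUE))
  course <- assemble_course(results, rec, days = c(8, 150))
  expect_equal(course$conversion_day, 150)
  expect_equal(course$lead_time_days, 76)
  expect_equal(course$landmark_status, "negative")

  ## all negative, no relapse -> conversion and lead time absent
  rec2 <- list(patient_id = "P02", relapse_day = NA, death_day = NA,
               last_followup_day = 500, stage = "IIB")
  course2 <- assemble_course(list(mk("postsurgery", FALSE),
                                  mk("followup_1", FALSE)),
                             rec2, days = c(8, 100))
  expect_true(is.na(course2$conversion_day))
  expect_true(is.na(course2$lead_time_days))

  ## isolated positive surrounded by negatives, no relapse -> flagged
  course3 <- assemble_course(list(mk("postsurgery", FALSE), mk("followup_1", TRUE),
                                  mk("followup_2", FALSE)),
                             rec2, days = c(8, 100, 190))
  expect_equal(course3$suspect_fp_days, 100)

  ## landmark positivity is read from the postsurgery sample
  course4 <- assemble_course(list(mk("postsurgery", TRUE), mk("followup_1", TRUE)),
                             rec, days = c(10, 100))
  expect_equal(course4$landmark_status, "positive")

  ## duplicate days are rejected
  expect_error(assemble_course(list(mk("postsurgery", FALSE),
                                    mk("followup_1", FALSE)),
                               rec, days = c(8, 8)), "duplicate")
})

test_that("detection summaries report numerators, denominators and rates", {
  status <- utils::read.delim(
    system.file("extdata", "synthetic_cohort_status.tsv", package = "mrdtrace"),
    stringsAsFactors = FALSE, na.strings = "")
  courses <- lapply(seq_len(nrow(status)), function(i) {
    r <- status[i, ]
    st <- c(presurgery = r$presurgery, intraoperative = r$intraoperative,
            postsurgery = r$postsurgery)
    patient_course_from_status(r$patient_id, st, stage = r$stage,
                               relapse_day = r$relapse_day,
                               death_day = r$death_day,
                               last_followup_day = r$last_followup_day)
  })
  pre <- cohort_detection_summary(courses, "preresection")
  expect_equal(pre$n_positive, 12L)
  expect_equal(pre$n, 21L)
  expect_equal(pre$rate_pct, 100 * 12 / 21, tolerance = 1e-12)

  ms <- cohort_detection_summary(courses, "milestone")
  expect_equal(ms$n_positive[ms$group == "presurgery"], 3L)
  expect_equal(ms$n[ms$group == "presurgery"], 16L)

  st <- cohort_detection_summary(courses, "stage")
  expect_equal(st$n_positive[st$group == "III"], 7L)
  expect_equal(st$n[st$group == "III"], 10L)

  expect_equal(nrow(cohort_detection_summary(list(), "preresection")), 0L)
})

test_that("high-depth monitoring at 0.1% tumor fraction is nearly always positive", {
  ## binomial cross-check: P(all 10 reporters undetected) = (1-p)^10 with
  ## p = P(Binom(10000, 0.001) >= 1) ~ 1 - e^-10; sensitivity >> 99%
  vars <- data.frame(chrom = "c1", pos = 1:10, ref = "A", alt = "T")
  rs <- make_reporter_set(vars)
  cfg <- run_config()
  hits <- vapply(1:40, function(s) {
    pl <- simulate_reporter_pileup(vars, depth = 10000, seed = 7000 + s,
                                   tumor_fraction = 0.1, residual_error = 0)
    classify_sample(quantify_reporters(rs, pl), cfg)$positive
  }, FALSE)
  expect_true(mean(hits) > 0.99)
})
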