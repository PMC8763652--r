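test_that("endpoint construction measures time from the landmark sample", {
  mk_course <- function(id, landmark_pos, relapse = NA, death = NA, lfu = 800,
                        lday = 10) {
    structure(list(patient_id = id,
                   samples = data.frame(day = lday, milestone = "postsurgery",
                                        n_detected = NA, mean_af = NA,
                                        positive = landmark_pos),
                   landmark_status = ifelse(landmark_pos, "positive", "negative"),
                   conversion_day = NA, lead_time_days = NA,
                   suspect_fp_days = numeric(0), relapse_day = relapse,
                   death_day = death, last_followup_day = lfu, stage = "IIB"),
              class = "patient_course")
  }
  courses <- list(mk_course("P1", TRUE, relapse = 226),
                  mk_course("P2", FALSE),
                  mk_course("P3", FALSE, death = 300))
  cl <- data.frame(patient_id = c("P1", "P2", "P3"))
  pfs <- compute_endpoints(cl, courses, "pfs")
  ## relapse day 226, landmark day 10 -> time 216, event
  expect_equal(pfs$time[pfs$patient_id == "P1"], 216)
  expect_true(pfs$event[pfs$patient_id == "P1"])
  ## no event -> censored at last follow-up
  expect_equal(pfs$time[pfs$patient_id == "P2"], 790)
  expect_false(pfs$event[pfs$patient_id == "P2"])
  ## death without progression is still a PFS event
  expect_true(pfs$event[pfs$patient_id == "P3"])
  os <- compute_endpoints(cl, courses, "os")
  expect_false(os$event[os$patient_id == "P1"])
  expect_true(os$event[os$patient_id == "P3"])
  expect_equal(os$group[os$patient_id == "P1"], "MRD-positive")

  ## label invariance: permuting patients changes nothing but row order
  pfs_perm <- compute_endpoints(cl, courses[c(3, 1, 2)], "pfs")
  expect_equal(pfs_perm[order(pfs_perm$patient_id), ],
               pfs[order(pfs$patient_id), ], ignore_attr = TRUE)
})

test_that("KM estimates match the hand product-limit oracle", {
  ## events at t = 1, 2 in n = 2 -> S(1) = 0.5, S(2) = 0
  km <- km_estimate(data.frame(time = c(1, 2), event = c(TRUE, TRUE)))
  expect_equal(km$surv[km$time == 0], 1)
  expect_equal(km$surv[km$time == 1], 0.5)
  expect_equal(km$surv[km$time == 2], 0)

  ## all censored -> flat at 1
  km2 <- km_estimate(data.frame(time = c(3, 5, 9), event = FALSE))
  expect_true(all(km2$surv == 1))

  ## random <= 10-patient instances vs the brute-force product
  set.seed(77)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    d <- data.frame(time = sample(1:12, n, TRUE),
                    event = sample(c(TRUE, FALSE), n, TRUE))
    km3 <- km_estimate(d)
    oracle <- hand_km(d$time, d$event)
    for (k in seq_len(nrow(oracle))) {
      expect_equal(km3$surv[km3$time == oracle$time[k]], oracle$surv[k])
    }
    ## curves are non-increasing and start at 1
    expect_true(all(diff(km3$surv) <= 1e-12))
    expect_equal(km3$surv[1], 1)
  }
})

test_that("log-rank agrees with symmetry and a permutation oracle", {
  g <- data.frame(time = c(5, 8, 12, 20), event = c(TRUE, TRUE, FALSE, TRUE))
  ## identical groups -> chi2 0, p 1
  lr <- logrank_test(g, g)
  expect_equal(lr$chi2, 0, tolerance = 1e-9)
  expect_equal(lr$p_value, 1, tolerance = 1e-9)

  ## no events anywhere -> undefined, flagged
  none <- data.frame(time = c(5, 8), event = FALSE)
  expect_false(logrank_test(none, none)$defined)

  ## hand-computed observed-minus-expected on a 6-patient instance:
  ## A: 1+, 3+, 5; B: 2, 4, 6  (+ = censored)
  gA <- data.frame(time = c(1, 3, 5), event = c(FALSE, FALSE, TRUE))
  gB <- data.frame(time = c(2, 4, 6), event = c(TRUE, TRUE, TRUE))
  ## event times 2 (n=5, nA=2): E_A += 2/5; t=4 (n=3, nA=1): E_A += 1/3
  ## t=5 (n=2, nA=1): E_A += 1/2; t=6: only B at risk, E_A += 0
  ## O_A = 1, E_A = 2/5 + 1/3 + 1/2 = 1.2333; V = sum of hypergeometric vars
  lr2 <- logrank_test(gA, gB)
  EA <- 2 / 5 + 1 / 3 + 1 / 2
  V <- (2 * 3) / 25 + (1 * 2) / 9 + (1 * 1) / 4
  expect_equal(lr2$chi2, (1 - EA)^2 / V, tolerance = 1e-9)

  ## permutation cross-check on a 10-patient instance
  set.seed(42)
  pA <- data.frame(time = c(2, 4, 6, 9, 15), event = c(T, T, T, F, T))
  pB <- data.frame(time = c(5, 10, 14, 18, 22), event = c(T, F, T, F, F))
  lr3 <- logrank_test(pA, pB)
  p_perm <- permutation_logrank_p(pA, pB, n_perm = 2000, seed = 9)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 2000)
  ## chi-square approximation vs exact permutation: generous but bounded
  expect_lt(abs(lr3$p_value - p_perm), 3 * mc_se + 0.05)
})

test_that("hazard ratios recover the truth and degrade gracefully", {
  ## exchangeable groups -> HR ~ 1
  set.seed(5)
  tt <- rexp(40, 0.1)
  ev <- tt < 15
  tt <- pmin(tt, 15)
  A <- data.frame(time = tt[1:20], event = ev[1:20])
  B <- data.frame(time = tt[21:40], event = ev[21:40])
  hr <- hazard_ratio(A, B)
  expect_equal(hr$method, "cox")
  expect_true(hr$ci_low < 1 && 1 < hr$ci_high)

  ## parameter recovery: true HR 0.1 at n = 200, CI coverage >= 90% of seeds
  cover <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    tA <- rexp(100, 0.02)   # hazard 0.02 (reference scale group A)
    tB <- rexp(100, 0.2)    # group B hazard 10x -> HR(A vs B) = 0.1
    cens <- 60
    dA <- data.frame(time = pmin(tA, cens), event = tA < cens)
    dB <- data.frame(time = pmin(tB, cens), event = tB < cens)
    h <- hazard_ratio(dA, dB)
    h$ci_low <= 0.1 && 0.1 <= h$ci_high
  }, FALSE)
  expect_gte(mean(cover), 0.9)

  ## zero-event group -> Mantel-Haenszel fallback, flagged by method
  Z <- data.frame(time = c(10, 12, 14), event = FALSE)
  E <- data.frame(time = c(2, 3, 4), event = TRUE)
  hz <- hazard_ratio(Z, E)
  expect_equal(hz$method, "mantel-haenszel")
  expect_true(hz$defined)
  ## no events at all -> undefined
  expect_false(hazard_ratio(Z, Z)$defined)
})

test_that("group comparisons match enumeration oracles", {
  ## Fisher [[10,0],[0,10]] -> p = 2 / C(20,10)
  p1 <- compare_groups(c(10, 0), c(0, 10))
  expect_equal(p1$method, "fisher")
  expect_equal(p1$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(p1$p_value, enumerate_fisher(rbind(c(10, 0), c(0, 10))),
               tolerance = 1e-9)

  ## presurgery vs intraoperative detection shape: 3/16 vs 11/19
  tab <- rbind(c(3, 13), c(11, 8))
  p2 <- compare_groups(c(3, 13), c(11, 8))
  expect_equal(p2$p_value, enumerate_fisher(tab), tolerance = 1e-9)

  ## identical samples -> Mann-Whitney two-sided p = 1
  x <- c(1.2, 3.4, 5.6, 7.8)
  p3 <- compare_groups(x, x)
  expect_equal(p3$method, "mannwhitney")
  expect_equal(p3$p_value, 1)

  ## forced method on numeric vectors of length 2
  p4 <- compare_groups(c(0.1, 0.2), c(5.5, 6.5), type = "mannwhitney")
  expect_equal(p4$method, "mannwhitney")
  expect_error(compare_groups(numeric(0), 1:3), "empty")
})

test_that("the cohort pipeline links MRD status to outcome separation", {
  rp <- small_refpanel(territory_bp = 2000)
  bun <- simulate_cohort(55, panel = rp$panel, reference = rp$reference,
                         n_patients = 21, n_donors = 6, tissue_reads = FALSE)
  out <- run_cohort_pipeline(bun)
  expect_equal(length(out$courses), 21L)
  pfs <- out$endpoints$pfs
  expect_equal(nrow(pfs), 21L)
  ## MRD-positive group relapses faster by construction
  if (!is.null(out$comparisons$pfs)) {
    hr <- out$comparisons$pfs$hazard_ratio
    expect_gt(hr$hr, 1)   # hazard of MRD-positive relative to MRD-negative
  }
  ## landmark grouping agrees with the latent truth
  truth_pos <- names(Filter(function(t) t$mrd_positive, bun$truth))
  called_pos <- pfs$patient_id[pfs$group == "MRD-positive"]
  expect_true(all(truth_pos %in% called_pos))
})
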