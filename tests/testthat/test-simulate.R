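test_that("reference/panel simulation is deterministic and hits the territory", {
  rp1 <- simulate_reference_and_panel(1)
  rp2 <- simulate_reference_and_panel(1)
  expect_identical(rp1$reference, rp2$reference)
  expect_identical(rp1$panel$regions, rp2$panel$regions)
  expect_equal(rp1$panel$territory_bp, 17000L)
  expect_equal(length(unique(rp1$panel$regions$gene)), 18L)

  one <- simulate_reference_and_panel(2, n_genes = 1, territory_bp = 100)
  expect_equal(nrow(one$panel$regions), 1L)
  expect_equal(one$panel$territory_bp, 100L)
  expect_error(simulate_reference_and_panel(3, n_genes = 10, territory_bp = 5),
               "smaller than n_genes")
})

test_that("patient profiles respect the panel and requested distributions", {
  rp <- small_refpanel()
  prof <- simulate_patient(1, rp$panel, rp$reference, n_germline = 8)
  all_sites <- rbind(prof$somatic[, c("chrom", "pos")],
                     prof$germline[, c("chrom", "pos")])
  expect_false(anyDuplicated(paste(all_sites$chrom, all_sites$pos)) > 0)
  r <- rp$panel$regions
  inside <- mapply(function(ch, po) {
    any(r$chrom == ch & r$start <= po & po < r$end)
  }, all_sites$chrom, all_sites$pos)
  expect_true(all(inside))
  expect_true(all(prof$somatic$tumor_af > 0 & prof$somatic$tumor_af <= 100))
  expect_true(all(prof$germline$germline_af %in% c(50, 100)))

  ## degenerate AF distribution: Beta(shape1 -> Inf-ish) not needed; exact count
  prof10 <- simulate_patient(2, rp$panel, rp$reference, n_somatic = 10)
  expect_equal(nrow(prof10$somatic), 10L)
  expect_error(simulate_patient(3, rp$panel, rp$reference, n_somatic = 1e6),
               "panel too small")
})

test_that("cohort somatic counts have median ~10 under the default distribution", {
  rp <- simulate_reference_and_panel(4)
  counts <- vapply(1:21, function(i) {
    nrow(simulate_patient(100 + i, rp$panel, rp$reference)$somatic)
  }, 0L)
  expect_true(abs(median(counts) - 10) <= 2)
})

test_that("read simulation is seed-deterministic and honors zero error", {
  rp <- small_refpanel()
  prof <- simulate_patient(1, rp$panel, rp$reference)
  spec0 <- sample_spec("s", tumor_fraction = 0, target_consensus_depth = 4,
                       raw_error_rate = 0, read_length = 50)
  ## tumor_fraction 0 + no germline + no errors -> every read matches reference
  reads <- simulate_sample_reads(prof, spec0, rp$panel, rp$reference,
                                 seed = 5, germline = FALSE)
  refseq <- substring(rp$reference[reads$chrom], reads$start + 1,
                      reads$start + 50)
  expect_identical(reads$seq, unname(refseq))

  spec <- sample_spec("s", target_consensus_depth = 4, read_length = 50)
  r1 <- simulate_sample_reads(prof, spec, rp$panel, rp$reference, seed = 6)
  r2 <- simulate_sample_reads(prof, spec, rp$panel, rp$reference, seed = 6)
  expect_identical(r1, r2)
})

test_that("mutant family counts follow Binomial(depth, af) within 3 SE", {
  rp <- small_refpanel()
  prof <- simulate_patient(2, rp$panel, rp$reference, n_somatic = 4,
                           n_germline = 0)
  prof$somatic$tumor_af <- 30
  depth <- 150
  spec <- sample_spec("s", target_consensus_depth = depth, raw_error_rate = 0,
                      family_size_mean = 3, read_length = 50)
  reads <- simulate_sample_reads(prof, spec, rp$panel, rp$reference, seed = 9)
  truth <- attr(reads, "families")
  ## count mutant families directly from the truth molecules
  n_mut <- vapply(seq_len(nrow(prof$somatic)), function(i) {
    v <- prof$somatic[i, ]
    fam <- truth[truth$chrom == v$chrom & truth$start <= v$pos &
                   v$pos < truth$start + 50, ]
    sum(substring(fam$molecule, v$pos - fam$start + 1,
                  v$pos - fam$start + 1) == v$alt)
  }, 0)
  covering <- vapply(seq_len(nrow(prof$somatic)), function(i) {
    v <- prof$somatic[i, ]
    sum(truth$chrom == v$chrom & truth$start <= v$pos & v$pos < truth$start + 50)
  }, 0)
  p_hat <- sum(n_mut) / sum(covering)
  se <- sqrt(0.3 * 0.7 / sum(covering))
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("reporter pileups recover the spiked AF and leave donors clean", {
  vars <- data.frame(chrom = "c1", pos = 1:20, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  pl <- simulate_reporter_pileup(vars, depth = 10000, seed = 3,
                                 tumor_fraction = 1, residual_error = 0)
  af_hat <- mean(pl$T / pl$depth)
  expect_lt(abs(af_hat - 0.01), 3 * sqrt(0.01 * 0.99 / (10000 * 20)))
  expect_true(all(pl$A + pl$T == pl$depth))

  donor <- simulate_reporter_pileup(vars, depth = 5000, seed = 4,
                                    tumor_fraction = 0, residual_error = 0)
  expect_true(all(donor$T == 0))
  expect_true(all(donor$A == 5000))
})

test_that("spike-in series layout and measured/nominal AF slope ~ 1", {
  rp <- small_refpanel()
  ser <- simulate_spikein_series(rp$panel, rp$reference, seed = 5,
                                 afs = c(5, 1, 0.5, 0.1, 0.01),
                                 replicates = 10, n_variants = 8,
                                 depth = 10000)
  expect_equal(length(ser$samples), 50L)
  expect_equal(nrow(ser$variants), 8L)
  q <- quantify_spikein_series(ser)
  an <- run_spikein_analysis(q)
  expect_lt(abs(an$af_slope - 1), 0.1)

  ## an AF-0 sample contains no variant reads (up to residual error ~ 0)
  ser0 <- simulate_spikein_series(rp$panel, rp$reference, seed = 6,
                                  afs = c(0, 1), replicates = 2,
                                  n_variants = 4, depth = 1000,
                                  residual_error = 0)
  zero <- Filter(function(s) s$nominal_af == 0, ser0$samples)
  for (s in zero) {
    m <- as.matrix(s$pileup[, c("A", "C", "G", "T")])
    alt_reads <- sum(m[cbind(seq_len(4), match(ser0$variants$alt,
                                               c("A", "C", "G", "T")))])
    expect_equal(alt_reads, 0L)
  }
})

test_that("cohort bundles are deterministic, donor-clean, and outcome-linked", {
  rp <- simulate_reference_and_panel(10)
  b1 <- simulate_cohort(20, panel = rp$panel, reference = rp$reference,
                        n_patients = 12, n_donors = 3, tissue_reads = FALSE)
  b2 <- simulate_cohort(20, panel = rp$panel, reference = rp$reference,
                        n_patients = 12, n_donors = 3, tissue_reads = FALSE)
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$plasma, b2$plasma)

  ## byte-identical clinical TSV for the same seed
  t1 <- tempfile(); t2 <- tempfile()
  write_clinical_table(b1$clinical, t1)
  write_clinical_table(b2$clinical, t2)
  expect_identical(readLines(t1), readLines(t2))

  ## donors carry no somatic alleles beyond the residual error process
  for (d in b1$donors) {
    alt_sum <- sum(as.matrix(d[, c("A", "C", "G", "T")])) - sum(d$depth == 0)
    expect_true(all(d$depth == rowSums(as.matrix(d[, c("A", "C", "G", "T")]))))
  }
  ## MRD-positive truth patients relapse with probability 1 by default
  lat <- b1$truth
  mrd_pos <- Filter(function(t) t$mrd_positive, lat)
  if (length(mrd_pos)) {
    expect_true(all(vapply(mrd_pos, function(t) t$relapse, FALSE)))
  }
  ## intraop tumor fraction exceeds presurgical in shedders
  shed <- Filter(function(t) t$shedder, lat)
  expect_true(all(vapply(shed, function(t) t$intraop_tf >= t$presurgery_tf, FALSE)))
  ## configured intraop/presurgery ratio is 4 where both are positive
  both <- Filter(function(t) t$presurgery_tf > 0, shed)
  if (length(both)) {
    ratios <- vapply(both, function(t) t$intraop_tf / t$presurgery_tf, 0)
    expect_equal(unname(ratios), rep(4, length(ratios)))
  }
})

test_that("written cohorts round-trip through the standard formats", {
  rp <- small_refpanel()
  b <- simulate_cohort(30, panel = rp$panel, reference = rp$reference,
                       n_patients = 2, n_donors = 1,
                       params = cohort_params(tissue_depth = 12,
                                              germline_depth = 12,
                                              plasma_depth = 200,
                                              n_germline_snps = 4),
                       tissue_reads = TRUE, out_dir = td <- tempfile())
  expect_true(file.exists(file.path(td, "panel.bed")))
  p2 <- load_panel(file.path(td, "panel.bed"))
  expect_equal(p2$territory_bp, rp$panel$territory_bp)
  ref2 <- load_reference(file.path(td, "reference.fa"), p2)
  expect_identical(ref2, rp$reference)
  cl2 <- read_clinical_table(file.path(td, "clinical.tsv"))
  expect_equal(cl2$patient_id, b$clinical$patient_id)
  sam <- read_sam(file.path(td, "P01_tumor.sam"))
  expect_equal(nrow(sam), nrow(b$tissue_reads$P01$tumor))
  truth <- jsonlite::read_json(file.path(td, "truth.json"))
  expect_equal(length(truth$profiles), 2L)
})
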