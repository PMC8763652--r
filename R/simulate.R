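## Synthetic cohort generator. Two tiers:
##  * read-level (simulate_sample_reads): UMI families with raw sequencing
##    errors, exercising the full dedup path — used at tissue-scale depths;
##  * consensus-pileup-level (simulate_reporter_pileup): per-position
##    consensus counts with binomial tumor molecules and Poisson residual
##    errors — used at the 5,000-10,000x depths of plasma monitoring,
##    spike-in and donor calibration, where the per-family model makes the
##    read-level detour an identity.
## All outputs are pure functions of (arguments, seed).

#' Simulate a reference genome and matching capture panel
#'
#' Builds a deterministic panel layout (for `n_genes = 18` the default
#' 18-gene NSCLC design with its exon labels, merged territory exactly
#' `territory_bp`) and draws random contig sequences.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 18).
#' @param territory_bp Total merged target territory (default 17,000 bp).
#' @return list with `reference` (named character vector) and `panel`
#'   (a [panel_def()]).
#' @export
simulate_reference_and_panel <- function(seed, n_genes = 18,
                                         territory_bp = 17000) {
  layout <- panel_layout(as.integer(n_genes), as.integer(territory_bp))
  panel <- panel_def(layout)
  contig_len <- vapply(split(layout$end, layout$chrom), max, 0) + 100L
  contig_len <- contig_len[unique(layout$chrom)]
  reference <- with_seed(seed, {
    vapply(contig_len, function(n) {
      paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, "")
  })
  names(reference) <- unique(layout$chrom)
  list(reference = reference, panel = panel)
}

#' Simulate one patient's truth profile
#'
#' Draws a somatic SNV profile (count ~ max(1, Poisson(`n_somatic_mean`)),
#' tissue AFs ~ 100 x Beta(`af_shape1`, `af_shape2`), so a majority of
#' variants clear the 18% genotyping threshold) and heterozygous/homozygous
#' germline SNPs, at collision-free panel positions.
#'
#' @param seed Integer seed.
#' @param panel,reference Panel and reference.
#' @param patient_id Identifier.
#' @param n_somatic_mean Mean somatic SNV count (default 10; the cohort
#'   median is then 10).
#' @param n_somatic Optional exact somatic SNV count, overriding the
#'   Poisson draw (used by fixed-design calibration experiments).
#' @param af_shape1,af_shape2 Beta shape parameters for tissue AFs
#'   (default 2, 2).
#' @param n_germline Germline SNP count (default 20).
#' @param stage Optional TNM stage label stored with the profile.
#' @return Object of class `truth_profile`: list with `patient_id`,
#'   `somatic` (chrom, pos, ref, alt, tumor_af), `germline` (chrom, pos,
#'   ref, alt, germline_af in {50, 100}), `stage`.
#' @export
simulate_patient <- function(seed, panel, reference,
                             patient_id = "P01", n_somatic_mean = 10,
                             n_somatic = NULL, af_shape1 = 2, af_shape2 = 2,
                             n_germline = 20, stage = "IIB") {
  with_seed(seed, {
    n_som <- if (!is.null(n_somatic)) as.integer(n_somatic)
             else max(1L, rpois(1, n_somatic_mean))
    all_pos <- panel_positions(panel)
    assert_that(n_som + n_germline <= nrow(all_pos),
                "panel too small: %d positions for %d variants",
                nrow(all_pos), n_som + n_germline)
    idx <- sample.int(nrow(all_pos), n_som + n_germline)
    sites <- all_pos[idx, , drop = FALSE]
    sites$ref <- ref_base_at(reference, sites$chrom, sites$pos)
    sites$alt <- vapply(sites$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, "")
    som <- sites[seq_len(n_som), , drop = FALSE]
    som$tumor_af <- 100 * rbeta(n_som, af_shape1, af_shape2)
    gl <- sites[n_som + seq_len(n_germline), , drop = FALSE]
    gl$germline_af <- sample(c(50, 100), n_germline, replace = TRUE,
                             prob = c(2 / 3, 1 / 3))
    rownames(som) <- rownames(gl) <- NULL
    structure(list(patient_id = patient_id, somatic = som, germline = gl,
                   stage = stage),
              class = "truth_profile")
  })
}

## All 0-based positions inside the panel, as a chrom/pos data.frame.
panel_positions <- function(panel) {
  r <- panel$regions
  do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
    data.frame(chrom = r$chrom[i], pos = seq(r$start[i], r$end[i] - 1L),
               stringsAsFactors = FALSE)
  }))
}

#' Specification of one simulated sample
#'
#' @param sample_id,patient_id,milestone Identifiers.
#' @param tumor_fraction Mean variant AF in the sample, percent (0 for
#'   donors and tumor-free plasma). For tissue samples use `NA`: each
#'   somatic variant then uses its own `tumor_af` from the truth profile.
#' @param target_consensus_depth UMI families per covered position.
#' @param family_size_mean Mean reads per family (shifted Poisson,
#'   `1 + Poisson(mean - 1)`).
#' @param raw_error_rate Substitutions per base per raw read.
#' @param consensus_residual_error Residual specific-alternate errors per
#'   consensus read (pileup tier).
#' @param read_length Read length in bases.
#' @return list of class `sample_spec`.
#' @export
sample_spec <- function(sample_id, patient_id = NA_character_,
                        milestone = NA_character_, tumor_fraction = NA_real_,
                        target_consensus_depth = 100, family_size_mean = 12,
                        raw_error_rate = 1e-3, consensus_residual_error = 1e-6,
                        read_length = 100) {
  assert_that(is.na(tumor_fraction) || tumor_fraction >= 0,
              "tumor_fraction must be >= 0")
  assert_that(target_consensus_depth >= 1, "depth must be >= 1")
  assert_that(family_size_mean >= 1, "family_size_mean must be >= 1")
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 milestone = milestone, tumor_fraction = tumor_fraction,
                 target_consensus_depth = as.integer(target_consensus_depth),
                 family_size_mean = family_size_mean,
                 raw_error_rate = raw_error_rate,
                 consensus_residual_error = consensus_residual_error,
                 read_length = as.integer(read_length)),
            class = "sample_spec")
}

#' Simulate a sample's UMI-tagged reads
#'
#' Physical model matching what UMI consensus assumes: each covered
#' position receives `target_consensus_depth` original molecules
#' (families); a family carries a variant allele with probability
#' `af / 100` (per-variant tissue AF for tissue samples, the sample
#' `tumor_fraction` for plasma; germline SNPs at their germline AF in all
#' patient-derived samples); each family is read `1 + Poisson(mean - 1)`
#' times and raw reads then acquire independent substitution errors at
#' `raw_error_rate`. Reads tile each panel region with fixed-length
#' windows (a shortened step at region ends keeps full coverage); UMIs are
#' unique per family by construction.
#'
#' @param profile A `truth_profile`, or `NULL` for a variant-free donor.
#' @param spec A [sample_spec()].
#' @param panel,reference Panel and reference.
#' @param seed Integer seed.
#' @param germline Include the profile's germline SNPs (default TRUE;
#'   FALSE only makes sense for spike-in-like material).
#' @return data.frame of reads (`read_id`, `chrom`, `start`, `seq`, `umi`)
#'   with attribute `families`: the truth table (`chrom`, `start`, `umi`,
#'   `family_size`, `molecule`) of error-free family sequences.
#' @export
simulate_sample_reads <- function(profile, spec, panel, reference, seed,
                                  germline = TRUE) {
  validate_reference(reference, panel)
  vars <- sample_variant_table(profile, spec, germline)
  with_seed(seed, {
    r <- panel$regions
    L <- spec$read_length
    fam_chunks <- list()
    read_chunks <- list()
    fam_counter <- 0L
    for (i in seq_len(nrow(r))) {
      assert_that(r$end[i] - r$start[i] >= L,
                  "region %s:[%d,%d) shorter than read length %d",
                  r$chrom[i], r$start[i], r$end[i], L)
      starts <- seq(r$start[i], r$end[i] - L, by = L)
      if (max(starts) + L < r$end[i]) starts <- c(starts, r$end[i] - L)
      for (ws in starts) {
        nfam <- spec$target_consensus_depth
        mol <- substring(reference[r$chrom[i]], ws + 1L, ws + L)
        mols <- rep(mol, nfam)
        wv <- vars[vars$chrom == r$chrom[i] & vars$pos >= ws &
                     vars$pos < ws + L, , drop = FALSE]
        for (k in seq_len(nrow(wv))) {
          mut <- runif(nfam) < wv$af[k] / 100
          if (any(mut)) {
            off <- wv$pos[k] - ws + 1L
            substr(mols[mut], off, off) <- wv$alt[k]
          }
        }
        sizes <- 1L + rpois(nfam, spec$family_size_mean - 1)
        umis <- int_to_umi(fam_counter + seq_len(nfam))
        fam_counter <- fam_counter + nfam
        fam_chunks[[length(fam_chunks) + 1L]] <- data.table::data.table(
          chrom = r$chrom[i], start = as.integer(ws), umi = umis,
          family_size = sizes, molecule = mols)
        read_chunks[[length(read_chunks) + 1L]] <- data.table::data.table(
          chrom = r$chrom[i], start = as.integer(ws),
          umi = rep(umis, sizes), seq = rep(mols, sizes))
      }
    }
    fams <- data.table::rbindlist(fam_chunks)
    reads <- data.table::rbindlist(read_chunks)
    ## layer raw sequencing errors on top of the molecule copies
    if (spec$raw_error_rate > 0 && nrow(reads) > 0) {
      n_err <- rbinom(nrow(reads), L, spec$raw_error_rate)
      which_err <- which(n_err > 0)
      for (ri in which_err) {
        ppos <- sample.int(L, n_err[ri])
        s <- reads$seq[ri]
        for (p in ppos) {
          old <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
        reads[ri, seq := s]
      }
    }
    reads[, read_id := sprintf("r%08d", .I)]
    data.table::setcolorder(reads, c("read_id", "chrom", "start", "seq", "umi"))
    out <- as.data.frame(reads)
    attr(out, "families") <- as.data.frame(fams)
    out
  })
}

## The variant table a sample draws alleles from (af in percent).
sample_variant_table <- function(profile, spec, germline = TRUE) {
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), af = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(profile)) return(empty)
  som <- profile$somatic
  som_af <- if (is.na(spec$tumor_fraction)) som$tumor_af
            else rep(spec$tumor_fraction, nrow(som))
  out <- data.frame(chrom = som$chrom, pos = som$pos, ref = som$ref,
                    alt = som$alt, af = som_af, stringsAsFactors = FALSE)
  if (germline && nrow(profile$germline)) {
    gl <- profile$germline
    out <- rbind(out, data.frame(chrom = gl$chrom, pos = gl$pos, ref = gl$ref,
                                 alt = gl$alt, af = gl$germline_af,
                                 stringsAsFactors = FALSE))
  }
  out[out$af > 0, , drop = FALSE]
}

#' Simulate a consensus-level pileup at chosen positions
#'
#' Pileup-tier generator for deep plasma/donor/spike-in samples: at each
#' variant position, true mutant consensus reads ~ Binomial(depth,
#' af / 100) and residual specific-alternate errors ~ Poisson(depth x
#' `residual_error`); the remaining reads carry the reference base.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `af` (percent; overridden by `tumor_fraction` when given).
#' @param depth Consensus depth per position.
#' @param seed Integer seed.
#' @param tumor_fraction Scalar percent AF applied to every variant
#'   (use 0 for donors); `NULL` to use the per-variant `af` column.
#' @param residual_error Specific-alternate errors per consensus read.
#' @return A `locus_pileup` data.frame.
#' @export
simulate_reporter_pileup <- function(variants, depth, seed,
                                     tumor_fraction = NULL,
                                     residual_error = 1e-6) {
  af <- if (!is.null(tumor_fraction)) rep(tumor_fraction, nrow(variants))
        else variants$af %||% rep(0, nrow(variants))
  assert_that(all(af >= 0) && all(af <= 100), "variant AFs must be in [0, 100]")
  with_seed(seed, {
    n <- nrow(variants)
    true_alt <- rbinom(n, depth, af / 100)
    err_alt <- rpois(n, depth * residual_error)
    alt_n <- pmin(depth, true_alt + err_alt)
    out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                      ref = variants$ref,
                      A = 0L, C = 0L, G = 0L, T = 0L,
                      depth = as.integer(depth), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      out[i, variants$alt[i]] <- alt_n[i]
      out[i, variants$ref[i]] <- out[i, variants$ref[i]] + depth - alt_n[i]
    }
    class(out) <- unique(c("locus_pileup", class(out)))
    out
  })
}

#' Simulate a spike-in dilution series
#'
#' One truth profile of `n_variants` SNVs is reused across the whole
#' series; each (nominal AF, replicate) pair becomes an independent
#' consensus pileup at `depth`.
#'
#' @param panel,reference Panel and reference.
#' @param seed Integer seed.
#' @param afs Nominal AFs in percent (default `c(5, 1, 0.5, 0.1, 0.01)`).
#' @param replicates Replicates per AF (default 10).
#' @param n_variants Spiked SNVs (default 8).
#' @param depth Consensus depth (default 10,000).
#' @param residual_error Residual error per consensus read (default 1e-6).
#' @return list with `variants` (the spiked truth set) and `samples`, a
#'   list of `list(nominal_af, replicate, pileup)`.
#' @export
simulate_spikein_series <- function(panel, reference, seed,
                                    afs = c(5, 1, 0.5, 0.1, 0.01),
                                    replicates = 10, n_variants = 8,
                                    depth = 10000, residual_error = 1e-6) {
  assert_that(all(afs >= 0), "nominal AFs must be non-negative")
  prof <- simulate_patient(child_seed(seed, "spikein_profile"), panel,
                           reference, patient_id = "spikein",
                           n_somatic_mean = n_variants, n_germline = 0)
  ## fix the variant count exactly at n_variants for the dilution design
  while (nrow(prof$somatic) < n_variants) {
    extra <- simulate_patient(child_seed(seed, paste0("spikein_extra", nrow(prof$somatic))),
                              panel, reference, n_somatic_mean = n_variants,
                              n_germline = 0)
    new <- extra$somatic[!paste(extra$somatic$chrom, extra$somatic$pos) %in%
                           paste(prof$somatic$chrom, prof$somatic$pos), , drop = FALSE]
    prof$somatic <- rbind(prof$somatic, new)
  }
  prof$somatic <- prof$somatic[seq_len(n_variants), , drop = FALSE]
  samples <- list()
  for (a in afs) {
    for (r in seq_len(replicates)) {
      pl <- simulate_reporter_pileup(
        prof$somatic, depth = depth,
        seed = child_seed(seed, sprintf("spike_%g_%d", a, r)),
        tumor_fraction = a, residual_error = residual_error)
      samples[[length(samples) + 1L]] <- list(nominal_af = a, replicate = r,
                                              pileup = pl)
    }
  }
  list(variants = prof$somatic, samples = samples)
}

#' Cohort generator parameters
#'
#' Defaults encode the study conditions the generator emulates: 21
#' patients (10 stage III), 6 healthy donors; 57% of patients shed
#' detectable ctDNA before resection (70% in stage III, ~45% in stage
#' I--II), presurgery samples positive in a third of shedders,
#' intraoperative tumor fractions 4x presurgical ones, 19% of patients
#' MRD-positive 1--2 weeks postsurgery; every MRD-positive patient
#' relapses, a third of MRD-negative patients relapse; follow-up draws
#' every 90 days out to day 798 (26.2 months).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of parameters.
#' @export
cohort_params <- function(...) {
  p <- list(
    frac_stage3 = 10 / 21,
    p_shedder_stage3 = 0.70,
    p_shedder_stage12 = 0.45,
    p_presurgery_given_shedder = 1 / 3,
    intraop_presurgery_ratio = 4,
    intraop_af_meanlog = log(0.10),   # percent
    intraop_af_sdlog = 0.8,
    p_mrd_positive = 4 / 21,
    postsurgery_af_meanlog = log(0.01),
    postsurgery_af_sdlog = 0.5,
    relapse_prob_mrd_pos = 1.0,
    relapse_prob_mrd_neg = 1 / 3,
    conversion_prob_relapsing_neg = 0.5,
    mrd_pos_relapse_mean_day = 320,
    mrd_neg_relapse_min_day = 300,
    mrd_neg_relapse_max_day = 700,
    death_prob_given_relapse = 0.75,
    death_delay_min = 100,
    death_delay_max = 300,
    followup_interval = 90,
    last_followup_day = 798,
    n_followups = 6,
    day_postsurgery = 10,
    plasma_depth = 5000,
    tissue_depth = 100,
    germline_depth = 100,
    n_germline_snps = 20
  )
  ov <- list(...)
  assert_that(all(names(ov) %in% names(p)), "unknown cohort parameter(s): %s",
              paste(setdiff(names(ov), names(p)), collapse = ", "))
  p[names(ov)] <- ov
  p
}

#' Simulate a full MRD study cohort
#'
#' Generates, per patient: a truth profile, tumor-tissue and germline
#' read-level samples (full dedup path), and plasma consensus pileups at
#' the four milestones (presurgery, intraoperative, postsurgery,
#' follow-ups), with tumor fractions following the study's qualitative
#' pattern (intraoperative > presurgery; postsurgery near zero unless the
#' patient is destined to relapse); plus variant-free donor cfDNA pileups
#' over the union of all patients' somatic positions, a clinical table
#' whose relapse/death outcomes are driven by the latent postsurgical MRD
#' state, and the complete latent truth for recovery tests.
#'
#' @param seed Integer seed.
#' @param panel,reference Panel and reference (defaults: a fresh
#'   `simulate_reference_and_panel(seed)`).
#' @param n_patients,n_donors Cohort sizes (defaults 21 and 6).
#' @param params A [cohort_params()] list.
#' @param config An [run_config()] (error rates, family size).
#' @param tissue_reads If `FALSE`, skip read-level tissue samples and emit
#'   tissue-truth reporter candidates only (fast mode for
#'   monitoring-focused analyses).
#' @param out_dir Optional directory; when given, writes panel BED,
#'   reference FASTA, per-sample SAM files, clinical TSV and truth JSON.
#' @return list of class `mrd_cohort` with `panel`, `reference`,
#'   `profiles`, `clinical`, `samples` (spec table), `tissue_reads`
#'   (per patient: `tumor`, `germline`), `plasma` (per patient: named list
#'   of pileups by milestone), `donors` (pileups), `truth` (latent states).
#' @export
simulate_cohort <- function(seed, panel = NULL, reference = NULL,
                            n_patients = 21, n_donors = 6,
                            params = cohort_params(), config = run_config(),
                            tissue_reads = TRUE, out_dir = NULL) {
  if (is.null(panel) || is.null(reference)) {
    rp <- simulate_reference_and_panel(child_seed(seed, "refpanel"))
    panel <- rp$panel
    reference <- rp$reference
  }
  ids <- sprintf("P%02d", seq_len(n_patients))
  n_st3 <- round(params$frac_stage3 * n_patients)
  stages <- with_seed(child_seed(seed, "stages"), {
    s3 <- sample(c("IIIA", "IIIB"), n_st3, replace = TRUE, prob = c(0.8, 0.2))
    s12 <- sample(c("IA", "IIA", "IIB"), n_patients - n_st3, replace = TRUE,
                  prob = c(0.2, 0.1, 0.7))
    sample(c(s3, s12))
  })

  profiles <- lapply(seq_len(n_patients), function(i) {
    simulate_patient(child_seed(seed, paste0("profile_", ids[i])), panel,
                     reference, patient_id = ids[i],
                     n_germline = params$n_germline_snps, stage = stages[i])
  })
  names(profiles) <- ids

  truth <- with_seed(child_seed(seed, "latent"), {
    lapply(seq_len(n_patients), function(i) {
      st3 <- grepl("^III", stages[i])
      shedder <- runif(1) < if (st3) params$p_shedder_stage3 else params$p_shedder_stage12
      intraop_tf <- if (shedder) rlnorm(1, params$intraop_af_meanlog,
                                        params$intraop_af_sdlog) else 0
      pre_tf <- if (shedder && runif(1) < params$p_presurgery_given_shedder) {
        intraop_tf / params$intraop_presurgery_ratio
      } else 0
      mrd_pos <- runif(1) < params$p_mrd_positive
      post_tf <- if (mrd_pos) rlnorm(1, params$postsurgery_af_meanlog,
                                     params$postsurgery_af_sdlog) else 0
      relapse <- runif(1) < if (mrd_pos) params$relapse_prob_mrd_pos
                            else params$relapse_prob_mrd_neg
      relapse_day <- if (relapse) {
        if (mrd_pos) {
          round(params$day_postsurgery +
                  rlnorm(1, log(params$mrd_pos_relapse_mean_day), 0.3))
        } else {
          round(runif(1, params$mrd_neg_relapse_min_day,
                      params$mrd_neg_relapse_max_day))
        }
      } else NA_real_
      if (!is.na(relapse_day)) {
        relapse_day <- min(relapse_day, params$last_followup_day - 30)
      }
      converts <- relapse && (mrd_pos ||
                                runif(1) < params$conversion_prob_relapsing_neg)
      death_day <- if (relapse && runif(1) < params$death_prob_given_relapse) {
        relapse_day + round(runif(1, params$death_delay_min, params$death_delay_max))
      } else NA_real_
      ## deaths beyond the observation horizon are censored, not observed
      if (!is.na(death_day) && death_day > params$last_followup_day) {
        death_day <- NA_real_
      }
      list(patient_id = ids[i], shedder = shedder, mrd_positive = mrd_pos,
           presurgery_tf = pre_tf, intraop_tf = intraop_tf,
           postsurgery_tf = post_tf, relapse = relapse,
           relapse_day = relapse_day, death_day = death_day,
           converts = converts)
    })
  })
  names(truth) <- ids

  followup_days <- params$day_postsurgery +
    params$followup_interval * seq_len(params$n_followups)
  followup_days <- followup_days[followup_days < params$last_followup_day]

  clinical <- data.frame(
    patient_id = ids, stage = stages,
    resection_status = with_seed(child_seed(seed, "resection"),
                                 sample(c("R0", "R1"), n_patients, TRUE,
                                        prob = c(0.9, 0.1))),
    adjuvant = with_seed(child_seed(seed, "adjuvant"),
                         sample(.adjuvant_levels, n_patients, TRUE,
                                prob = c(10, 9, 2, 2) / 23)),
    relapse_day = vapply(truth, function(t) t$relapse_day, 0),
    death_day = vapply(truth, function(t) t$death_day, 0),
    last_followup_day = params$last_followup_day,
    day_presurgery = -7, day_intraoperative = 0,
    day_postsurgery = params$day_postsurgery,
    stringsAsFactors = FALSE
  )
  ## truncate follow-up at death; keep events <= last_followup_day
  clinical$last_followup_day <- pmin(clinical$last_followup_day,
                                     ifelse(is.na(clinical$death_day),
                                            clinical$last_followup_day,
                                            clinical$death_day))
  for (k in seq_along(followup_days)) {
    clinical[[sprintf("day_followup_%d", k)]] <- followup_days[k]
  }
  clinical <- validate_clinical(clinical)

  tissue <- NULL
  if (isTRUE(tissue_reads)) {
    tissue <- lapply(ids, function(id) {
      tum_spec <- sample_spec(paste0(id, "_tumor"), id, "tumor",
                              tumor_fraction = NA_real_,
                              target_consensus_depth = params$tissue_depth,
                              family_size_mean = config$family_size_mean,
                              raw_error_rate = config$raw_error_rate)
      gl_spec <- sample_spec(paste0(id, "_germline"), id, "germline",
                             tumor_fraction = 0,
                             target_consensus_depth = params$germline_depth,
                             family_size_mean = config$family_size_mean,
                             raw_error_rate = config$raw_error_rate)
      list(
        tumor = simulate_sample_reads(profiles[[id]], tum_spec, panel,
                                      reference,
                                      child_seed(seed, paste0("tumor_", id))),
        germline = simulate_sample_reads(profiles[[id]], gl_spec, panel,
                                         reference,
                                         child_seed(seed, paste0("germline_", id)))
      )
    })
    names(tissue) <- ids
  }

  milestone_tfs <- function(t) {
    tf <- c(presurgery = t$presurgery_tf, intraoperative = t$intraop_tf,
            postsurgery = t$postsurgery_tf)
    for (k in seq_along(followup_days)) {
      d <- followup_days[k]
      tf[sprintf("followup_%d", k)] <- if (!t$relapse || !t$converts) 0
      else {
        ## ctDNA re-emerges ahead of radiographic relapse and grows
        window <- 120
        if (d >= t$relapse_day - window) {
          t$postsurgery_tf + 0.05 * 2^((d - (t$relapse_day - window)) / 60)
        } else if (t$mrd_positive) t$postsurgery_tf else 0
      }
    }
    tf
  }

  plasma <- lapply(ids, function(id) {
    t <- truth[[id]]
    tfs <- milestone_tfs(t)
    keep_days <- c(-7, 0, params$day_postsurgery, followup_days)
    keep <- keep_days <= clinical$last_followup_day[clinical$patient_id == id]
    tfs <- tfs[keep]
    out <- lapply(seq_along(tfs), function(j) {
      simulate_reporter_pileup(
        profiles[[id]]$somatic, depth = params$plasma_depth,
        seed = child_seed(seed, paste0("plasma_", id, "_", names(tfs)[j])),
        tumor_fraction = min(100, tfs[[j]]),
        residual_error = config$consensus_residual_error)
    })
    names(out) <- names(tfs)
    out
  })
  names(plasma) <- ids

  all_somatic <- unique(do.call(rbind, lapply(profiles, `[[`, "somatic"))[,
    c("chrom", "pos", "ref", "alt")])
  donors <- lapply(seq_len(n_donors), function(d) {
    simulate_reporter_pileup(
      all_somatic, depth = params$plasma_depth,
      seed = child_seed(seed, paste0("donor_", d)), tumor_fraction = 0,
      residual_error = config$consensus_residual_error)
  })
  names(donors) <- sprintf("donor_%d", seq_len(n_donors))

  bundle <- structure(list(panel = panel, reference = reference,
                           profiles = profiles, clinical = clinical,
                           truth = truth, tissue_reads = tissue,
                           plasma = plasma, donors = donors,
                           params = params, seed = as.integer(seed)),
                      class = "mrd_cohort")
  if (!is.null(out_dir)) write_cohort(bundle, out_dir)
  bundle
}

#' @export
print.mrd_cohort <- function(x, ...) {
  cat(sprintf("Simulated MRD cohort: %d patients, %d donors, seed %d\n",
              length(x$profiles), length(x$donors), x$seed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits panel BED, reference FASTA, clinical TSV, truth JSON, per-sample
#' SAM files (when tissue reads were simulated) and per-sample plasma/donor
#' pileup TSVs under `out_dir`.
#'
#' @param bundle An `mrd_cohort`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(bundle$panel, file.path(out_dir, "panel.bed"))
  write_reference(bundle$reference, file.path(out_dir, "reference.fa"))
  write_clinical_table(bundle$clinical, file.path(out_dir, "clinical.tsv"))
  truth <- list(
    seed = bundle$seed, params = bundle$params,
    profiles = lapply(bundle$profiles, function(p) {
      list(patient_id = p$patient_id, stage = p$stage, somatic = p$somatic,
           germline = p$germline)
    }),
    latent = bundle$truth
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  if (!is.null(bundle$tissue_reads)) {
    for (id in names(bundle$tissue_reads)) {
      write_sam(bundle$tissue_reads[[id]]$tumor,
                file.path(out_dir, sprintf("%s_tumor.sam", id)),
                bundle$reference)
      write_sam(bundle$tissue_reads[[id]]$germline,
                file.path(out_dir, sprintf("%s_germline.sam", id)),
                bundle$reference)
    }
  }
  for (id in names(bundle$plasma)) {
    for (ms in names(bundle$plasma[[id]])) {
      utils::write.table(bundle$plasma[[id]][[ms]],
                         file.path(out_dir, sprintf("%s_plasma_%s.tsv", id, ms)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (d in names(bundle$donors)) {
    utils::write.table(bundle$donors[[d]],
                       file.path(out_dir, sprintf("%s.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
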