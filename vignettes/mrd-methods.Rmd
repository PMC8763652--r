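---
title: "Methods: tumor-informed ctDNA MRD monitoring with mrdtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-informed ctDNA MRD monitoring with mrdtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdtrace)
options(mrdtrace.quiet = TRUE)
```

## The problem

After curative-intent resection of early-stage or locally advanced NSCLC,
a substantial fraction of patients relapse, and no routine biomarker
identifies them early. Tumor-informed ctDNA assays address this by
genotyping the resected tumor once, selecting a patient-specific set of
somatic SNVs ("reporters"), and then searching for exactly those variants
in serial plasma cell-free DNA. Because plasma tumor fractions after
surgery can sit orders of magnitude below the raw sequencing error rate,
every stage — molecular error suppression, genotyping, plasma calling —
has to be quantitatively calibrated. `mrdtrace` implements that entire
desk-side pipeline together with a generative model of the data it
consumes, so each stage is testable against known truth.

## Error suppression: UMI consensus

Each original cfDNA molecule is tagged with a unique molecular identifier
(UMI) before amplification. All reads sharing `(chrom, aligned start,
UMI)` form a *family* presumed to descend from one molecule. A family is
collapsed to a consensus read under two thresholds, both exposed in
`run_config()`:

* `min_family_size = 10` — families with fewer reads are discarded;
* `consensus_freq = 0.90` — per column, the modal base is emitted only if
  it reaches 90% of the family; otherwise the column becomes `N`.

`N` bases are excluded from downstream pileups on **both** sides of the AF
ratio; this is a deliberate choice (the alternative — counting `N` in the
denominator — deflates AF at noisy columns and would bias the mean-AF
statistic downward). Ties for the modal base resolve to `N`; with the 0.90
default a tie always fails the threshold anyway, the rule just keeps the
function total. Base qualities are not modeled: the consensus rules are
defined on base identity fractions alone. Strand is ignored in the family
key (single-strand UMIs, and the simulator emits no soft-clips); this is
documented on `group_families()` so users bringing real alignments know
the contract.

With the simulator's raw substitution rate of $10^{-3}$ per base and mean
family size 12, a consensus column is wrong (or `N`) only when two or more
raw errors coincide in the same column — probability
$\approx \binom{12}{2} 10^{-6} \approx 7 \times 10^{-5}$ — which the test
suite verifies as a $\ge 10\times$ error-rate reduction relative to raw
reads. The dedup rate is defined as $1 - \text{consensus out} /
\text{reads in}$; at mean family size 12 with no size filter this sits
near $1 - 1/12 \approx 0.92$, matching the high duplication typical of
such libraries.

## Genotyping and reporter selection

Allele frequency is always
$\mathrm{AF} = 100 \cdot \text{alt count} / \text{depth}$ on consensus
reads at a position. Tumor tissue and the matched normal run through the
same dedup path as plasma (the library chemistry is identical), then:

* `min_genotyping_depth = 50` consensus reads for a tissue locus to be
  callable. The paper-style workflow states no depth floor; 50 bounds the
  binomial standard error of an 18%-AF estimate to about 5.4 percentage
  points, which keeps the threshold decision meaningful.
* `germline_af_cutoff = 5`%: any matched-normal evidence at or above 5%
  marks the site constitutional and removes it. A hard "present in
  normal" rule at any AF would let single-read normal artifacts delete
  true somatic reporters.
* `genotyping_af_threshold = 18`% (inclusive): somatic tissue SNVs at or
  above it become reporters. The threshold is applied to the tumor-tissue
  AF (that is where the assay defines it; plasma AFs are far below any
  such cutoff).

Multi-allelic sites yield one call per alternate base, monitored
independently — the monitoring logic is keyed on `(pos, alt)`.

## Plasma monitoring and the positivity rule

`quantify_reporters()` looks up each reporter in the plasma consensus
pileup; a reporter is *detected* with `detection_min_reads = 1` supporting
consensus read (the most literal reading of "detection of at least one
predefined SNV"; configurable). The sample statistic is the arithmetic
mean AF over **detected** reporters only — undetected reporters do not
contribute zeros. A switch (`include_undetected_in_mean`) exposes the
zero-inclusive alternative for sensitivity analyses; it makes the
statistic depend on reporter-set size in a way the detected-only mean does
not. A sample is positive iff at least one reporter is detected **and**
the mean AF is at or above `mrd_mean_af_threshold = 0.001`% (inclusive).

Courses (`assemble_course()`) order samples by day offset from surgery and
derive: the landmark (postsurgical) status used for outcome grouping;
`conversion_day`, the first positive sample after a negative one; and
`lead_time_days`, relapse day minus the first *sustained* positive day,
where sustained means no later negative before relapse. Isolated positives
with a later negative are flagged as suspected false positives rather than
used for lead time — surveillance series do show single spurious positive
draws, and counting them would overstate anticipation.

No minimum plasma depth is imposed for a sample to be evaluable; depth is
reported per reporter so users can filter. Clinical dates are day offsets
from surgery (day 0), never calendar dates — the analyses only use
relative times, and offsets remove format/timezone ambiguity.

## Calibration

The spike-in analysis (`run_spikein_analysis()`) takes a dilution series
(defaults {5, 1, 0.5, 0.1, 0.01}% AF, 8 variants × 10 replicates,
10,000× consensus depth) and reports the *detection floor*: the smallest
nominal AF at which the robustness rule holds. "Robust detection" is
operationalized as **all** variant-replicates detected; a fractional rule
(e.g. ≥ 95%) is selectable since the qualitative criterion admits either
reading. At 10,000× depth the expected per-variant detection probability
is $1 - e^{-10} \approx 0.99995$ at 0.1% AF but only
$1 - e^{-1} \approx 0.63$ at 0.01%, so the floor lands at 0.1% in
essentially every seed — the measured limit of detection, not an assumed
one.

The false-positive matrix (`build_fp_matrix()`) monitors every patient's
reporter set in every healthy-donor cfDNA sample — 21 × 6 = 126 tests at
the default design (each patient-donor pair is one test; this reading
makes the 126 arithmetic exact) — using the *production* quantify/classify
path, never a shortcut model, so calibration cannot drift from the
pipeline it calibrates. With the synthetic residual error of $10^{-6}$
specific-alternate errors per consensus read at 5,000× depth and 10
reporters, the analytic per-test positive probability is
$1 - (1 - (1 - e^{-0.005}))^{10} \approx 0.049$; the simulated matrix
reproduces it within Monte-Carlo error, and sits at the ≈ 5% rate the
thresholds were chosen to achieve. `threshold_grid_search()` selects the
*least stringent* qualifying threshold pair (ordered by mean-AF, then
genotyping threshold): among settings meeting the specificity target, the
smallest thresholds maximize sensitivity.

## Outcomes

Landmark analysis: time zero is the postsurgical blood draw, groups are
the MRD status at that draw. PFS events are the earliest of progression or
death; OS events are death; censoring is at last follow-up. KM estimation,
the one-degree-of-freedom log-rank test, and the Cox hazard ratio come
from the `survival` package; the test suite checks them against
hand-computed product-limit/observed-minus-expected tables and a
permutation null. At MRD cohort sizes (4 vs 12) Cox fits can separate
(zero events in a group); `hazard_ratio()` then falls back to the
Mantel–Haenszel O/E ratio with a log-scale Wald CI and flags the method,
keeping small fixtures total rather than failing. Proportion comparisons
use Fisher's exact test, distribution comparisons the two-sided
Mann–Whitney U test (normal approximation with continuity correction, so
tied and small samples behave identically across inputs). No
multiple-testing correction is applied anywhere.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
emulated study conditions:

| quantity | default | basis |
|---|---|---|
| patients / donors | 21 / 6 | study design |
| panel | 18 genes, 17 kb, 53 exon regions | study design |
| somatic SNVs per patient | Poisson(10), min 1 | median 10 observed |
| tissue AFs | 100·Beta(2,2) | ~91% of variants clear 18% |
| germline SNPs | 20 per patient at 50/100% | ~1/kb heterozygosity |
| family size | 1 + Poisson(11) (mean 12) | makes the size-10 filter meaningful |
| raw error rate | 1e-3 /base | Illumina substitution scale |
| residual consensus error | 1e-6 /read toward a specific alternate | puts the FP calibration at the ~5% regime |
| pre-resection shedders | 70% stage III, 45% stage I–II | observed detection gradient |
| presurgery positive among shedders | 1/3 | 19% vs 57% sample rates |
| intraop/presurgery tumor fraction | ×4 | observed concentration ratio |
| postsurgical MRD prevalence | 4/21 | observed |
| relapse probability | 1.0 if MRD+, 1/3 if MRD− | observed outcome link |
| follow-up horizon | 798 days (26.2 months) | median follow-up |

Two tiers generate data. The **read level**
(`simulate_sample_reads()`) assigns mutation status per family — per
original molecule, exactly the physical model UMI consensus assumes — then
lays raw substitution errors on the copies; it exercises grouping,
consensus and pileup end to end and is used at tissue-scale depths
(~100×). The **consensus-pileup level** (`simulate_reporter_pileup()`)
draws true mutant consensus reads Binomial(depth, AF) and residual errors
Poisson(depth · error) directly; it is used at plasma/calibration depths
of 5,000–10,000×, where the read-level detour would multiply runtime by
the family size for no information — under the per-family model the
two tiers are distributionally identical at the pileup. Donor and
spike-in classification nevertheless always runs through the production
monitoring code path.

What the generator does **not** model — and what passing tests therefore
do not demonstrate about real data: UMI sequencing errors and barcode
collisions, indels, FFPE deamination artifacts, GC/coverage bias,
fragment-length structure, paired-end overlap, contamination between
samples, and clonal evolution (plasma variants outside the reporter set
are never searched for, by design). Results on real alignments with heavy
soft-clipping would additionally stress the position-exact family key.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only at the VCF/SAM text boundary (tested as `BED/internal + 1 =
  VCF POS`). One convention prevents off-by-one drift.
* The bundled default panel is a synthetic stand-in: its gene/exon list
  matches the published design and its merged territory is exactly
  17,000 bp, but the true genomic intervals are not published, so contigs
  are synthetic (one per gene).
* All simulation is a pure function of `(arguments, seed)`; seeds derive
  from a single master seed and stay below $2^{31}$.
* Validation is strict and loud (line- and patient-named errors), never
  silent row skipping — at n = 21, silently dropping one record moves
  detection rates by 5 percentage points.
* Threshold comparisons are inclusive (`>=`) at 18%, 0.001%, family size
  10, and 90% agreement; the boundary cases (11/12 vs 10/12 agreement,
  AF exactly 18%) are pinned by tests.
* Problem sizes in the test suite: grouping oracle ≤ 500 reads; tissue
  end-to-end at 80× on a 2-gene, 800 bp panel; FP calibration at the full
  126-test design over 200 replicates; spike-in at the full 400-sample
  design; HR recovery at n = 200 over 25–30 seeds. These sizes give each
  statistical check ≥ 3-sigma resolution while keeping the default suite
  in minutes on one CPU.

## Known limitations

The cohort-specific survival figures of any single real study (specific
hazard ratios, p values, lead times) depend on individual patient times
that are not public; the package therefore validates its outcome layer by
parameter recovery on simulated cohorts and by oracle equivalence, not by
reproducing per-patient numbers. The printed confidence interval of one
published PFS hazard ratio (0.094 [0.01–0.061]) cannot contain its point
estimate and is presumed a typo; no attempt is made to match it. Stage-
and milestone-specific detection percentages quoted at single-percent
precision can correspond to several possible small-count denominators;
the bundled synthetic stand-in tables realize one consistent choice
(e.g. 5/11 = 45% for stage I–II) and say so in their filenames.
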