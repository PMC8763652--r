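Package: mrdtrace
Title: Tumor-Informed ctDNA Minimal Residual Disease Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for tumor-informed circulating
    tumor DNA (ctDNA) minimal residual disease (MRD) detection over a small
    targeted capture panel, as used in resected non-small-cell lung cancer.
    Implements UMI read-family grouping and error-suppressed consensus
    calling, pileup-based single-nucleotide variant calling with germline
    subtraction and reporter selection at an 18 percent allele-frequency
    threshold, plasma reporter monitoring with a mean allele-frequency
    positivity rule (0.001 percent), assay calibration (spike-in dilution
    detection limit and healthy-donor false-positive matrix with threshold
    grid search), landmark Kaplan-Meier/log-rank/hazard-ratio outcome
    analysis, and a seeded synthetic cohort generator that emulates the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    survival
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
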