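Package: diaq
Title: Post-Processing and Quality Control for Large-Scale DIA (SWATH) Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-processing large data-independent acquisition (SWATH)
    proteomics experiments acquired in batches with interspersed quality-control
    samples. Implements retention-time calibration against spiked iRT standard
    peptides, the four precursor Qvalue filtering policies (sparse, complete,
    percentile, median), robust-sum injection normalization, QC-anchored
    empirical-Bayes (ComBat-style) batch correction with covariates, supervised
    surrogate-variable correction, correlation-based peptide selection with
    geometric protein rollup, CV and batch-clustering diagnostics, and SWATH
    acquisition-scheme design arithmetic (isolation-window tiling, cycle time,
    points per peak, peak capacity, restricted mass-range coverage). A synthetic
    cohort generator with known ground truth emulates a multi-batch,
    QC-interspersed study design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
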