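Package: poolscreen
Title: Pooled-Barcode Viability Screens, Dose-Response and Resistance Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of pooled-barcode cell-line viability
    screens and companion resistance-genomics assays. Implements spike-in
    calibration of per-well fluorescence readouts, control-separability
    quality control, log-viability computation with empirical-Bayes batch
    correction, constrained robust four-parameter logistic dose-response
    fitting with AUC and IC50 summaries, mutation-sensitivity association
    testing, sparse whole-genome copy-number analysis (GC correction,
    mean-normalization, circular binary segmentation, focal-gain calling,
    cohort gain-frequency comparison), excess-over-Bliss synergy scoring of
    dose matrices, z-score drug-perturbation expression signatures with
    consensus integration, and pharmacokinetic-pharmacodynamic exposure
    summaries. A synthetic-data module generates every input with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    pracma,
    IRanges,
    S4Vectors,
    sva,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
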