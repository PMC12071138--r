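Package: csgsa
Title: Comprehensive Serum Glycopeptide Spectra Analysis for Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for serum glycoproteomics-based cancer
    screening: simulation of LC-MS glycopeptide peak lists and tumor-marker
    panels with known ground truth, peak alignment within m/z and retention
    time tolerances, QC-based filtering (coefficient of variation,
    signal-to-noise, isotope/adduct/fragment removal), glycopeptide mass
    annotation by exhaustive peptide-plus-glycan enumeration, single-feature
    biomarker statistics (t-tests, volcano selection, ROC-AUC), fused
    machine-learning classifiers over tumor markers, marker glycopeptides
    and PCA-compressed glycopeptide spectra, the CSGSA score transform, and
    prevalence-corrected screening evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
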