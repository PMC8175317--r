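Package: tauroi
Title: Composite ROI Construction and Diagnostic Accuracy for Tau-PET SUVR Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-tracer tau-PET region-of-interest (ROI) analysis
    from regional standardized uptake value ratio (SUVR) tables: a synthetic
    multi-tracer cohort generator with a latent tau-burden model, theory-driven
    composite ROIs (entorhinal, early tau, temporal and neocortical meta-ROIs),
    data-driven ROI selection combining cross-validated extremely-randomized-trees
    feature importance with hierarchical clustering of regions, ROC/AUC
    estimation with Youden-index cut-points and bootstrap confidence intervals,
    paired DeLong tests for correlated AUCs, and an end-to-end per-tracer
    diagnostic report including a cross-tracer cut-off summary for tau-positivity
    classification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
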