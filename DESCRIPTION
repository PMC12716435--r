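Package: ovascreen
Title: Batch-Effect Auditing for Ovarian Cancer Biomarker Screening Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and auditing blood-based ovarian cancer
    screening classifiers that combine protein biomarkers (CA125, HE4) with
    cell-free DNA copy-number features. Implements the zlog reference-interval
    transformation and its inverse, class-weight-balanced L2-penalised
    logistic regression with repeated stratified cross-validation, a
    batch-confounding audit (single-feature AUCs, ANOVA feature ordering,
    batch composition and leakage flags), scaled-coefficient feature
    importances, clinical operating-point analysis (minimal threshold at a
    specificity floor, sensitivity, PPV under low prevalence, threshold to
    concentration conversion), and a synthetic cohort simulator with a batch
    effect confounded with case status for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
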