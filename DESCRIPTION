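Package: dysglyc
Title: Multiclass Prediction of Inpatient Blood Glucose Decompensation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Event-anchored prediction of inpatient dysglycemia (hypoglycemia
    and three grades of hyperglycemia) from irregular electronic-health-record
    data. Builds look-back windows anchored at the first decompensation event
    of each category, derives per-analyte summary statistics and patient
    history variables, trains a library of gradient-boosted binary classifiers
    over clinically relevant class combinations with inverse-frequency
    instance weights, and assembles them into a second-level error-correcting
    ensemble decoded by minimal Hamming distance with a clinical tie-break
    priority; the ensemble composition is selected by a genetic algorithm
    maximizing macro-averaged precision. Includes a synthetic-cohort generator
    with injected ground-truth events, plausibility-limit cleaning with
    isolation-based outlier flags, and confusion-matrix evaluation with
    k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
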