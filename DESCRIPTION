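Package: amlrec
Title: Outcome Prediction and Therapy-Intensity Recommendation for Acute
    Myeloid Leukemia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multimodal decision-support pipeline for Acute Myeloid
    Leukemia (AML) cohorts. Reads linked clinical, gene-mutation and
    gene-expression tables; applies adult-AML cleaning filters and
    k-nearest-neighbour imputation; selects features per modality
    (expert clinical list, L1-penalised linear model for expression,
    chi-square independence tests for mutations); trains random-forest,
    logistic-regression and support-vector-machine outcome classifiers
    with a grid search under hold-out validation; fuses the best model
    per modality into a classifier committee whose votes are weighted by
    validation F1-score; and recommends, per patient, the
    treatment-intensity protocol that maximises the committee's predicted
    survival probability via a counterfactual sweep. Includes a synthetic
    cohort generator with known ground-truth optimal protocols so every
    stage can be tested without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
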