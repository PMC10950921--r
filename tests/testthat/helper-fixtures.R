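# Shared fixtures: all built in code, deterministic given their seed.

# A tiny hand-writable cohort with known values.
tiny_cohort <- function(n = 3, ids = sprintf("P%02d", seq_len(n))) {
  clin <- data.frame(
    patient_id = ids,
    diagnosis_age = seq(30, by = 5, length.out = n),
    bm_blast_pct = rep(50, n),
    mutation_count = rep(5, n),
    pb_blast_pct = rep(30, n),
    wbc = rep(20, n),
    gender = rep(c("male", "female"), length.out = n),
    is_white = rep(1, n),
    cytogenetic_group = rep("normal_karyotype", n),
    eln_risk = rep("intermediate", n),
    treatment_intensity = rep("regular", n),
    overall_survival_status = rep(c("living", "deceased"), length.out = n),
    stringsAsFactors = FALSE)
  mut <- data.frame(patient_id = ids, TP53 = rep(0, n), SRSF2 = rep(1, n),
                    stringsAsFactors = FALSE)
  expr <- data.frame(patient_id = ids, MX1 = seq_len(n) / 2,
                     XIST = -seq_len(n), stringsAsFactors = FALSE)
  aml_cohort(clin, mut, expr)
}

# Compact grid used where the grid contents are not themselves under test.
small_grid <- function() {
  hyperparameter_grid(
    random_forest = list(n_estimators = 50, min_samples_leaf = 4,
                         max_depth = 10, class_weight = c("balanced", "none")),
    logistic_regression = list(C = c(1.77e-1, 10),
                               class_weight = c("balanced", "none")),
    svm = list(kernel = c("linear", "rbf"), C = 1e-2,
               class_weight = c("balanced", "none")))
}

# Study conditions for the ensemble-benefit experiment: three modalities of
# comparable, independent signal so every individual model is informative.
benefit_config <- function(seed) {
  generator_config(
    n_patients = 2000, seed = seed,
    outcome_model = list(
      intercept = 0, age = 0.8, bm_blast = 0.35, log_wbc = 0.55,
      eln = c(favorable = -0.8, intermediate = 0, adverse = 0.8),
      beta_expression = stats::setNames(
        c(rep(0.62, 3), rep(-0.62, 3), rep(0, 16)), aml_expression_panel()),
      beta_mutation = stats::setNames(rep(c(1.1, -1.1), 5),
                                      aml_mutation_panel()),
      mutation_prevalence = stats::setNames(rep(0.3, 10),
                                            aml_mutation_panel()),
      interaction_age = 0.5))
}

# Study conditions for recommendation recovery: genetic effects damped so
# the clinical model sees the treatment-by-age interaction clearly.
recovery_config <- function(strength, seed, n = 800) {
  generator_config(
    n_patients = n, seed = seed,
    outcome_model = list(
      beta_expression = stats::setNames(rep(c(0.15, -0.15), 11),
                                        aml_expression_panel()),
      beta_mutation = stats::setNames(rep(c(0.25, -0.25), 5),
                                      aml_mutation_panel()),
      interaction_age = strength))
}

# Train a clinical-only random-forest committee on one recovery cohort.
train_clinical_committee <- function(cohort, seed) {
  grid1 <- hyperparameter_grid(random_forest = list(
    n_estimators = 50, min_samples_leaf = 4, max_depth = NA,
    class_weight = "none"))
  sp <- split_holdout(cohort, split_spec(seed = seed))
  m <- train_with_grid(
    "random_forest", "clinical",
    subset_cohort(cohort, which(sp$labels != "validation")),
    subset_cohort(cohort, which(sp$labels == "validation")),
    setdiff(aml_clinical_panel(), "overall_survival_status"),
    grid = grid1, seed = seed)
  build_committee(list(m))
}
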