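test_that("hold-out fold sizes follow the ceiling convention", {
  sp <- split_holdout(272, split_spec(seed = 1))
  expect_equal(sum(sp$labels == "test"), 28)
  expect_equal(sum(sp$labels == "validation"), 28)
  expect_equal(sum(sp$labels == "feature_select"), 28)
  # models are fitted on training + feature-selection records
  expect_equal(sum(sp$labels %in% c("train", "feature_select")), 216)

  sp10 <- split_holdout(10, split_spec(seed = 2))
  expect_equal(as.vector(table(sp10$labels)[c("feature_select",
                                              "validation", "test")]),
               c(1, 1, 1))
  expect_equal(sum(sp10$labels == "train"), 7)
  expect_error(split_holdout(9), "at least 10")
})

test_that("splits are deterministic in the seed and exhaustive for any n", {
  a <- split_holdout(101, split_spec(seed = 7))
  b <- split_holdout(101, split_spec(seed = 7))
  c <- split_holdout(101, split_spec(seed = 8))
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, c$labels))
  set.seed(55)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    sp <- split_holdout(n, split_spec(seed = i))
    expect_length(sp$labels, n)
    expect_true(all(sp$labels %in% c("train", "feature_select",
                                     "validation", "test")))
    expect_equal(sum(sp$labels == "test"), ceiling(0.1 * n))
  }
})

test_that("merging validation into training implements the 9:1 scheme", {
  sp <- split_holdout(272, split_spec(seed = 3,
                                      merge_validation_into_train = TRUE))
  expect_equal(sum(sp$labels == "test"), 28)
  expect_false("validation" %in% sp$labels)
  expect_equal(sum(sp$labels == "train"), 272 - 28 - 28)
})

test_that("grid search evaluates the full grid and a 1-point grid returns it", {
  co <- generate_cohort(generator_config(n_patients = 120, seed = 31))$cohort
  sp <- split_holdout(co, split_spec(seed = 31))
  tr <- subset_cohort(co, which(sp$labels %in% c("train", "feature_select")))
  va <- subset_cohort(co, which(sp$labels == "validation"))
  feats <- setdiff(aml_clinical_panel(), "overall_survival_status")

  g1 <- hyperparameter_grid(logistic_regression = list(C = 10,
                                                       class_weight = "none"))
  m1 <- train_with_grid("logistic_regression", "clinical", tr, va, feats,
                        grid = g1, seed = 31)
  expect_equal(m1$n_evaluated, 1)
  expect_equal(m1$hyperparameters$C, 10)

  g <- hyperparameter_grid()
  expect_equal(prod(lengths(g$random_forest)), 7 * 4 * 3 * 2)
  m <- train_with_grid("svm", "clinical", tr, va, feats, grid = g, seed = 31)
  expect_equal(m$n_evaluated, prod(lengths(g$svm)))
  expect_true(m$hyperparameters$kernel %in% g$svm$kernel)
  expect_true(m$hyperparameters$C %in% g$svm$C)
  expect_gte(m$validation_f1, 0)
  expect_lte(m$validation_f1, 1)
})

test_that("a linearly separable modality reaches validation F1 = 1", {
  co <- generate_cohort(generator_config(n_patients = 100, seed = 17))$cohort
  # plant perfect separation in one expression gene
  g1 <- co$panels$expression[1]
  y <- co$clinical$overall_survival_status
  co$expression[[g1]] <- ifelse(y == "living", 3, -3) + rnorm(100, 0, 0.1)
  sp <- split_holdout(co, split_spec(seed = 17))
  tr <- subset_cohort(co, which(sp$labels %in% c("train", "feature_select")))
  va <- subset_cohort(co, which(sp$labels == "validation"))
  f1s <- vapply(c("random_forest", "logistic_regression", "svm"),
                function(me) {
    train_with_grid(me, "expression", tr, va, co$panels$expression,
                    grid = small_grid(), seed = 17)$validation_f1
  }, numeric(1))
  expect_true(any(f1s == 1))

  m <- train_with_grid("svm", "expression", tr, va, co$panels$expression,
                       grid = small_grid(), seed = 17)
  te <- subset_cohort(co, which(sp$labels == "test"))
  pred <- predict_outcome(m, te)
  expect_true(all(pred$survive_probability >= 0 &
                    pred$survive_probability <= 1))
  liv <- pred$survive_probability[te$clinical$overall_survival_status ==
                                    "living"]
  expect_true(all(liv > 0.9))
})

test_that("single-class training folds are rejected with a re-split hint", {
  co <- tiny_cohort(12)
  co$clinical$overall_survival_status <- "living"
  expect_error(
    train_with_grid("svm", "clinical", subset_cohort(co, 1:9),
                    subset_cohort(co, 10:12),
                    setdiff(aml_clinical_panel(), "overall_survival_status"),
                    seed = 1),
    "re-split")
})

test_that("prediction on a cohort missing a model feature names it", {
  co <- generate_cohort(generator_config(n_patients = 60, seed = 23))$cohort
  sp <- split_holdout(co, split_spec(seed = 23))
  tr <- subset_cohort(co, which(sp$labels != "test"))
  te <- subset_cohort(co, which(sp$labels == "test"))
  m <- train_with_grid("logistic_regression", "mutation", tr, te,
                       co$panels$mutation, grid = small_grid(), seed = 23)
  te$mutation$TP53 <- NULL
  expect_error(predict_outcome(m, te), "TP53")
})

test_that("best-per-modality selection follows F1 then method-order ties", {
  stub <- function(modality, method, f1) {
    structure(list(modality = modality, method = method, validation_f1 = f1),
              class = "aml_model")
  }
  models <- list(
    stub("clinical", "random_forest", 0.6562),
    stub("clinical", "svm", 0.6713),
    stub("clinical", "logistic_regression", 0.7044),
    stub("mutation", "random_forest", 0.7129),
    stub("mutation", "svm", 0.4807),
    stub("mutation", "logistic_regression", 0.7129),
    stub("expression", "random_forest", 0.7803),
    stub("expression", "svm", 0.6284),
    stub("expression", "logistic_regression", 0.6200))
  best <- select_best_per_modality(models)
  expect_equal(best$clinical$method, "logistic_regression")
  expect_equal(best$expression$method, "random_forest")
  expect_equal(best$expression$validation_f1, 0.7803)
  # exact F1 tie within the mutation modality goes to the random forest
  expect_equal(best$mutation$method, "random_forest")
  # single model per modality is returned as-is
  one <- select_best_per_modality(models[7])
  expect_identical(one$expression, models[[7]])
})

test_that("pure-noise modalities do not beat the majority baseline materially", {
  # no-signal sanity: with outcome decoupled from every feature, the best
  # validation F1 stays near the majority-class level
  f1_gap <- vapply(1:12, function(s) {
    cfg <- generator_config(
      n_patients = 150, seed = s,
      outcome_model = list(
        age = 0, bm_blast = 0, log_wbc = 0,
        eln = c(favorable = 0, intermediate = 0, adverse = 0),
        protocol = c(target = 0, regular = 0, low_intensity = 0,
                     high_intensity = 0),
        beta_expression = stats::setNames(rep(0, 22),
                                          aml_expression_panel()),
        beta_mutation = stats::setNames(rep(0, 10), aml_mutation_panel()),
        interaction_age = 0))
    co <- generate_cohort(cfg)$cohort
    sp <- split_holdout(co, split_spec(seed = s))
    tr <- subset_cohort(co, which(sp$labels %in% c("train",
                                                   "feature_select")))
    va <- subset_cohort(co, which(sp$labels == "validation"))
    y_va <- va$clinical$overall_survival_status
    maj <- names(which.max(table(tr$clinical$overall_survival_status)))
    base <- metrics_from_confusion(confusion(y_va, rep(maj, length(y_va))))
    m <- train_with_grid("logistic_regression", "clinical", tr, va,
                         setdiff(aml_clinical_panel(),
                                 "overall_survival_status"),
                         grid = small_grid(), seed = s)
    m$validation_f1 - base$weighted[["f1"]]
  }, numeric(1))
  # mean gap over seeds within 3 standard errors of zero (one-sided check:
  # selection makes small positive gaps expected; large ones indicate leakage)
  expect_lt(mean(f1_gap), 3 * sd(f1_gap) / sqrt(length(f1_gap)) + 0.05)
})
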