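make_clin_cohort <- function(clin) {
  n <- nrow(clin)
  mut <- data.frame(patient_id = clin$patient_id, TP53 = rep(1, n),
                    stringsAsFactors = FALSE)
  expr <- data.frame(patient_id = clin$patient_id, MX1 = rep(0, n),
                     stringsAsFactors = FALSE)
  aml_cohort(clin, mut, expr)
}

test_that("adult-AML filter keeps the inclusive 18-year and 20%-blast boundaries", {
  co <- tiny_cohort(3)
  co$clinical$diagnosis_age <- c(17, 18, 40)
  r <- filter_adult_aml(co)
  expect_identical(r$cohort$clinical$diagnosis_age, c(18, 40))

  co2 <- tiny_cohort(3)
  co2$clinical$bm_blast_pct <- c(19.9, 20, 80)
  r2 <- filter_adult_aml(co2)
  expect_identical(r2$cohort$clinical$bm_blast_pct, c(20, 80))
  expect_identical(r2$report$removed_ids$low_bm_blast, "P01")
})

test_that("records missing age or blast are removed by the adult-AML rule", {
  co <- tiny_cohort(4)
  co$clinical$diagnosis_age[2] <- NA
  co$clinical$bm_blast_pct[3] <- NA
  r <- filter_adult_aml(co)
  expect_equal(n_patients(r$cohort), 2)
  expect_equal(sum(r$report$n_removed_per_rule), 2)
})

test_that("missing-survival filter removes only unlabelled records", {
  co <- tiny_cohort(4)
  expect_equal(n_patients(filter_missing_survival(co)$cohort), 4)
  co$clinical$overall_survival_status[2] <- NA
  r <- filter_missing_survival(co)
  expect_equal(n_patients(r$cohort), 3)
  expect_identical(r$report$removed_ids$missing_survival, "P02")
})

test_that("deduplication keeps the marrow de-novo sample and first record per patient", {
  clin <- tiny_cohort(4)$clinical
  clin$patient_id <- c("A", "A", "B", "C")
  clin$sample_site <- c("bone_marrow_aspirate", "peripheral_blood",
                        "bone_marrow_aspirate", "bone_marrow_aspirate")
  clin$sample_timepoint <- c("de_novo", "de_novo", "relapse", "de_novo")
  clin$diagnosis_age <- c(40, 41, 42, 43)
  co <- make_clin_cohort(clin)
  r <- deduplicate_samples(co)
  expect_identical(r$cohort$clinical$patient_id, c("A", "C"))
  expect_equal(r$cohort$clinical$diagnosis_age[1], 40) # first kept
  expect_identical(r$report$removed_ids$wrong_timepoint, "B")
})

test_that("deduplication is vacuous, with a notice, when metadata are absent", {
  co <- tiny_cohort(3)
  r <- deduplicate_samples(co)
  expect_equal(n_patients(r$cohort), 3)
  expect_length(r$report$notes, 2)
})

test_that("race binarisation maps white to 1, everything else to 0, NA to NA", {
  clin <- tiny_cohort(3)$clinical
  clin$is_white <- NULL
  clin$race <- c("White", "asian", NA)
  co <- binarize_race(make_clin_cohort(clin))
  expect_identical(co$clinical$is_white, c(1, 0, NA_real_))
  expect_false("race" %in% names(co$clinical))
})

test_that("never-mutated genes are pruned from the panel", {
  co <- tiny_cohort(3)
  co$mutation$TP53 <- c(0, 0, 0)
  r <- prune_empty_mutation_genes(co)
  expect_identical(r$dropped, "TP53")
  expect_identical(r$cohort$panels$mutation, "SRSF2")
})

test_that("knn imputation fills a numeric hole with the neighbour mean", {
  clin <- tiny_cohort(4)$clinical
  # donors identical to the target in every predictor: all equidistant,
  # stable order picks the first three
  clin$diagnosis_age <- 50
  clin$gender <- "male"
  clin$overall_survival_status <- "living"
  clin$wbc <- c(NA, 10, 20, 30)
  co <- impute_knn(make_clin_cohort(clin))
  expect_equal(co$clinical$wbc[1], 20)
})

test_that("knn imputation fills a categorical hole with the neighbour majority", {
  clin <- tiny_cohort(5)$clinical
  clin$gender <- c(NA, "male", "male", "female", "female")
  clin$overall_survival_status <- "living"
  # ages force the neighbour order: two males and one female nearest
  clin$diagnosis_age <- c(50, 50, 50, 51, 90)
  clin$wbc <- 20
  co <- impute_knn(make_clin_cohort(clin))
  expect_identical(co$clinical$gender[1], "male")
})

test_that("imputation of a binary indicator stays binary", {
  clin <- tiny_cohort(5)$clinical
  clin$is_white <- c(NA, 1, 1, 0, 1)
  co <- impute_knn(make_clin_cohort(clin))
  expect_true(co$clinical$is_white[1] %in% c(0, 1))
})

test_that("imputation errors when fewer than k records observe the target", {
  clin <- tiny_cohort(4)$clinical
  clin$wbc <- c(NA, NA, 10, 20)
  expect_error(impute_knn(make_clin_cohort(clin)), "wbc")
})

test_that("filters are idempotent and the composite never adds missingness", {
  co <- generate_cohort(generator_config(n_patients = 60, seed = 21))$cohort
  co <- inject_missingness(co, 0.08, seed = 4)
  once <- filter_adult_aml(co)$cohort
  twice <- filter_adult_aml(once)$cohort
  expect_identical(twice$clinical, once$clinical)
  once_s <- filter_missing_survival(co)$cohort
  expect_identical(filter_missing_survival(once_s)$cohort$clinical,
                   once_s$clinical)

  res <- preprocess_cohort(co)
  expect_lte(n_patients(res$cohort), n_patients(co))
  expect_false(anyNA(res$cohort$clinical))
  expect_equal(nrow(validate_cohort(res$cohort)), 0)
})

test_that("the dirty fixture is cleaned exactly as its manifest says", {
  dirty <- make_dirty_fixture(seed = 42)
  man <- attr(dirty, "manifest")
  res <- preprocess_cohort(dirty)
  expect_equal(n_patients(res$cohort), man$n_clean)
  expect_equal(man$n_input, 21L)
})

test_that("dirty-fixture removals are attributed to the first-triggering rule", {
  dirty <- make_dirty_fixture(seed = 42)
  man <- attr(dirty, "manifest")
  res <- preprocess_cohort(dirty)
  got_adult <- unlist(res$reports$adult_aml$removed_ids, use.names = FALSE)
  expect_setequal(got_adult, man$expected_removed$adult_aml)
  expect_setequal(
    unlist(res$reports$missing_survival$removed_ids, use.names = FALSE),
    man$expected_removed$missing_survival)
  expect_setequal(
    unlist(res$reports$deduplicate$removed_ids, use.names = FALSE),
    man$expected_removed$deduplicate)
  # the double violator (underage AND missing survival) appears only under
  # the adult-AML rule
  dbl <- intersect(man$expected_removed$adult_aml, "SYN-0004")
  expect_length(dbl, 1)
  expect_false(dbl %in%
    unlist(res$reports$missing_survival$removed_ids, use.names = FALSE))
})
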