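test_that("write then read is the identity on valid cohorts", {
  for (seed in c(3, 17)) {
    co <- generate_cohort(generator_config(n_patients = 25, seed = seed,
                                           n_decoy_expression = 4,
                                           n_decoy_mutation = 2))$cohort
    dir <- withr::local_tempdir()
    paths <- write_cohort(co, dir)
    co2 <- read_cohort(paths["clinical"], paths["mutation"],
                       paths["expression"])
    expect_identical(co2$clinical, co$clinical)
    expect_identical(co2$mutation, co$mutation)
    expect_identical(co2$expression, co$expression)
    expect_identical(co2$panels, co$panels)
  }
})

test_that("an empty cohort writes three header-only files", {
  co <- subset_cohort(tiny_cohort(), integer(0))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  for (p in paths) expect_length(readLines(p), 1L)
})

test_that("a full-size cohort writes one data row per patient", {
  co <- generate_cohort(generator_config(seed = 5))$cohort
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  for (p in paths) expect_length(readLines(p), 272L + 1L)
})

test_that("patients missing from a genetic table are kept and NA-flagged", {
  co <- tiny_cohort(2, ids = c("A", "B"))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  # drop patient B from the mutation table on disk
  mut <- read.delim(paths["mutation"])
  write.table(mut[mut$patient_id == "A", ], paths["mutation"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  co2 <- read_cohort(paths["clinical"], paths["mutation"],
                     paths["expression"])
  expect_equal(n_patients(co2), 2)
  b <- co2$mutation[co2$mutation$patient_id == "B", ]
  expect_true(all(is.na(b[, co2$panels$mutation])))
  expect_identical(co2$provenance$unmatched$mutation, "B")
})

test_that("missing markers map to NA and labels are normalised at load", {
  dir <- withr::local_tempdir()
  writeLines(c("Patient ID\tDiagnosis Age\tWBC\tGender\tOverall Survival Status",
               "A\t44\tn/a\tMale\tLIVING",
               "B\t\t12.5\tFEMALE\t1:DECEASED"),
             file.path(dir, "clin.tsv"))
  writeLines(c("patient_id\tTP53", "A\t1", "B\t0"),
             file.path(dir, "mut.tsv"))
  writeLines(c("patient_id\tMX1", "A\t0.5", "B\t-1"),
             file.path(dir, "expr.tsv"))
  co <- read_cohort(file.path(dir, "clin.tsv"), file.path(dir, "mut.tsv"),
                    file.path(dir, "expr.tsv"))
  expect_true(is.na(co$clinical$wbc[1]))
  expect_true(is.na(co$clinical$diagnosis_age[2]))
  expect_identical(co$clinical$gender, c("male", "female"))
  expect_identical(co$clinical$overall_survival_status,
                   c("living", "deceased"))
  expect_identical(co$panels$mutation, "TP53")
})

test_that("parse and schema errors name the offending cell or header", {
  dir <- withr::local_tempdir()
  writeLines(c("patient_id\twbc\twbc", "A\t1\t2"), file.path(dir, "dup.tsv"))
  writeLines(c("patient_id\twbc", "A\ttwelve"), file.path(dir, "bad.tsv"))
  writeLines(c("patient_id\tTP53", "A\t1"), file.path(dir, "mut.tsv"))
  writeLines(c("patient_id\tMX1", "A\t0.5"), file.path(dir, "expr.tsv"))
  expect_error(read_cohort(file.path(dir, "dup.tsv"), file.path(dir, "mut.tsv"),
                           file.path(dir, "expr.tsv")),
               "duplicate header")
  err <- expect_error(
    read_cohort(file.path(dir, "bad.tsv"), file.path(dir, "mut.tsv"),
                file.path(dir, "expr.tsv")))
  expect_match(conditionMessage(err), "wbc")
  expect_match(conditionMessage(err), "row 1")
})

test_that("genes-in-rows orientation transposes genetic tables", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort(2, ids = c("A", "B"))
  paths <- write_cohort(co, dir)
  # rewrite expression/mutation transposed
  for (nm in c("mutation", "expression")) {
    tab <- co[[nm]]
    genes <- setdiff(names(tab), "patient_id")
    t_tab <- cbind(data.frame(gene = genes),
                   as.data.frame(t(tab[, genes, drop = FALSE])))
    names(t_tab) <- c("gene", tab$patient_id)
    write.table(t_tab, paths[[nm]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  co2 <- read_cohort(paths["clinical"], paths["mutation"],
                     paths["expression"], orientation = "genes_in_rows")
  expect_equal(co2$mutation, co$mutation)
  expect_equal(co2$expression, co$expression)
})

test_that("validate_cohort is empty on valid cohorts and flags each planted violation once", {
  co <- generate_cohort(generator_config(n_patients = 30, seed = 9))$cohort
  expect_equal(nrow(validate_cohort(co)), 0)

  inject <- list(
    out_of_range = function(c) {
      c$clinical$bm_blast_pct[4] <- 120; c
    },
    out_of_range_pb = function(c) {
      c$clinical$pb_blast_pct[2] <- -3; c
    },
    unknown_category = function(c) {
      c$clinical$eln_risk[1] <- "unheard_of"; c
    },
    unknown_protocol = function(c) {
      c$clinical$treatment_intensity[7] <- "experimental"; c
    },
    non_binary_mutation = function(c) {
      c$mutation[[c$panels$mutation[1]]][5] <- 2; c
    },
    duplicate_id = function(c) {
      c$clinical$patient_id[2] <- c$clinical$patient_id[1]
      c$mutation$patient_id[2] <- c$mutation$patient_id[1]
      c$expression$patient_id[2] <- c$expression$patient_id[1]
      c
    })
  for (nm in names(inject)) {
    v <- validate_cohort(inject[[nm]](co))
    expect_equal(nrow(v), 1, info = nm)
  }
})
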