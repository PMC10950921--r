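#' Cleaning report
#'
#' Bookkeeping for one cleaning step: input count, ids removed per rule
#' (a record failing several rules is attributed to the first-triggering
#' rule only), output count, and free-text notes.
#'
#' @param n_input,n_output record counts before/after.
#' @param removed named list: rule name -> character vector of removed ids.
#' @param notes character vector of notices (e.g. vacuous filters).
#' @return object of class `aml_cleaning_report`.
#' @export
cleaning_report <- function(n_input, removed = list(), n_output = NULL,
                            notes = character()) {
  n_removed <- vapply(removed, length, integer(1))
  if (is.null(n_output)) n_output <- n_input - sum(n_removed)
  stopifnot(n_input - sum(n_removed) == n_output)
  structure(list(n_input = n_input,
                 n_removed_per_rule = n_removed,
                 removed_ids = removed,
                 n_output = n_output,
                 notes = notes),
            class = "aml_cleaning_report")
}

#' @export
print.aml_cleaning_report <- function(x, ...) {
  cat("Cleaning report:", x$n_input, "->", x$n_output, "records\n")
  for (rule in names(x$removed_ids)) {
    cat(sprintf("  %-20s -%d\n", rule, length(x$removed_ids[[rule]])))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

.drop_records <- function(cohort, drop_idx) {
  if (!length(drop_idx)) return(cohort)
  subset_cohort(cohort, setdiff(seq_len(n_patients(cohort)), drop_idx))
}

#' Keep only adult AML records
#'
#' Retains records with `diagnosis_age >= min_age` and
#' `bm_blast_pct >= min_bm_blast` (both bounds inclusive, defaults 18 years
#' and 20%, the adult-AML diagnostic convention). Records missing either
#' field are removed by this rule.
#'
#' @param cohort an [aml_cohort()].
#' @param min_age,min_bm_blast inclusive thresholds.
#' @return list `cohort`, `report` (an [cleaning_report()] with rules
#'   `underage`, `low_bm_blast`).
#' @export
filter_adult_aml <- function(cohort, min_age = 18, min_bm_blast = 20) {
  clin <- cohort$clinical
  underage <- is.na(clin$diagnosis_age) | clin$diagnosis_age < min_age
  low_blast <- is.na(clin$bm_blast_pct) | clin$bm_blast_pct < min_bm_blast
  low_blast <- low_blast & !underage      # first-triggering rule attribution
  report <- cleaning_report(
    n_patients(cohort),
    removed = list(underage = clin$patient_id[underage],
                   low_bm_blast = clin$patient_id[low_blast]))
  list(cohort = .drop_records(cohort, which(underage | low_blast)),
       report = report)
}

#' Drop records without a survival label
#'
#' Removes records whose `overall_survival_status` is missing (all
#' configured missing markers were mapped to `NA` at load time).
#'
#' @param cohort an [aml_cohort()].
#' @return list `cohort`, `report`.
#' @export
filter_missing_survival <- function(cohort) {
  miss <- is.na(cohort$clinical$overall_survival_status)
  report <- cleaning_report(
    n_patients(cohort),
    removed = list(missing_survival = cohort$clinical$patient_id[miss]))
  list(cohort = .drop_records(cohort, which(miss)), report = report)
}

#' Deduplicate samples to one de-novo marrow record per patient
#'
#' Removes records whose sample site differs from the bone-marrow-aspirate
#' label or whose sample timepoint differs from de-novo, then enforces one
#' record per `patient_id`, keeping the first in stable input order.
#' Cohorts lacking the sample metadata columns pass through unchanged with
#' a logged notice (the rule is vacuous for already patient-level data).
#'
#' @param cohort an [aml_cohort()].
#' @param site_field,timepoint_field clinical column names carrying the
#'   sample-level metadata.
#' @param keep_site,keep_timepoint normalised labels to retain.
#' @return list `cohort`, `report` (rules `wrong_site`, `wrong_timepoint`,
#'   `duplicate_patient`).
#' @export
deduplicate_samples <- function(cohort, site_field = "sample_site",
                                timepoint_field = "sample_timepoint",
                                keep_site = "bone_marrow_aspirate",
                                keep_timepoint = "de_novo") {
  clin <- cohort$clinical
  n <- n_patients(cohort)
  notes <- character()

  wrong_site <- rep(FALSE, n)
  if (site_field %in% names(clin)) {
    wrong_site <- !is.na(clin[[site_field]]) & clin[[site_field]] != keep_site
  } else {
    notes <- c(notes, sprintf("no %s column; site rule vacuous", site_field))
  }
  wrong_tp <- rep(FALSE, n)
  if (timepoint_field %in% names(clin)) {
    wrong_tp <- !is.na(clin[[timepoint_field]]) &
      clin[[timepoint_field]] != keep_timepoint
  } else {
    notes <- c(notes, sprintf("no %s column; timepoint rule vacuous",
                              timepoint_field))
  }
  wrong_tp <- wrong_tp & !wrong_site

  keep_so_far <- !(wrong_site | wrong_tp)
  dup <- rep(FALSE, n)
  seen <- character()
  for (i in which(keep_so_far)) {
    if (clin$patient_id[i] %in% seen) dup[i] <- TRUE
    else seen <- c(seen, clin$patient_id[i])
  }

  report <- cleaning_report(
    n,
    removed = list(wrong_site = clin$patient_id[wrong_site],
                   wrong_timepoint = clin$patient_id[wrong_tp],
                   duplicate_patient = clin$patient_id[dup]),
    notes = notes)
  list(cohort = .drop_records(cohort, which(wrong_site | wrong_tp | dup)),
       report = report)
}

#' Binarise race to an is-white indicator
#'
#' Replaces the raw race column by `is_white`: 1 iff the normalised label
#' equals `"white"`, 0 otherwise; missing race stays missing (left for the
#' imputation stage). A cohort that already carries `is_white` and no race
#' column passes through unchanged.
#'
#' @param cohort an [aml_cohort()].
#' @param race_field clinical column holding the raw race label.
#' @return the cohort with `is_white` in place of the race column.
#' @export
binarize_race <- function(cohort, race_field = "race") {
  clin <- cohort$clinical
  if (!race_field %in% names(clin)) return(cohort)
  raw <- normalize_label(clin[[race_field]])
  clin$is_white <- ifelse(is.na(raw), NA_real_, as.numeric(raw == "white"))
  clin[[race_field]] <- NULL
  cohort$provenance$race_labels <- sort(unique(stats::na.omit(raw)))
  aml_cohort(clin, cohort$mutation, cohort$expression, cohort$provenance)
}

#' Drop never-mutated genes from the mutation panel
#'
#' Removes mutation columns whose flags are zero (or missing) for every
#' patient; such genes carry no information for the chi-square screen.
#'
#' @param cohort an [aml_cohort()].
#' @return list `cohort`, `dropped` (character vector of removed genes).
#' @export
prune_empty_mutation_genes <- function(cohort) {
  genes <- cohort$panels$mutation
  empty <- genes[vapply(genes, function(g) {
    all(is.na(cohort$mutation[[g]]) | cohort$mutation[[g]] == 0)
  }, logical(1))]
  if (length(empty)) {
    cohort$mutation <- cohort$mutation[,
      setdiff(names(cohort$mutation), empty), drop = FALSE]
    cohort <- aml_cohort(cohort$clinical, cohort$mutation, cohort$expression,
                         cohort$provenance)
  }
  list(cohort = cohort, dropped = empty)
}

#' Imputation settings
#'
#' @param k neighbour count (default 3).
#' @param numeric_scaling currently only `"zscore"`.
#' @param distance currently only `"euclidean_matching"` (squared z-score
#'   differences for numeric predictors, simple 0/1 matching for
#'   categorical ones, averaged over predictors observed in both records).
#' @return object of class `aml_imputation_spec`.
#' @export
imputation_spec <- function(k = 3L, numeric_scaling = "zscore",
                            distance = "euclidean_matching") {
  stopifnot(k >= 1)
  structure(list(k = as.integer(k), numeric_scaling = numeric_scaling,
                 distance = distance),
            class = "aml_imputation_spec")
}

#' k-nearest-neighbour imputation of clinical features
#'
#' Fills missing clinical cells feature by feature: each feature with
#' missing entries is treated as a prediction target and its missing
#' entries are filled from the `k` nearest records (by the mixed-type
#' distance of [imputation_spec()]) among records where the target is
#' observed. Numeric targets receive the neighbour mean; categorical and
#' binary 0/1 targets the neighbour majority, with distance ties broken by
#' stable input order and majority ties by the cohort's modal category.
#' Genetic tables are untouched; the survival label is never imputed.
#'
#' @param cohort an [aml_cohort()].
#' @param spec an [imputation_spec()].
#' @return the cohort with all clinical features complete.
#' @export
impute_knn <- function(cohort, spec = imputation_spec()) {
  clin <- cohort$clinical
  feat <- setdiff(names(clin), c("patient_id", "overall_survival_status"))
  is_num <- vapply(clin[feat], is.numeric, logical(1))
  # binary numeric columns are imputed by majority, not mean
  is_binary <- vapply(feat, function(f) {
    is_num[[f]] && all(stats::na.omit(clin[[f]]) %in% c(0, 1))
  }, logical(1))

  # z-scored numeric predictors (cohort mean/sd over observed cells)
  zs <- lapply(feat, function(f) {
    if (!is_num[[f]]) return(NULL)
    v <- clin[[f]]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    (v - mean(v, na.rm = TRUE)) / s
  })
  names(zs) <- feat

  targets <- feat[vapply(feat, function(f) anyNA(clin[[f]]), logical(1))]
  for (f in targets) {
    donors <- which(!is.na(clin[[f]]))
    if (length(donors) < spec$k) {
      stop("cannot impute ", f, ": only ", length(donors),
           " records observe it (need k = ", spec$k, ")")
    }
    preds <- setdiff(feat, f)
    for (i in which(is.na(clin[[f]]))) {
      d <- vapply(donors, function(j) {
        acc <- 0; m <- 0L
        for (p in preds) {
          vi <- clin[[p]][i]; vj <- clin[[p]][j]
          if (is.na(vi) || is.na(vj)) next
          acc <- acc + if (is_num[[p]]) (zs[[p]][i] - zs[[p]][j])^2
                       else as.numeric(vi != vj)
          m <- m + 1L
        }
        if (m == 0L) Inf else acc / m
      }, numeric(1))
      ord <- order(d, seq_along(d))          # stable under distance ties
      nb <- donors[ord[seq_len(spec$k)]]
      vals <- clin[[f]][nb]
      if (is_num[[f]] && !is_binary[[f]]) {
        clin[[f]][i] <- mean(vals)
      } else {
        tab <- table(vals)
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1) {
          pool <- table(clin[[f]][donors])
          pool <- pool[names(pool) %in% top]
          top <- names(pool)[order(-as.numeric(pool), names(pool))][1]
        }
        clin[[f]][i] <- if (is_num[[f]]) as.numeric(top) else top
      }
    }
  }
  cohort$clinical <- clin
  cohort
}

#' Run the full cleaning and preprocessing chain
#'
#' Applies, in fixed order: adult-AML filtering, missing-survival
#' filtering, sample deduplication, race binarisation, empty-mutation-gene
#' pruning, and k-nearest-neighbour imputation. The composite never
#' increases the record count and leaves no missing clinical values.
#'
#' @param cohort an [aml_cohort()].
#' @param impute an [imputation_spec()].
#' @param min_age,min_bm_blast thresholds passed to [filter_adult_aml()].
#' @return list `cohort`, `reports` (named list of [cleaning_report()]s
#'   plus `dropped_genes`).
#' @export
preprocess_cohort <- function(cohort, impute = imputation_spec(),
                              min_age = 18, min_bm_blast = 20) {
  s1 <- filter_adult_aml(cohort, min_age, min_bm_blast)
  s2 <- filter_missing_survival(s1$cohort)
  s3 <- deduplicate_samples(s2$cohort)
  cohort <- binarize_race(s3$cohort)
  pr <- prune_empty_mutation_genes(cohort)
  cohort <- impute_knn(pr$cohort, impute)
  list(cohort = cohort,
       reports = list(adult_aml = s1$report,
                      missing_survival = s2$report,
                      deduplicate = s3$report,
                      dropped_genes = pr$dropped))
}
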