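#' Counterfactual protocol sweep
#'
#' Scores each patient under all four treatment-intensity protocols: a
#' copy of the patient's record with `treatment_intensity` set to each
#' protocol in turn is passed through [committee_predict()]. Treatment
#' intensity is a clinical feature, so genetic committee members are
#' constant across the sweep by construction; only the clinical member can
#' move the score.
#'
#' @param committee an [build_committee()] result.
#' @param cohort an [aml_cohort()] complete in all member modalities.
#' @return data.frame: `patient_id` plus one `score_<protocol>` column per
#'   protocol (the committee survive score under that protocol).
#' @export
sweep_protocols <- function(committee, cohort) {
  out <- data.frame(patient_id = cohort$clinical$patient_id,
                    stringsAsFactors = FALSE)
  for (p in aml_protocols()) {
    cf <- cohort
    cf$clinical$treatment_intensity <- p
    out[[paste0("score_", p)]] <- committee_predict(committee, cf)$survive_score
  }
  out
}

.recommend_from_sweep <- function(sweep, min_margin = 0) {
  protos <- aml_protocols()
  scores <- as.matrix(sweep[, paste0("score_", protos), drop = FALSE])
  # arg-max with canonical-order tie-break: less burdensome protocol first
  best_idx <- apply(scores, 1, which.max)      # which.max takes first max
  best <- protos[best_idx]
  margin <- apply(scores, 1, function(s) {
    o <- sort(s, decreasing = TRUE)
    if (length(o) > 1) o[1] - o[2] else 0
  })
  tie <- apply(scores, 1, function(s) sum(s == max(s)) > 1)
  out <- sweep
  out$recommended <- best
  out$margin <- margin
  out$tie <- tie
  out$low_confidence <- margin < min_margin
  out
}

#' Recommend the survival-maximising protocol for one patient
#'
#' Runs the counterfactual sweep and returns the protocol whose committee
#' survive score is maximal. Exact ties go to the first protocol in
#' canonical order (the less burdensome one) and are flagged; the margin
#' between best and second-best score is reported so near-ties are
#' visible.
#'
#' @param committee an [build_committee()] result.
#' @param record an [aml_cohort()] slice with exactly one patient.
#' @param min_margin margin below which the `low_confidence` flag is set.
#' @return one-row data.frame: `patient_id`, the four `score_*` columns,
#'   `recommended`, `margin`, `tie`, `low_confidence`.
#' @export
recommend_protocol <- function(committee, record, min_margin = 0) {
  stopifnot(n_patients(record) == 1)
  .recommend_from_sweep(sweep_protocols(committee, record), min_margin)
}

#' Recommend protocols for a whole cohort
#'
#' Per-patient recommendations plus an aggregate summary. Records whose
#' features cannot be scored (missing values in a member feature) are
#' collected as errors rather than aborting the run.
#'
#' @param committee an [build_committee()] result.
#' @param cohort a preprocessed [aml_cohort()].
#' @param min_margin margin below which `low_confidence` is flagged.
#' @return list: `recommendations` (data.frame as in
#'   [recommend_protocol()]), `summary` (list `protocol_distribution`,
#'   `mean_margin`, `n_low_confidence`), `errors` (data.frame
#'   `patient_id`, `message`).
#' @export
recommend_cohort <- function(committee, cohort, min_margin = 0) {
  feats <- lapply(committee$members, `[[`, "features")
  ok <- rep(TRUE, n_patients(cohort))
  msgs <- character(n_patients(cohort))
  for (mod in names(feats)) {
    tab <- switch(mod, clinical = cohort$clinical,
                  mutation = cohort$mutation, expression = cohort$expression)
    for (f in setdiff(feats[[mod]], "overall_survival_status")) {
      if (!f %in% names(tab)) stop("cohort lacks feature ", f)
      bad <- is.na(tab[[f]])
      msgs[bad & ok] <- paste0("missing ", mod, " feature ", f)
      ok <- ok & !bad
    }
  }
  errors <- data.frame(patient_id = cohort$clinical$patient_id[!ok],
                       message = msgs[!ok], stringsAsFactors = FALSE)
  scored <- subset_cohort(cohort, which(ok))
  if (n_patients(scored) == 0) {
    rec <- data.frame()
  } else {
    rec <- .recommend_from_sweep(sweep_protocols(committee, scored),
                                 min_margin)
  }
  dist <- if (nrow(rec)) {
    table(factor(rec$recommended, levels = aml_protocols()))
  } else {
    table(factor(character(), levels = aml_protocols()))
  }
  list(recommendations = rec,
       summary = list(protocol_distribution = dist,
                      mean_margin = if (nrow(rec)) mean(rec$margin) else NA,
                      n_low_confidence = if (nrow(rec))
                        sum(rec$low_confidence) else 0L),
       errors = errors)
}
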