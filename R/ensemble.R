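#' Vote weight from a validation F1-score
#'
#' Integer ballot size of a committee member: `ceiling(1 / log10(1 / F1))`.
#' The weight grows without bound as F1 approaches 1, so it is capped;
#' F1 = 1 returns the cap directly (the formula is singular there) and
#' F1 = 0 returns 0, silencing the member. Values whose formula lands
#' within 1e-12 of an integer are snapped to that integer before the
#' ceiling, so exact powers of ten (e.g. F1 = 0.1 -> 1) do not drift up a
#' step through floating-point noise.
#'
#' @param f1 F1-score(s) in \[0, 1\].
#' @param cap maximum weight (default 100).
#' @return non-negative integer vote weight(s).
#' @export
#' @examples
#' vote_weight(c(0.1, 0.7044, 0.7129, 0.7803))
vote_weight <- function(f1, cap = 100L) {
  if (any(is.na(f1)) || any(f1 < 0 | f1 > 1)) {
    stop("f1 must lie in [0, 1]")
  }
  vapply(f1, function(v) {
    if (v == 0) return(0L)
    if (v == 1) return(as.integer(cap))
    w <- 1 / log10(1 / v)
    k <- round(w)
    out <- if (abs(w - k) < 1e-12) k else ceiling(w)
    as.integer(min(out, cap))
  }, integer(1))
}

#' Build a weighted-vote committee
#'
#' Selects the best model per modality (by validation F1, ties to the
#' earlier method in random-forest / logistic-regression / SVM order) and
#' assigns each member its [vote_weight()]. A committee whose members all
#' weigh zero is an error — it could never cast a vote.
#'
#' @param models list of `aml_model`s covering at least one modality.
#' @param cap vote-weight cap.
#' @return object of class `aml_committee`: `members` (named list
#'   modality -> model), `weights` (named integer vector), `weight_cap`.
#' @export
build_committee <- function(models, cap = 100L) {
  members <- select_best_per_modality(models)
  weights <- vapply(members, function(m) {
    vote_weight(m$validation_f1, cap)
  }, integer(1))
  if (all(weights == 0)) {
    stop("all committee weights are zero (every member has F1 = 0)")
  }
  structure(list(members = members, weights = weights,
                 weight_cap = as.integer(cap)),
            class = "aml_committee")
}

#' @export
print.aml_committee <- function(x, ...) {
  cat("Classifier committee:\n")
  for (mod in names(x$members)) {
    m <- x$members[[mod]]
    cat(sprintf("  %-10s %s  F1 %.4f  weight %d\n", mod, m$method,
                m$validation_f1, x$weights[[mod]]))
  }
  invisible(x)
}

#' Refit committee members on new training data
#'
#' Refits each member with its already-chosen hyperparameters on the given
#' cohort (typically training + validation merged, the 9:1 scheme used at
#' the ensemble stage). Vote weights are kept — they encode the members'
#' original validation performance.
#'
#' @param committee an [build_committee()] result.
#' @param cohort training [aml_cohort()].
#' @return the committee with refitted members.
#' @export
refit_committee <- function(committee, cohort) {
  for (mod in names(committee$members)) {
    m <- committee$members[[mod]]
    fr <- .modality_frame(cohort, m$modality, m$features)
    if (nlevels(droplevels(fr$y)) < 2) {
      stop("refit cohort contains a single outcome class")
    }
    design <- .design_spec(fr$x, fr$features)
    x <- .design_matrix(fr$x, design)
    fitted <- .fit_one(m$method, x, fr$y, m$hyperparameters, m$seed)
    # SVM margins are re-calibrated on the refit data itself; the original
    # validation fold is part of it under the 9:1 scheme.
    link <- .make_prob_link(m$method, .raw_score(fitted, x), fr$y)
    m$fit <- fitted
    m$design <- design
    m$prob_link <- link
    committee$members[[mod]] <- m
  }
  committee
}

#' Weighted-vote committee prediction
#'
#' Each member casts its predicted label with its integer weight; the
#' committee label is the class with the larger summed weight. The
#' committee survive score is the weight-averaged member survive
#' probability, and it breaks exact weight-sum ties (score above 0.5 votes
#' living; at or below, deceased).
#'
#' @param committee an [build_committee()] (or [refit_committee()])
#'   result.
#' @param cohort an [aml_cohort()] providing every member's features.
#' @return data.frame: `patient_id`, `label`, `survive_score`, plus one
#'   `vote_<modality>` column per member.
#' @export
committee_predict <- function(committee, cohort) {
  preds <- lapply(committee$members, predict_outcome, cohort = cohort)
  labels <- vapply(preds, `[[`, character(n_patients(cohort)), "label")
  probs <- vapply(preds, `[[`, numeric(n_patients(cohort)),
                  "survive_probability")
  if (n_patients(cohort) == 1) {
    labels <- matrix(labels, nrow = 1, dimnames = list(NULL, names(preds)))
    probs <- matrix(probs, nrow = 1, dimnames = list(NULL, names(preds)))
  }
  agg <- aggregate_votes(labels, probs,
                         committee$weights[names(committee$members)])
  out <- data.frame(patient_id = cohort$clinical$patient_id,
                    label = agg$label, survive_score = agg$survive_score,
                    stringsAsFactors = FALSE)
  for (mod in names(committee$members)) {
    out[[paste0("vote_", mod)]] <- labels[, mod]
  }
  out
}

#' Aggregate weighted member votes
#'
#' The committee decision rule in isolation: every member casts its label
#' with its integer weight, the class with the larger summed weight wins,
#' and the survive score is the weight-averaged member probability.
#' Weight-sum ties fall back to the survive score against 0.5 (above 0.5
#' living, at or below deceased). Zero-weight members contribute nothing.
#'
#' @param labels patients-by-members matrix of `"living"`/`"deceased"`
#'   labels.
#' @param probs patients-by-members matrix of survive probabilities.
#' @param weights integer member weights (recycled along columns).
#' @return list `label` (character vector), `survive_score` (numeric).
#' @export
aggregate_votes <- function(labels, probs, weights) {
  labels <- as.matrix(labels)
  probs <- as.matrix(probs)
  weights <- as.numeric(weights)
  stopifnot(ncol(labels) == length(weights), all(weights >= 0),
            sum(weights) > 0)
  w_living <- (labels == "living") %*% weights
  w_deceased <- (labels == "deceased") %*% weights
  survive_score <- as.numeric(probs %*% weights) / sum(weights)
  label <- ifelse(w_living > w_deceased, "living",
           ifelse(w_living < w_deceased, "deceased",
                  ifelse(survive_score > 0.5, "living", "deceased")))
  list(label = as.character(label), survive_score = survive_score)
}
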