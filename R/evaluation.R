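#' Confusion counts
#'
#' Cross-tabulates true and predicted binary labels. The positive class is
#' `"deceased"` by convention: TP counts patients who deceased and were
#' predicted to decease, TN patients who survived and were predicted to
#' survive.
#'
#' @param labels_true,labels_pred equal-length binary label vectors.
#' @param positive the positive class.
#' @return object of class `aml_confusion`: list `tp`, `fp`, `tn`, `fn`,
#'   `positive`, `negative`.
#' @export
confusion <- function(labels_true, labels_pred, positive = "deceased") {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors differ in length")
  }
  labels_true <- as.character(labels_true)
  labels_pred <- as.character(labels_pred)
  classes <- unique(c(labels_true, labels_pred))
  if (length(classes) > 2) {
    stop("labels are not binary: ", paste(classes, collapse = ", "))
  }
  if (!positive %in% classes && length(classes) == 2) {
    stop("positive class ", positive, " not among the labels")
  }
  negative <- setdiff(classes, positive)
  if (!length(negative)) negative <- "other"
  structure(list(
    tp = sum(labels_true == positive & labels_pred == positive),
    fp = sum(labels_true == negative & labels_pred == positive),
    tn = sum(labels_true == negative & labels_pred == negative),
    fn = sum(labels_true == positive & labels_pred == negative),
    positive = positive, negative = negative
  ), class = "aml_confusion")
}

.safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Threshold metrics from a confusion matrix
#'
#' Accuracy, per-class precision/recall/F1, Matthews correlation
#' coefficient, and support-weighted plus macro aggregates. Zero-division
#' conventions: a precision or recall with zero denominator is reported as
#' 0; MCC is 0 whenever any marginal is zero (the degenerate-predictor
#' convention).
#'
#' @param c an [confusion()] object.
#' @return object of class `aml_metrics`: list with `acc`, `mcc`, `n`,
#'   `per_class` (data.frame class/support/precision/recall/f1),
#'   `weighted` and `macro` (named vectors precision/recall/f1).
#' @export
metrics_from_confusion <- function(c) {
  stopifnot(inherits(c, "aml_confusion"))
  n <- c$tp + c$fp + c$tn + c$fn
  if (n == 0) stop("empty confusion matrix")

  prf <- function(tp, fp, fn) {
    prec <- .safe_div(tp, tp + fp)
    rec <- .safe_div(tp, tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  }
  pos <- prf(c$tp, c$fp, c$fn)
  neg <- prf(c$tn, c$fn, c$fp)
  support <- c(c$tp + c$fn, c$tn + c$fp)

  per_class <- data.frame(
    class = c(c$positive, c$negative), support = support,
    precision = c(pos["precision"], neg["precision"]),
    recall = c(pos["recall"], neg["recall"]),
    f1 = c(pos["f1"], neg["f1"]),
    row.names = NULL, stringsAsFactors = FALSE)

  wavg <- function(col) sum(per_class[[col]] * support) / n
  weighted <- c(precision = wavg("precision"), recall = wavg("recall"),
                f1 = wavg("f1"))
  macro <- c(precision = mean(per_class$precision),
             recall = mean(per_class$recall), f1 = mean(per_class$f1))

  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  tn <- as.numeric(c$tn); fn <- as.numeric(c$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)

  structure(list(acc = (tp + tn) / n, mcc = mcc, n = n,
                 per_class = per_class, weighted = weighted, macro = macro),
            class = "aml_metrics")
}

#' @export
print.aml_metrics <- function(x, ...) {
  cat(sprintf("n = %d  ACC %.4f  MCC %.4f\n", x$n, x$acc, x$mcc))
  cat(sprintf("weighted: F1 %.4f  PREC %.4f  REC %.4f\n",
              x$weighted["f1"], x$weighted["precision"],
              x$weighted["recall"]))
  invisible(x)
}

#' Rank-based AUC from survival scores
#'
#' Area under the ROC curve computed by the rank (Mann-Whitney) identity:
#' the probability that a random surviving patient receives a higher
#' survive score than a random deceased patient, ties counted one half.
#' This equals the AUC of the deceased class under the deceased score, so
#' one number describes the classifier.
#'
#' @param labels_true binary outcome labels.
#' @param survive_scores numeric scores, higher = more likely to survive.
#' @param positive the class whose *low* scores are expected
#'   (`"deceased"`).
#' @return AUC in \[0, 1\]; `NA` with a warning if only one class is
#'   present.
#' @export
auc_score <- function(labels_true, survive_scores, positive = "deceased") {
  labels_true <- as.character(labels_true)
  is_neg <- labels_true == positive            # low scores expected
  n_pos <- sum(!is_neg); n_neg <- sum(is_neg)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(survive_scores, ties.method = "average")
  (sum(r[!is_neg]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metric report for a prediction table
#'
#' Convenience wrapper producing the six headline metrics in the order
#' F1, AUC, ACC, PREC, REC, MCC (weighted aggregates as the headline),
#' plus the underlying per-class table.
#'
#' @param labels_true,labels_pred binary label vectors.
#' @param survive_scores optional numeric survive scores for the AUC; when
#'   absent, AUC is computed from the hard labels (a degenerate two-point
#'   ROC).
#' @param positive positive class.
#' @return named list: `f1`, `auc`, `acc`, `prec`, `rec`, `mcc`, `n`,
#'   `per_class`.
#' @export
evaluate_predictions <- function(labels_true, labels_pred,
                                 survive_scores = NULL,
                                 positive = "deceased") {
  m <- metrics_from_confusion(confusion(labels_true, labels_pred, positive))
  if (is.null(survive_scores)) {
    survive_scores <- as.numeric(as.character(labels_pred) != positive)
  }
  auc <- auc_score(labels_true, survive_scores, positive)
  list(f1 = unname(m$weighted["f1"]), auc = auc, acc = m$acc,
       prec = unname(m$weighted["precision"]),
       rec = unname(m$weighted["recall"]), mcc = m$mcc, n = m$n,
       per_class = m$per_class)
}
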