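#' Feature-selection result
#'
#' @param modality `"clinical"`, `"expression"` or `"mutation"`.
#' @param selected ordered character vector of chosen features.
#' @param scores named numeric vector over the scored candidates
#'   (coefficient magnitudes for the L1 screen, p-values for the
#'   chi-square screen, rank order for the expert list).
#' @param threshold the applied cut-off (regularisation strength or alpha).
#' @param notes character vector of notices.
#' @return object of class `aml_selection`.
#' @export
selection_result <- function(modality, selected, scores = numeric(),
                             threshold = NA_real_, notes = character()) {
  structure(list(modality = modality, selected = selected, scores = scores,
                 threshold = threshold, notes = notes),
            class = "aml_selection")
}

#' @export
print.aml_selection <- function(x, ...) {
  cat(sprintf("%s selection: %d features (threshold %s)\n", x$modality,
              length(x$selected), format(x$threshold)))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Expert-curated clinical feature selection
#'
#' Clinical features are chosen by domain experts rather than by a
#' statistic: the result is the expert list, in expert order, verified to
#' be present in the candidate schema.
#'
#' @param candidates available clinical feature names.
#' @param expert_list expert-chosen features; defaults to the 11-feature
#'   panel of [aml_clinical_panel()].
#' @return an [selection_result()] for the clinical modality.
#' @export
select_clinical_expert <- function(candidates,
                                   expert_list = aml_clinical_panel()) {
  absent <- setdiff(expert_list, candidates)
  if (length(absent)) {
    stop("expert clinical feature(s) absent from the schema: ",
         paste(absent, collapse = ", "))
  }
  selection_result("clinical", expert_list,
                   scores = stats::setNames(seq_along(expert_list),
                                            expert_list))
}

#' L1-penalised expression screen
#'
#' Fits an L1-penalised linear classifier of the survival outcome on the
#' standardised expression columns and keeps the genes with a non-zero
#' coefficient. The regularisation strength is parameterised as in common
#' machine-learning stacks by `C` (larger `C` = weaker penalty), mapped to
#' the lasso penalty `lambda = 1 / (n * C)`.
#'
#' @param X patients-by-genes numeric matrix (no missing values).
#' @param y outcome vector (`"deceased"` / `"living"`), both classes
#'   present.
#' @param C regularisation strength, default 0.01 as in the original
#'   expression screen.
#' @return an [selection_result()]: `selected` ordered by decreasing
#'   coefficient magnitude, `scores` = |coefficient| over all fitted
#'   genes.
#' @export
select_expression_l1 <- function(X, y, C = 0.01) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("expression matrix contains missing values")
  yf <- factor(.canon_survival(y), levels = .aml_outcomes)
  if (nlevels(droplevels(yf)) < 2) {
    stop("outcome vector contains a single class; cannot fit the screen")
  }
  notes <- character()
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    notes <- c(notes, paste("zero-variance columns excluded:",
                            paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  lambda <- 1 / (nrow(X) * C)
  fit <- glmnet::glmnet(X, yf, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = TRUE)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  scores <- abs(beta)
  selected <- names(scores)[scores > 0]
  selected <- selected[order(-scores[selected],
                             match(selected, colnames(X)))]
  selection_result("expression", selected, scores = scores, threshold = C,
                   notes = notes)
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-square statistic
#' with 1 degree of freedom and upper-tail p-value, testing independence
#' of the two binary factors. Tables with a zero marginal have no defined
#' statistic and are reported as degenerate with statistic 0 and p = 1.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return list `statistic`, `p`, `degenerate` (logical).
#' @export
chi2_independence <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(statistic = 0, p = 1, degenerate = TRUE))
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       degenerate = FALSE)
}

#' Chi-square mutation screen
#'
#' For each gene, cross-tabulates the 0/1 mutation flag against the binary
#' survival outcome and applies [chi2_independence()]. Genes with p
#' strictly below `alpha` are selected; no multiple-testing correction is
#' applied (the screen is a deliberate liberal filter ahead of supervised
#' model training).
#'
#' @param M patients-by-genes 0/1 matrix.
#' @param y outcome vector (`"deceased"` / `"living"`).
#' @param alpha selection threshold in (0, 1\]; default 0.1. `alpha = 0`
#'   selects nothing.
#' @return an [selection_result()]: `selected` ordered by ascending
#'   p-value, `scores` = p-values over all genes.
#' @export
select_mutations_chi2 <- function(M, y, alpha = 0.1) {
  M <- as.matrix(M)
  stopifnot(all(is.na(M) | M %in% c(0, 1)), alpha >= 0, alpha <= 1)
  yv <- .canon_survival(y)
  genes <- colnames(M)
  p <- vapply(genes, function(g) {
    tab <- table(factor(M[, g], levels = c(0, 1)),
                 factor(yv, levels = .aml_outcomes))
    chi2_independence(tab)$p
  }, numeric(1))
  selected <- genes[p < alpha]
  selected <- selected[order(p[selected], match(selected, genes))]
  selection_result("mutation", selected, scores = p, threshold = alpha)
}
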