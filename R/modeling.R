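#' Hold-out split specification
#'
#' Four-way hold-out: 70% training, 10% feature selection, 10% validation,
#' 10% independent test. Each held-out fold receives `ceiling(fraction*n)`
#' records and training the remainder — the only convention consistent
#' with reporting 216 training records at n = 272 once the
#' feature-selection fold is folded back into training for model fitting.
#'
#' @param fractions named fractions summing to 1; names other than
#'   `train` are held-out folds.
#' @param seed integer seed for the random permutation.
#' @param merge_validation_into_train when `TRUE`, the validation fold is
#'   relabelled `train` (the 9:1 hold-out used at the ensemble stage).
#' @return object of class `aml_split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.7, feature_select = 0.1,
                                     validation = 0.1, test = 0.1),
                       seed = 1L, merge_validation_into_train = FALSE) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, "train" %in% names(fractions))
  structure(list(fractions = fractions, seed = as.integer(seed),
                 merge_validation_into_train = merge_validation_into_train),
            class = "aml_split_spec")
}

#' Random hold-out partition
#'
#' Assigns each patient to exactly one fold: held-out folds get
#' `ceiling(fraction * n)` patients each, drawn from a seeded random
#' permutation; training receives the remainder. Deterministic given the
#' seed.
#'
#' @param cohort an [aml_cohort()] (or an integer n).
#' @param spec an [split_spec()].
#' @return object of class `aml_split`: list `labels` (character vector,
#'   one fold label per patient, input order), `sizes`, `spec`.
#' @export
split_holdout <- function(cohort, spec = split_spec()) {
  n <- if (inherits(cohort, "aml_cohort")) n_patients(cohort)
       else as.integer(cohort)
  if (n < 10) stop("need at least 10 records for a 70/10/10/10 hold-out")
  held <- setdiff(names(spec$fractions), "train")
  sizes <- ceiling(spec$fractions[held] * n)
  if (sum(sizes) >= n) stop("hold-out folds leave no training data")

  set.seed(spec$seed)
  perm <- sample.int(n)
  labels <- rep("train", n)
  offset <- 0L
  for (h in held) {
    idx <- perm[(offset + 1L):(offset + sizes[[h]])]
    labels[idx] <- h
    offset <- offset + sizes[[h]]
  }
  if (spec$merge_validation_into_train) {
    labels[labels == "validation"] <- "train"
  }
  structure(list(labels = labels, sizes = table(labels), spec = spec),
            class = "aml_split")
}

#' @export
print.aml_split <- function(x, ...) {
  cat("Hold-out split (seed", x$spec$seed, "):",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Hyperparameter grid
#'
#' The default grid evaluated for each method family: random forest
#' (number of trees, minimum leaf size, maximum depth, class weighting),
#' L2-penalised logistic regression (inverse regularisation strength `C`,
#' class weighting) and support vector machine (kernel, `C`, class
#' weighting). `max_depth = NA` means unlimited depth. All other settings
#' stay at library defaults.
#'
#' @param random_forest,logistic_regression,svm optional named lists of
#'   candidate-value vectors overriding the defaults per method.
#' @return object of class `aml_grid`: per-method named lists.
#' @export
hyperparameter_grid <- function(random_forest = NULL,
                                logistic_regression = NULL, svm = NULL) {
  g <- list(
    random_forest = list(
      n_estimators = c(10, 15, 20, 25, 30, 45, 50),
      min_samples_leaf = c(1, 2, 3, 4),
      max_depth = c(8, 10, NA),
      class_weight = c("balanced", "none")),
    logistic_regression = list(
      C = c(1e-6, 5.62e-5, 3.166e-3, 1.77e-1, 10),
      class_weight = c("balanced", "none")),
    svm = list(
      kernel = c("linear", "rbf"),
      C = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
      class_weight = c("balanced", "none"))
  )
  for (m in names(g)) {
    ov <- switch(m, random_forest = random_forest,
                 logistic_regression = logistic_regression, svm = svm)
    if (!is.null(ov)) g[[m]][names(ov)] <- ov
    stopifnot(all(vapply(g[[m]], length, integer(1)) > 0))
  }
  structure(g, class = "aml_grid")
}

.aml_methods <- c("random_forest", "logistic_regression", "svm")

# -- design matrices -------------------------------------------------------

# A design spec freezes, at training time, how raw modality features are
# encoded: numeric columns are z-scored with training statistics,
# categorical columns one-hot encoded over the training levels.
.design_spec <- function(df, features) {
  spec <- list(features = features, kind = list(), levels = list(),
               center = list(), scale = list())
  for (f in features) {
    v <- df[[f]]
    if (is.numeric(v)) {
      spec$kind[[f]] <- "numeric"
      spec$center[[f]] <- mean(v)
      s <- stats::sd(v)
      spec$scale[[f]] <- if (is.finite(s) && s > 0) s else 1
    } else {
      spec$kind[[f]] <- "categorical"
      spec$levels[[f]] <- sort(unique(as.character(v)))
    }
  }
  spec
}

.design_matrix <- function(df, spec) {
  cols <- list()
  for (f in spec$features) {
    if (!f %in% names(df)) stop("missing feature: ", f)
    v <- df[[f]]
    if (anyNA(v)) stop("missing values in feature: ", f)
    if (spec$kind[[f]] == "numeric") {
      cols[[f]] <- (as.numeric(v) - spec$center[[f]]) / spec$scale[[f]]
    } else {
      for (lv in spec$levels[[f]]) {
        cols[[paste0(f, "=", lv)]] <- as.numeric(as.character(v) == lv)
      }
    }
  }
  do.call(cbind, cols)
}

# Raw predictor frame + outcome for one modality of a cohort.
.modality_frame <- function(cohort, modality, features) {
  tab <- switch(modality,
                clinical = cohort$clinical,
                mutation = cohort$mutation,
                expression = cohort$expression,
                stop("unknown modality: ", modality))
  features <- setdiff(features, "overall_survival_status")
  absent <- setdiff(features, names(tab))
  if (length(absent)) {
    stop("modality ", modality, " lacks feature(s): ",
         paste(absent, collapse = ", "))
  }
  list(x = tab[, features, drop = FALSE],
       y = factor(cohort$clinical$overall_survival_status,
                  levels = .aml_outcomes),
       ids = cohort$clinical$patient_id,
       features = features)
}

# -- fitting ---------------------------------------------------------------

.class_weights <- function(y, scheme) {
  tab <- table(y)
  if (scheme == "balanced") {
    w <- length(y) / (length(tab) * as.numeric(tab))
    stats::setNames(w, names(tab))
  } else {
    stats::setNames(rep(1, length(tab)), names(tab))
  }
}

.fit_one <- function(method, x, y, params, seed) {
  set.seed(seed)
  cw <- .class_weights(y, params$class_weight)
  if (method == "random_forest") {
    fit <- ranger::ranger(
      x = x, y = y,
      num.trees = params$n_estimators,
      min.node.size = params$min_samples_leaf,
      max.depth = if (is.na(params$max_depth)) 0 else params$max_depth,
      class.weights = unname(cw[levels(y)]),
      probability = TRUE, seed = seed, num.threads = 1)
    list(method = method, fit = fit)
  } else if (method == "logistic_regression") {
    lambda <- 1 / (nrow(x) * params$C)
    # glmnet requires >= 2 columns; single-feature designs get an inert
    # all-zero pad column
    if (ncol(x) < 2) x <- cbind(x, `..pad..` = 0)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE,
                          weights = unname(cw[as.character(y)]))
    list(method = method, fit = fit)
  } else if (method == "svm") {
    fit <- e1071::svm(x, y, kernel = if (params$kernel == "rbf") "radial"
                                     else "linear",
                      cost = params$C, class.weights = cw,
                      scale = FALSE, probability = FALSE)
    list(method = method, fit = fit)
  } else stop("unknown method: ", method)
}

# Raw survive-probability-like score (before any SVM link calibration).
.raw_score <- function(fitted, x) {
  if (fitted$method == "random_forest") {
    pr <- stats::predict(fitted$fit, data = x, num.threads = 1)$predictions
    pr[, "living"]
  } else if (fitted$method == "logistic_regression") {
    if (ncol(x) < nrow(fitted$fit$beta)) x <- cbind(x, `..pad..` = 0)
    # glmnet binomial response = P(second factor level) = P(living)
    as.numeric(stats::predict(fitted$fit, newx = x, type = "response"))
  } else {
    pred <- stats::predict(fitted$fit, x, decision.values = TRUE)
    dv <- as.numeric(attr(pred, "decision.values"))
    # positive decision values favour the first level ("deceased")
    -dv
  }
}

# Map raw scores to probabilities; SVM margins go through a logistic link
# fitted on the validation fold (fallback: plain logistic squashing).
.make_prob_link <- function(method, raw_val, y_val) {
  if (method != "svm") return(list(type = "identity"))
  y01 <- as.numeric(y_val == "living")
  link <- tryCatch({
    fit <- suppressWarnings(stats::glm(y01 ~ raw_val,
                                       family = stats::binomial()))
    if (!fit$converged || !is.finite(stats::coef(fit)[2])) stop("nc")
    list(type = "logistic", coef = unname(stats::coef(fit)))
  }, error = function(e) list(type = "squash"))
  link
}

.apply_prob_link <- function(link, raw) {
  switch(link$type,
         identity = pmin(pmax(raw, 0), 1),
         logistic = stats::plogis(link$coef[1] + link$coef[2] * raw),
         squash = stats::plogis(raw))
}

#' Grid-search training of one modality model
#'
#' Exhaustively evaluates the method's hyperparameter grid: each
#' configuration is fitted on the training slice and scored on the
#' validation slice by the objective (weighted F1 by default). The first
#' configuration attaining the maximum, in grid order, wins. The winner's
#' validation F1 is recorded as the model's vote-weight basis.
#'
#' @param method one of `"random_forest"`, `"logistic_regression"`,
#'   `"svm"`.
#' @param modality `"clinical"`, `"mutation"` or `"expression"`.
#' @param train_cohort,validation_cohort disjoint [aml_cohort()] slices.
#' @param features predictor feature names for the modality (the selected
#'   panel; the survival label is excluded automatically).
#' @param grid an [hyperparameter_grid()].
#' @param seed integer seed threaded through model fitting.
#' @return object of class `aml_model`: `method`, `modality`, `fit`,
#'   `hyperparameters`, `validation_f1`, `design` (frozen encoding),
#'   `features`, `prob_link`, `n_evaluated`.
#' @export
train_with_grid <- function(method, modality, train_cohort,
                            validation_cohort, features,
                            grid = hyperparameter_grid(), seed = 1L) {
  method <- match.arg(method, .aml_methods)
  tr <- .modality_frame(train_cohort, modality, features)
  va <- .modality_frame(validation_cohort, modality, features)
  if (nlevels(droplevels(tr$y)) < 2) {
    stop("training fold contains a single outcome class; re-split")
  }

  design <- .design_spec(tr$x, tr$features)
  x_tr <- .design_matrix(tr$x, design)
  x_va <- .design_matrix(va$x, design)

  configs <- expand.grid(grid[[method]], stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (i in seq_len(nrow(configs))) {
    params <- as.list(configs[i, , drop = FALSE])
    fitted <- .fit_one(method, x_tr, tr$y, params, seed)
    raw_va <- .raw_score(fitted, x_va)
    link <- .make_prob_link(method, raw_va, va$y)
    p_va <- .apply_prob_link(link, raw_va)
    pred <- ifelse(p_va > 0.5, "living", "deceased")
    f1 <- metrics_from_confusion(confusion(as.character(va$y),
                                           pred))$weighted[["f1"]]
    if (is.null(best) || f1 > best$validation_f1) {
      best <- list(fitted = fitted, params = params, link = link,
                   validation_f1 = f1)
    }
  }

  structure(list(method = method, modality = modality,
                 fit = best$fitted, hyperparameters = best$params,
                 validation_f1 = best$validation_f1,
                 design = design, features = tr$features,
                 prob_link = best$link,
                 n_evaluated = nrow(configs), seed = seed),
            class = "aml_model")
}

#' @export
print.aml_model <- function(x, ...) {
  cat(sprintf("%s model on %s data: validation F1 %.4f\n", x$method,
              x$modality, x$validation_f1))
  hp <- vapply(x$hyperparameters, function(v) format(v), character(1))
  cat(" ", paste(names(hp), hp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict survival outcome for patients
#'
#' Applies a trained modality model to a cohort (or a single-patient
#' slice) and returns the predicted label and a survive probability in
#' \[0, 1\]. A probability of exactly 0.5 is labelled `"deceased"` by
#' convention.
#'
#' @param model an `aml_model` from [train_with_grid()].
#' @param cohort an [aml_cohort()]; all of the model's features must be
#'   present and complete.
#' @return data.frame: `patient_id`, `label`, `survive_probability`.
#' @export
predict_outcome <- function(model, cohort) {
  fr <- .modality_frame(cohort, model$modality, model$features)
  x <- .design_matrix(fr$x, model$design)
  p <- .apply_prob_link(model$prob_link, .raw_score(model$fit, x))
  p <- pmin(pmax(p, 0), 1)
  data.frame(patient_id = fr$ids,
             label = ifelse(p > 0.5, "living", "deceased"),
             survive_probability = p,
             stringsAsFactors = FALSE)
}

#' Best model per modality
#'
#' Picks, for each modality present, the model with the highest validation
#' F1; exact ties are broken by method order (random forest, logistic
#' regression, SVM) for determinism.
#'
#' @param models list of `aml_model`s.
#' @return named list modality -> `aml_model`.
#' @export
select_best_per_modality <- function(models) {
  stopifnot(length(models) > 0)
  modalities <- unique(vapply(models, `[[`, character(1), "modality"))
  out <- list()
  for (mod in modalities) {
    cand <- Filter(function(m) m$modality == mod, models)
    f1 <- vapply(cand, `[[`, numeric(1), "validation_f1")
    meth <- match(vapply(cand, `[[`, character(1), "method"), .aml_methods)
    out[[mod]] <- cand[[order(-f1, meth)[1]]]
  }
  out
}
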