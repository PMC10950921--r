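# Truncated-normal / truncated-log-normal draws by inverse-CDF so that the
# printed min/max bounds are respected exactly.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

.rtrunclnorm <- function(n, meanlog, sdlog, lo, hi) {
  u <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

#' Configuration for the synthetic AML cohort generator
#'
#' Assembles every knob of the generator with defaults that emulate the
#' processed study cohort: 272 patients, the 11-feature clinical panel, the
#' 22-gene expression and 10-gene mutation signal panels, continuous
#' clinical marginals matched to the published summary statistics
#' (truncation at the printed min/max), about 75% white patients, and a
#' binary survival outcome drawn from a logistic model with
#' treatment-intensity main effects and a treatment-by-age interaction.
#'
#' @param n_patients cohort size.
#' @param expression_signal_genes,mutation_signal_genes gene name vectors
#'   for the outcome-linked panels.
#' @param n_decoy_expression,n_decoy_mutation number of additional
#'   outcome-independent decoy genes per genetic modality.
#' @param clinical_marginals named list of per-feature distribution
#'   parameters; see the default for the expected structure.
#' @param outcome_model named list of logistic-model coefficients on the
#'   deceased log-odds scale: `intercept`; `age`, `bm_blast`, `log_wbc`
#'   (per standardised unit); `eln` (named offsets); `protocol` (named main
#'   effects, lower = better survival); `beta_mutation`, `beta_expression`
#'   (named per-gene effects); `interaction_age` (strength `s` of the
#'   protocol-by-age term `s * z_age * d[protocol]` with contrast
#'   `d = c(target 0, regular 0, low_intensity -1, high_intensity +1)`:
#'   high-intensity therapy harms older patients and helps younger ones);
#'   `interaction_expression` (strength of an optional protocol-by-gene
#'   term) and `interaction_expression_gene`.
#' @param treatment_policy `"marginal"` (treatment independent of
#'   covariates, default) or `"eln_age"` (confounded assignment: adverse
#'   risk and older age push toward low-intensity, favorable/young toward
#'   high-intensity).
#' @param missingness_rate MCAR missingness rate applied to clinical cells
#'   (class label never masked).
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return a list of class `aml_generator_config`.
#' @export
generator_config <- function(n_patients = 272,
                             expression_signal_genes = aml_expression_panel(),
                             mutation_signal_genes = aml_mutation_panel(),
                             n_decoy_expression = 0,
                             n_decoy_mutation = 0,
                             clinical_marginals = NULL,
                             outcome_model = NULL,
                             treatment_policy = c("marginal", "eln_age"),
                             missingness_rate = 0,
                             seed = 1L) {
  stopifnot(n_patients >= 1, missingness_rate >= 0, missingness_rate < 1)
  treatment_policy <- match.arg(treatment_policy)

  marg <- list(
    diagnosis_age = list(mean = 56, sd = 15, min = 18, max = 88),
    bm_blast_pct = list(mean = 70, sd = 24, min = 20, max = 100),
    mutation_count = list(meanlog = log(9), sdlog = 0.6, min = 1, max = 34),
    pb_blast_pct = list(mean = 37, sd = 28, min = 0, max = 99.2),
    wbc = list(meanlog = log(39.44), sdlog = 1.0, min = 0.4, max = 483),
    p_male = 0.55,
    p_white = 0.75,
    cytogenetic = c(normal_karyotype = 0.45, intermediate_abnormal = 0.35,
                    complex = 0.20),
    eln = c(favorable = 0.22, intermediate = 0.50, adverse = 0.28)
  )
  if (!is.null(clinical_marginals)) {
    marg[names(clinical_marginals)] <- clinical_marginals
  }

  n_exp <- length(expression_signal_genes)
  n_mut <- length(mutation_signal_genes)
  om <- list(
    intercept = 0.25,
    age = 0.5, bm_blast = 0.2, log_wbc = 0.3,
    eln = c(favorable = -0.6, intermediate = 0, adverse = 0.7),
    protocol = c(target = -0.2, regular = -0.3,
                 low_intensity = 0.6, high_intensity = -0.5),
    beta_mutation = stats::setNames(
      rep_len(c(0.7, 0.6, -0.3, 0.3, -0.4, 0.3, 0.4, 0.5, 0.3, 0.9), n_mut),
      mutation_signal_genes),
    mutation_prevalence = stats::setNames(
      rep_len(seq(0.08, 0.30, length.out = max(n_mut, 2))[seq_len(n_mut)],
              n_mut),
      mutation_signal_genes),
    beta_expression = stats::setNames(
      rep_len(c(1, -1), n_exp) *
        seq(0.15, 0.45, length.out = max(n_exp, 2))[seq_len(n_exp)],
      expression_signal_genes),
    interaction_age = 1.0,
    interaction_expression = 0,
    interaction_expression_gene = expression_signal_genes[1]
  )
  if (!is.null(outcome_model)) om[names(outcome_model)] <- outcome_model

  structure(
    list(n_patients = as.integer(n_patients),
         expression_signal_genes = expression_signal_genes,
         mutation_signal_genes = mutation_signal_genes,
         n_decoy_expression = as.integer(n_decoy_expression),
         n_decoy_mutation = as.integer(n_decoy_mutation),
         clinical_marginals = marg,
         outcome_model = om,
         treatment_policy = treatment_policy,
         missingness_rate = missingness_rate,
         seed = as.integer(seed)),
    class = "aml_generator_config")
}

# Protocol-by-age interaction contrast: positive entries are harmed by
# older age, negative entries helped.
.protocol_contrast <- c(target = 0, regular = 0,
                        low_intensity = -1, high_intensity = 1)

# Deceased log-odds for each patient under the given protocol assignment.
# `protocol` is a character vector of length n.
.deceased_log_odds <- function(config, clin, mut, expr, protocol) {
  om <- config$outcome_model
  marg <- config$clinical_marginals
  z_age <- (clin$diagnosis_age - marg$diagnosis_age$mean) /
    marg$diagnosis_age$sd
  z_bm <- (clin$bm_blast_pct - marg$bm_blast_pct$mean) / marg$bm_blast_pct$sd
  z_wbc <- (log(clin$wbc) - marg$wbc$meanlog) / marg$wbc$sdlog

  lp <- om$intercept +
    om$age * z_age + om$bm_blast * z_bm + om$log_wbc * z_wbc +
    unname(om$eln[clin$eln_risk]) +
    unname(om$protocol[protocol]) +
    om$interaction_age * z_age * unname(.protocol_contrast[protocol])

  # mutation effects act on prevalence-centred flags so that the intercept
  # alone sets the marginal outcome rate
  for (g in names(om$beta_mutation)) {
    prev <- om$mutation_prevalence[[g]]
    if (is.null(prev)) prev <- 0
    lp <- lp + om$beta_mutation[[g]] * (mut[[g]] - prev)
  }
  for (g in names(om$beta_expression)) {
    lp <- lp + om$beta_expression[[g]] * expr[[g]]
  }
  if (om$interaction_expression != 0) {
    g <- om$interaction_expression_gene
    lp <- lp + om$interaction_expression * expr[[g]] *
      unname(.protocol_contrast[protocol])
  }
  lp
}

#' Generate a synthetic AML cohort with ground truth
#'
#' Draws a complete multimodal cohort from [generator_config()] together
#' with the generative ground truth needed for parameter-recovery testing:
#' each patient's survival probability under all four protocols, the
#' protocol that maximises it, and the realised outcome under the assigned
#' protocol. Identical configs (including seed) yield identical cohorts.
#'
#' @param config an [generator_config()].
#' @return list with elements `cohort` (an [aml_cohort()]) and
#'   `ground_truth` (data.frame: `patient_id`, one `p_survive_<protocol>`
#'   column per protocol, `optimal_protocol`, `assigned_protocol`,
#'   `outcome`).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "aml_generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  marg <- config$clinical_marginals

  clin <- data.frame(
    patient_id = sprintf("SYN-%04d", seq_len(n)),
    diagnosis_age = .rtruncnorm(n, marg$diagnosis_age$mean,
                                marg$diagnosis_age$sd,
                                marg$diagnosis_age$min, marg$diagnosis_age$max),
    bm_blast_pct = .rtruncnorm(n, marg$bm_blast_pct$mean, marg$bm_blast_pct$sd,
                               marg$bm_blast_pct$min, marg$bm_blast_pct$max),
    mutation_count = round(.rtrunclnorm(n, marg$mutation_count$meanlog,
                                        marg$mutation_count$sdlog,
                                        marg$mutation_count$min,
                                        marg$mutation_count$max)),
    pb_blast_pct = .rtruncnorm(n, marg$pb_blast_pct$mean, marg$pb_blast_pct$sd,
                               marg$pb_blast_pct$min, marg$pb_blast_pct$max),
    wbc = .rtrunclnorm(n, marg$wbc$meanlog, marg$wbc$sdlog,
                       marg$wbc$min, marg$wbc$max),
    gender = ifelse(stats::runif(n) < marg$p_male, "male", "female"),
    is_white = as.numeric(stats::runif(n) < marg$p_white),
    cytogenetic_group = sample(names(marg$cytogenetic), n, replace = TRUE,
                               prob = marg$cytogenetic),
    eln_risk = sample(names(marg$eln), n, replace = TRUE, prob = marg$eln),
    stringsAsFactors = FALSE
  )

  # Treatment assignment: marginal draw, or an ELN/age-driven policy that
  # confounds treatment with prognosis.
  base_probs <- c(target = 0.10, regular = 0.35,
                  low_intensity = 0.12, high_intensity = 0.43)
  if (config$treatment_policy == "marginal") {
    clin$treatment_intensity <- sample(names(base_probs), n, replace = TRUE,
                                       prob = base_probs)
  } else {
    z_age <- (clin$diagnosis_age - marg$diagnosis_age$mean) /
      marg$diagnosis_age$sd
    tilt <- z_age + (clin$eln_risk == "adverse") -
      (clin$eln_risk == "favorable")
    clin$treatment_intensity <- vapply(seq_len(n), function(i) {
      w <- base_probs * exp(c(0, 0, 1, -1) * tilt[i])
      sample(names(w), 1, prob = w / sum(w))
    }, character(1))
  }

  mut_panel <- c(config$mutation_signal_genes,
                 if (config$n_decoy_mutation > 0) {
                   sprintf("DECOY_M%03d", seq_len(config$n_decoy_mutation))
                 })
  mut <- data.frame(patient_id = clin$patient_id, stringsAsFactors = FALSE)
  prev <- config$outcome_model$mutation_prevalence
  for (g in config$mutation_signal_genes) {
    mut[[g]] <- as.numeric(stats::runif(n) < prev[[g]])
  }
  for (g in setdiff(mut_panel, config$mutation_signal_genes)) {
    mut[[g]] <- as.numeric(stats::runif(n) < 0.15)
  }

  exp_panel <- c(config$expression_signal_genes,
                 if (config$n_decoy_expression > 0) {
                   sprintf("DECOY_E%03d", seq_len(config$n_decoy_expression))
                 })
  expr <- data.frame(patient_id = clin$patient_id, stringsAsFactors = FALSE)
  for (g in exp_panel) expr[[g]] <- stats::rnorm(n)

  # Ground truth: survival probability under every protocol.
  p_survive <- sapply(aml_protocols(), function(p) {
    1 - stats::plogis(.deceased_log_odds(config, clin, mut, expr,
                                         rep(p, n)))
  })
  if (n == 1) p_survive <- matrix(p_survive, nrow = 1,
                                  dimnames = list(NULL, aml_protocols()))
  optimal <- aml_protocols()[apply(p_survive, 1, which.max)]

  lp_assigned <- .deceased_log_odds(config, clin, mut, expr,
                                    clin$treatment_intensity)
  outcome <- ifelse(stats::runif(n) < stats::plogis(lp_assigned),
                    "deceased", "living")
  clin$overall_survival_status <- outcome

  ground_truth <- data.frame(patient_id = clin$patient_id,
                             stringsAsFactors = FALSE)
  for (p in aml_protocols()) {
    ground_truth[[paste0("p_survive_", p)]] <- unname(p_survive[, p])
  }
  ground_truth$optimal_protocol <- optimal
  ground_truth$assigned_protocol <- clin$treatment_intensity
  ground_truth$outcome <- outcome

  cohort <- aml_cohort(clin, mut, expr,
                       provenance = list(generator = "amlrec synthetic",
                                         seed = config$seed))
  if (config$missingness_rate > 0) {
    cohort <- inject_missingness(cohort, config$missingness_rate,
                                 seed = config$seed + 1L)
  }
  list(cohort = cohort, ground_truth = ground_truth)
}

#' Mask clinical cells completely at random
#'
#' Sets clinical feature cells (never `patient_id`, never the survival
#' class label) to missing with the given probability, to exercise the
#' imputation stage. Deterministic given the seed.
#'
#' @param cohort an [aml_cohort()].
#' @param rate masking probability in \[0, 1).
#' @param seed integer seed.
#' @return the masked cohort.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(cohort)
  set.seed(seed)
  cols <- setdiff(names(cohort$clinical),
                  c("patient_id", "overall_survival_status"))
  for (col in cols) {
    mask <- stats::runif(n_patients(cohort)) < rate
    cohort$clinical[[col]][mask] <- NA
  }
  cohort
}

#' Small cohort with planted cleaning violations
#'
#' Builds a compact cohort whose defects are known exactly, for testing the
#' cleaning filters end to end: two minors, one low-blast record, one
#' record violating both the age and the missing-survival rules (attributed
#' to the first-triggering filter), one missing survival label, one
#' peripheral-blood sample, one relapse-timepoint sample, and one
#' duplicated patient id. The expected per-rule removals are attached as
#' `attr(, "manifest")`.
#'
#' @param seed integer seed for the clean backbone.
#' @return an [aml_cohort()] carrying sample-level `sample_site` and
#'   `sample_timepoint` columns plus a `manifest` attribute (list with
#'   `n_input`, `expected_removed` per rule, `n_clean`).
#' @export
make_dirty_fixture <- function(seed = 42L) {
  gen <- generate_cohort(generator_config(n_patients = 20, seed = seed))
  cohort <- gen$cohort
  clin <- cohort$clinical
  clin$sample_site <- "bone_marrow_aspirate"
  clin$sample_timepoint <- "de_novo"
  # race column as it would arrive pre-binarisation
  clin$race <- ifelse(clin$is_white == 1, "white", "other")
  clin$is_white <- NULL

  id <- function(k) sprintf("SYN-%04d", k)
  clin$diagnosis_age[clin$patient_id == id(2)] <- 17
  clin$bm_blast_pct[clin$patient_id == id(3)] <- 15
  clin$diagnosis_age[clin$patient_id == id(4)] <- 16          # also loses label
  clin$overall_survival_status[clin$patient_id == id(4)] <- NA
  clin$overall_survival_status[clin$patient_id == id(5)] <- NA
  clin$sample_site[clin$patient_id == id(6)] <- "peripheral_blood"
  clin$sample_timepoint[clin$patient_id == id(7)] <- "relapse"

  dup <- clin[clin$patient_id == id(8), , drop = FALSE]
  dup$sample_timepoint <- "de_novo"
  clin <- rbind(clin, dup)

  cohort$clinical <- clin
  cohort <- aml_cohort(clin, cohort$mutation, cohort$expression,
                       provenance = list(generator = "amlrec dirty fixture",
                                         seed = seed))
  manifest <- list(
    n_input = nrow(clin),
    expected_removed = list(
      adult_aml = c(id(2), id(3), id(4)),
      missing_survival = id(5),
      deduplicate = c(id(6), id(7), id(8))
    ),
    n_clean = nrow(clin) - 7L
  )
  attr(cohort, "manifest") <- manifest
  cohort
}

#' Expression matrix with planted signal genes
#'
#' Generates an i.i.d. standard-normal patients-by-genes matrix and a
#' binary outcome drawn from a logistic model in which only the first
#' `n_signal` genes carry a non-zero log-odds coefficient. Used to measure
#' recovery rates of the L1 expression screen.
#'
#' @param n patients; @param n_genes total genes; @param n_signal planted
#'   signal genes; @param beta log-odds effect per signal gene;
#' @param seed integer seed.
#' @return list with `X` (matrix, columns `G0001`...), `y` (character
#'   vector of outcome labels) and `signal` (signal gene names).
#' @export
generate_planted_expression <- function(n = 400, n_genes = 200,
                                        n_signal = 5, beta = 1.5,
                                        seed = 1L) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * n_genes), n, n_genes,
              dimnames = list(NULL, sprintf("G%04d", seq_len(n_genes))))
  signal <- colnames(X)[seq_len(n_signal)]
  lp <- X[, seq_len(n_signal), drop = FALSE] %*% rep(beta, n_signal)
  y <- ifelse(stats::runif(n) < stats::plogis(lp), "deceased", "living")
  list(X = X, y = y, signal = signal)
}
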