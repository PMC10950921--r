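---
title: "Methods: multimodal outcome prediction and therapy-intensity recommendation for AML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal outcome prediction and therapy-intensity recommendation for AML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(amlrec)
```

## The model

`amlrec` predicts a binary clinical outcome — deceased versus living — for
Acute Myeloid Leukemia patients from three linked modalities (clinical
features, binary gene-mutation flags, continuous gene-expression values),
and converts the prediction into a therapy recommendation by intervening on
a single clinical feature, the treatment-intensity protocol. The modelling
assumptions, in decreasing order of importance:

* **Late fusion.** Each modality is modelled separately and the three
  fitted classifiers are fused only at the vote level. Nothing in the
  committee sees cross-modality interactions.
* **The treatment enters only the clinical modality.** Genetic classifiers
  never condition on treatment, so in the counterfactual sweep their scores
  are constant across protocols. A direct consequence (worth knowing when
  interpreting output): the *ranking* of protocols for a patient is decided
  entirely by the clinical member, because the genetic members add the same
  constant to every protocol's committee score. Treatment-by-gene effects
  are therefore structurally invisible to the recommender.
* **The sweep is a model intervention, not a causal estimate.** Setting
  `treatment_intensity` and re-scoring ignores confounding by indication.
  The synthetic generator has a confounded treatment-assignment policy
  (`treatment_policy = "eln_age"`) precisely so users can observe what that
  omission does; it is off by default.

## Pipeline stages and their parameters

**Cleaning (`preprocess_cohort`).** Fixed order: adult-AML filter
(diagnosis age ≥ 18 years, bone-marrow blasts ≥ 20%, both inclusive;
records missing either field are removed by this rule), missing-survival
filter, sample deduplication (bone-marrow-aspirate site, de-novo timepoint,
then one record per patient by stable input order), race binarisation
(`is_white` = 1 iff the normalised label is `white`), pruning of
never-mutated genes, and k-nearest-neighbour imputation. A record failing
several filters is attributed to the first-triggering rule in the cleaning
report. The site/timepoint rules are generalised to optional metadata
columns so synthetic and real cohorts share one code path; when the columns
are absent the rule is vacuous and logged.

**Imputation (`impute_knn`).** k = 3 neighbours by default. The distance is
the mean, over predictors observed in both records, of squared z-score
differences (numeric) and 0/1 mismatches (categorical); z-scores use
cohort-level statistics. Numeric targets receive the neighbour mean,
categorical targets the neighbour majority. Binary 0/1 indicators
(`is_white`) are imputed by majority, not mean, so they stay binary.
Distance ties break by stable input order, majority ties by the cohort's
modal category — every run is deterministic. The metric is a package
choice; only the neighbour count is inherited from the study design.

**Feature selection (`select_*`).** Clinical features are an expert list
(the 11-feature panel of `aml_clinical_panel()`), not a statistic. The
mutation screen runs an uncorrected Pearson χ² independence test per gene
(2×2 mutation-by-outcome table, df = 1) and keeps genes with p strictly
below 0.1. No continuity correction and no multiplicity correction: the
screen is a deliberately liberal filter ahead of supervised training, and
the uncorrected statistic is the default in the common ML stacks, which
makes the published 10-gene panel reproducible in kind. Zero-marginal
tables are degenerate (statistic 0, p = 1). The expression screen fits an
L1-penalised linear classifier (binomial deviance, `glmnet`) on
standardised columns and keeps genes with non-zero coefficients. The
penalty is parameterised as `C` with `lambda = 1/(n·C)`, matching the
convention in which the published screen's `C = 0.01` was stated. Because
the mapping involves `n` and the candidate-panel size changes what a
sensible penalty is, `C = 0.01` (suited to a 14,712-gene screen) empties a
22-gene panel: `select_expression_l1()` defaults to 0.01 for fidelity, but
`run_aml_pipeline()` defaults to `C = 1` and falls back to the full panel
(with a notice) should a screen return nothing. Screens are fitted on the
dedicated feature-selection fold, never on test data; a config switch
(`feature_select_scope = "all"`) widens them to all non-test records.

**Hold-out (`split_holdout`).** Fractions 70/10/10/10. Each held-out fold
gets ⌈fraction·n⌉ records from a seeded permutation, training the
remainder; the feature-selection fold rejoins the training data for model
fitting. At n = 272 this yields 28/28/28 held out and 216 records reaching
the fits — the only convention consistent with the published sizing. The
ensemble stage merges validation into training (the 9:1 scheme) before
refitting committee members.

**Models and grid (`train_with_grid`).** Random forest (`ranger`),
L2-penalised logistic regression (`glmnet`, `lambda = 1/(n·C)`), and SVM
(`e1071`, linear/RBF). The default grid reproduces the published search space: RF trees
{10..50} × leaf {1..4} × depth {8, 10, unlimited} × class weight; LR
C {1e-6 … 10} × class weight; SVM kernel × C {1e-6 … 1e-2} × class weight.
All other settings stay at library defaults. The objective is the
support-weighted F1 on the validation fold (chosen because a degenerate
majority predictor is then visible as a mid-range F1 with MCC 0 on an
imbalanced fold rather than a flat zero); ties break by grid order. Categorical features are one-hot encoded over training levels,
numeric features z-scored with training statistics. SVM margins are mapped
to probabilities by a logistic link fitted on the validation fold (at refit
time, on the refit data); if that fit degenerates the raw margin is passed
through a plain logistic squash. A probability of exactly 0.5 is labelled
deceased by convention.

**Committee (`build_committee`).** Best model per modality by validation
F1, ties to the earlier method in RF/LR/SVM order. Ballot size
⌈1/log₁₀(1/F1)⌉ with three boundary conventions chosen here: F1 = 0
silences the member (no evidence), F1 = 1 returns the cap (the formula is
singular), and the cap (default 100, reached near F1 ≈ 0.977) keeps votes
finite. The formula value is snapped to an integer when within 1e-12
before the ceiling, so exact powers of ten do not drift one vote upward
through floating-point noise. The committee label is the larger summed
ballot; weight-sum ties defer to the weight-averaged survive probability
against 0.5, then to deceased.

**Recommendation (`recommend_cohort`).** Only `treatment_intensity` is
intervened on; everything else, including the ELN risk label, is held
fixed. Exact score ties resolve to the canonical protocol order (target,
regular, low-intensity, high-intensity): under indifference the less
burdensome protocol is the clinically conservative, deterministic default.
No abstention threshold is imposed, but the margin is always reported and a
configurable `min_margin` raises a low-confidence flag. The probability
score ranks protocols; hard votes only decide the outcome label.

## The synthetic generator

`generate_cohort()` emulates the processed 272-patient study cohort:

* Continuous clinical features are drawn by inverse-CDF from truncated
  distributions so the published minima and maxima hold exactly; truncated
  normals for age (mean 56, sd 15, range 18–88), marrow blasts (70/24 on
  20–100) and peripheral blasts (37/28 on 0–99.2), truncated log-normals
  for the heavy-tailed WBC and for mutation counts. Shapes are a package
  choice fitted to the published min/median/mean/max; medians land within
  10% of the published values over 10,000 draws. The published WBC summary
  prints a median (39.44) above its mean (18.04), which a right-skewed
  positive quantity cannot satisfy; the generator targets the min, max and
  median and documents the discrepancy rather than resolving it.
* About 75% of patients are white; gender is mildly male-skewed;
  intermediate ELN risk is the largest group; regular and high-intensity
  therapy dominate the protocol mix.
* The outcome is drawn from a logistic model over standardised clinical
  covariates, per-gene mutation and expression effects, protocol main
  effects and a protocol-by-age interaction (high intensity harms older
  patients, helps younger ones — the contrast acts only on the low/high
  intensity protocols). Mutation effects act on prevalence-centred flags so
  the intercept alone pins the marginal outcome rate; expression covariates
  are standard normal, hence already centred.
* Ground truth records each patient's survival probability under all four
  protocols, the arg-max protocol and the realised outcome, enabling
  parameter-recovery testing.

What it does **not** emulate: gene–gene correlation, the multi-sample
pre-cleaning structure of the raw repositories (beyond the small dirty
fixture of `make_dirty_fixture()`), survival time (the outcome is the
binary label only), and any real biological linkage between the named
panel genes and AML. Passing tests on this generator demonstrate that the
pipeline recovers what it assumes — not that it would perform comparably on
real patients.

## Study conditions used by the test suite

The statistical suites fix their problem sizes as package choices:

* χ²-screen null calibration: 20 cohorts of 1,000 patients × 500
  outcome-independent genes at 30% prevalence (large cells keep the
  asymptotic test near its nominal level); pooled selection rate compared
  to α = 0.1 within three binomial standard errors.
* L1 recovery: 5 signal genes of 1.5 log-odds among 200, n = 400, screened
  at `C = 0.03`; the recovery bound (≥ 4 of 5, median of 20 seeds) was
  measured empirically before being frozen.
* Ensemble benefit: 30 cohorts of 2,000 patients whose three modalities
  carry comparable, independent signal, trained on a compact grid; the
  committee's test F1 is required to track the best of the nine individual
  models within 0.02 in at least 80% of seeds. Symmetric signal is the
  regime in which vote fusion can help; with one dominant modality the
  committee converges to that member.
* Recommendation recovery: protocol-by-age interaction strengths
  {1.5, 3, 6} on the deceased log-odds scale, 20 seeds each, training and
  evaluation cohorts of 800 patients; median accuracy against the
  generative optimum must beat the best single-protocol baseline at every
  strength and increase with it. Below a strength of about 1 the score
  differences near the decision boundary are smaller than random-forest
  estimation noise at this sample size, so weaker regimes are not part of
  the design.

## Known limitations

* Validation folds of tens of patients make grid-search winners noisy;
  validation F1 systematically overstates test F1 (winner's curse), which
  feeds directly into the ballot weights. The cap bounds the damage but
  cannot remove it.
* The recommender inherits every bias of the clinical member; with a
  treatment-blind committee all four scores tie and the canonical-order
  fallback (target) is returned with a flag.
* No uncertainty accompanies the recommendation beyond the score margin.
* The L1 expression screen here uses binomial deviance loss; stacks that
  implement the L1-penalised squared-hinge loss select very similar
  supports on standardised inputs, but coefficients are not comparable
  across the two losses.
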