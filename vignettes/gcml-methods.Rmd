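---
title: "G-computation with machine-learning Q-models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G-computation with machine-learning Q-models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcml)
```

## The estimand and the estimator

We target the average causal effect (ACE) of a binary exposure $Z$ on a
binary outcome $Y$ on the risk-difference scale,
$ACE = E[Y(1) - Y(0)]$, where $Y(1)$ and $Y(0)$ are the potential
outcomes under exposure and non-exposure. Under consistency,
conditional exchangeability given the measured pre-exposure covariates
$X = (X_1, \dots, X_k)$, and positivity, the ACE is identified by
standardization and estimated by G-computation:

1. fit an outcome regression (the *Q-model*) $f(Y \mid Z, X)$ on the
   observed data — the exposure must remain a predictor;
2. for every individual $i$, predict both counterfactual outcome
   probabilities, $\hat Y_i(1) = \hat f(Y \mid 1, X_i)$ and
   $\hat Y_i(0) = \hat f(Y \mid 0, X_i)$, keeping the covariates at
   their observed values;
3. average: $\widehat{ACE} = n^{-1} \sum_i [\hat Y_i(1) - \hat Y_i(0)]$.

The package treats the Q-model as pluggable. Candidates are a lasso
logistic regression (LLR), an elastic-net logistic regression (ELR), a
single-hidden-layer neural network (NN), a radial-kernel support vector
machine (SVM), boosted classification trees (BCART), an AUC-weighted
super learner (SL) over the first four, and — as the parametric
comparator — a plain unpenalized logistic regression (GLM) on the raw
covariates. G-computation itself makes no assumption about the form of
the Q-model; everything rests on the Q-model approximating
$f(Y \mid Z, X)$ well.

## The flexible design

For the penalized regressions, flexibility comes from the feature
matrix rather than the learner: each continuous covariate is expanded
in a cubic b-spline basis, and every covariate (basis) column is paired
with an exposure-interaction column, so exposure effects can vary
across covariate levels.

Decisions that were genuinely open, and how we fixed them:

- **Spline complexity.** Default `spline_df = 3`, cubic, no interior
  knots — the minimal flexible expansion. With 9–22 covariates and all
  interactions, richer bases overwhelm $n = 100$, the smallest sample
  size the package is designed around. Boundary knots sit at the
  training minimum/maximum, interior knots (when `spline_df` exceeds
  the degree) at training quantiles. Both are fitted state: they come
  from the training data only and are reused verbatim for
  counterfactual and out-of-bag prediction.
- **Out-of-range evaluation.** Bootstrap and out-of-bag rows can fall
  outside the training range; a cubic polynomial extrapolates wildly
  there. Values are therefore clamped to the boundary knots before
  basis evaluation.
- **Interactions.** Interactions are formed between the exposure and
  every expanded column (basis column × $Z$), not the raw covariate
  only, so the exposure effect can be non-linear in a covariate.
  Covariate-by-covariate interactions are deliberately out of scope.
- **The constant basis column is dropped**; the intercept belongs to
  the learner. Consequently the returned basis row-sums lie in $[0,1]$
  and the dropped column equals one minus the row sum (partition of
  unity), which the tests exploit as an exact invariant.
- **Standardization.** Only the scale-sensitive learners (NN, SVM) see
  z-scored inputs; the penalized regressions standardize internally
  per their own convention. Training means/SDs are fitted state.

## Tuning and the super learner

Tuning parameters are chosen by maximizing the mean area under the ROC
curve (AUC) over a 10-fold outcome-stratified cross-validation, with a
tuning grid of 20 candidates per learner. The AUC is computed by
midranks (exactly the pairwise-concordance fraction, with ties counting
one half). Design choices:

- **Grid semantics.** "Grid length 20" means 20 candidate
  *combinations* per learner. Single-parameter learners get 20 values
  spanning the range (log-spaced for penalties, cost and kernel width;
  consecutive integers for the NN hidden-layer size); multi-parameter
  learners get a seeded Latin-hypercube, since a per-parameter
  Cartesian product would explode for the four BCART parameters.
- **Default ranges** (configurable): penalty $10^{-4}..10^2$; mixing
  $0..1$; NN size $1..20$; SVM cost $2^{-5}..2^{10}$ and kernel width
  as a multiplier $2^{-3}..2^3$ of the median-heuristic width; trees
  $50..1000$; depth $1..4$; learning rate $0.001..0.3$; minimum node
  size $5..20$.
- **Tie-breaking** favours the least complex combination at equal CV
  AUC: largest penalty, smallest network, smallest cost, fewest trees.
- **The SL combines on the logit scale**: member probabilities are
  clipped to $[10^{-6}, 1 - 10^{-6}]$ (keeping logits finite), their
  logits convexly combined with simplex weights, and the result passed
  through the inverse logit. A probability-scale average is available
  behind a flag. Weights maximize the AUC of the combined out-of-fold
  member predictions. Because the AUC is piecewise constant in the
  weights, the search is gradient-free: all vertices (so the SL can
  never rank worse than its best member out-of-fold), the uniform
  point, seeded Dirichlet starts, and a Nelder–Mead polish on the
  softmax scale; exact ties resolve towards the most uniform weights.
  BCART is excluded from the ensemble for computational reasons.

## Variance: bootstrap cross-validation

Refitting the entire tuning pipeline inside every bootstrap resample is
prohibitive, so tuning parameters are chosen once on the full sample
and frozen. Each of $B$ iterations (default 500) draws $n$ rows with
replacement, retrains the Q-model on the resample, and evaluates the
ACE **on the out-of-bag rows only** (expected fraction
$(1 - 1/n)^n \approx 36.8\%$), which counteracts optimism from
overfitting. The standard error is the sample SD of the $B$ draws.

Open points we settled:

- **CI construction**: percentile interval by default; a
  normal-approximation interval is available behind a flag.
- **SL weights inside the bootstrap** are re-estimated on each
  resample — weight estimation is part of training — while member
  tuning parameters stay frozen; `sl_freeze_weights = TRUE` freezes
  the weights too.
- **Degenerate resamples** (single outcome class or exposure group, or
  an empty out-of-bag set) are redrawn, at most 100 times per
  iteration, so B completed draws are always reported; redraw counts
  are returned.
- The reported point estimate is the full-sample fit, not the mean of
  the bootstrap draws, matching the estimator's definition.

## The simulation scenarios

Two shipped presets span the difficulty range. The *realistic* scenario
has 22 sequentially dependent covariates (normal and Bernoulli
marginals, each depending linearly — on the mean or logit scale — on up
to two earlier covariates); nine enter the outcome model: four
linearly, three as centered quadratics, two as step functions, and one
interacts with the exposure. The *simplistic* scenario has nine
mutually independent covariates, six with linear outcome effects and no
interaction. Exposure and outcome are Bernoulli with logit-linear
probabilities in $X$ and $(X, Z)$ respectively.

The preset coefficient values are this package's own synthetic
calibration (the file names and scenario names say so): they were
chosen once to give realistic epidemiological magnitudes — log-odds
ratios between 0.2 and 0.6, exposure prevalence near 0.40, outcome
prevalence near 0.35–0.45, and a true marginal ACE near +0.10 — and
reproduce the documented *structure* of the two settings. They are not
tied to any external cohort. What the generator does **not** emulate:
measurement error, missingness (the cohort contract forbids it),
unmeasured confounding, mediators or colliders, non-logit link
functions, and heavy-tailed covariates. Passing tests therefore speak
to estimator behaviour under a correctly structured world, not to
robustness against those features.

The **theoretical ACE** of a scenario is computed by Monte Carlo:
datasets are generated with $Z \sim \text{Bernoulli}(1/2)$ drawn
independently of $X$, a univariate logistic model of $Y$ on $Z$ is
fitted to each, and $\text{expit}(b_0 + b_1) - \text{expit}(b_0)$ is
averaged over datasets (defaults: 1000 datasets of 10,000 rows; the
Monte-Carlo SE is reported so adequacy is checkable). With a binary
$Z$ that univariate logistic contrast equals the difference of group
means exactly, which is how it is evaluated. Randomizing $Z$ removes
confounding, so the average contrast converges to the true marginal
risk difference; its value is invariant to the randomization
probability up to Monte-Carlo error, which the tests check.

## Performance criteria

Given replicate estimates $\widehat{ACE}_r$ with bootstrap SEs and CIs,
and the true value $\Delta$:

- mean bias $MB = 100 \cdot \text{mean}(\widehat{ACE}_r - \Delta)$
  (percentage points on the risk-difference scale);
- $RMSE = \sqrt{\text{mean}[(\widehat{ACE}_r - \Delta)^2]}$, with the
  uncorrected ($n$) denominator;
- $ESD$: sample SD of the estimates ($n-1$ denominator; the
  uncorrected variant is also exposed, and with it
  $RMSE^2 = \text{bias}^2 + ESD_\text{unc}^2$ holds to $10^{-12}$,
  which is a frozen test invariant);
- $ASD$: mean of the bootstrap SEs;
- $VEB = 100 (ASD - ESD)/ESD$, on the SD scale by default (the
  variance-scale variant sits behind a flag);
- coverage: share of CIs containing $\Delta$; power: share of CIs
  excluding zero (the pipeline provides no other test statistic, so
  the CI-based decision is the power construct).

Calibration curves use equal-frequency (quantile) bins of the predicted
probabilities, merging bins when there are fewer distinct predictions
than requested.

## Numerical choices and degenerate inputs

- Probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ everywhere before
  logits are taken.
- Outcome-stratified fold assignment is round-robin within class, so
  fold sizes differ by at most one per class; if the minority class has
  fewer members than folds the plan fails loudly (inside bootstrap
  resamples it instead shrinks the fold count, where the alternative
  would abort a long run).
- `glm.fit` runs with a tightened IRLS tolerance ($10^{-12}$) so the
  saturated-model identity with exact standardization holds to
  $10^{-10}$.
- Cohorts are validated strictly: 0/1 coding, no missing values
  (rejection, never imputation), $n \ge 20$ so folds and out-of-bag
  sets are non-degenerate, both exposure groups and outcome classes
  present, explicit (never inferred) binary/continuous tagging.
- All randomness descends from one master seed; per-replicate seeds are
  a deterministic function of (master seed, replicate index), so
  results are independent of scheduling and resumable mid-run.

## Problem sizes used by the shipped checks

The full published-scale study (10,000 replicates × 500 bootstrap
iterations × six learners × three sample sizes × two scenarios) is
cluster work. The package's own test suite and the acceptance script
run a scaled-down version chosen to keep statistical checks sharp at
desk scale: 1000 replicates of $n = 500$ for the null-effect check,
500 replicates of $n = 1000$ with $B = 200$ for the bias/coverage
check of the correctly specified comparator, 150 replicates with
$B = 100$ for the reported simplistic-scenario table, and a
5-fold, grid-length-5, $B = 40$ four-member super-learner run on one realistic
cohort of $n = 200$. At these sizes coverage and power estimates carry
Monte-Carlo error of roughly ±2–4 percentage points, which the test
bands accommodate.

## Known limitations

- Exposure and outcome must both be binary; no survival outcomes,
  continuous exposures, or multi-level exposures.
- The ACE is for the whole sample; the effect among the exposed is not
  estimated.
- Doubly robust estimators (TMLE, AIPW) and propensity-score methods
  are out of scope: this package is the outcome-modelling arm.
- Covariate selection is the analyst's task. The package never drops
  mediators, colliders or instruments for you, and a well-predicting
  Q-model does not by itself guarantee an unbiased causal estimate —
  identification is an assumption, not an output.
- BCART is available as a Q-model but excluded from the SL; random
  forests are not offered at all because the exposure cannot be held
  as a forced predictor in small samples.

## A worked call

```{r example, eval = FALSE}
sc <- scenario_preset("simplistic")
cohort <- simulate_cohort(sc, n = 500, seed = 42)
cfg <- run_config(learner_id = "LLR", n_boot = 200, seed = 42)
est <- gc_estimate(cohort, cfg)
print(est)
```
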