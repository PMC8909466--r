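---
title: "Multitask longitudinal radiomics survival modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask longitudinal radiomics survival modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(flsglboost)
```

## The modelling problem

Early-phase imaging trials collect quantitative (radiomic) features from
tumour regions at several time points — typically before treatment and a few
weeks into it — for a few dozen patients, and follow them for overall
survival. The analysis problem has three linked difficulties: the feature
table is much wider than the cohort (here roughly 110 features per modality
and time point against ~45 patients), the features are strongly redundant
within families (shape, first-order intensity, texture matrices), and the
outcome is right-censored. `flsglboost` implements a two-stage pipeline for
this setting:

1. **FLSGL** — a *fused Laplacian sparse group LASSO* that selects features
   jointly across imaging time points, treating each time point as a related
   regression task; and
2. **CWGBS** — *component-wise gradient boosting* under the Cox
   partial-likelihood loss, which turns the selected features into a
   censoring-aware risk score and per-patient survival curves.

Both stages sit inside a stratified, repeated cross-validation harness so
every reported metric is an out-of-fold quantity.

## Stage 1: fused Laplacian sparse group LASSO

Let $X_t \in \mathbb{R}^{N\times F}$ be the standardized feature matrix at
time point $t = 1,\dots,T$ and $y$ the shared regression target (one value
per patient). With the coefficient matrix
$\Phi = (\varphi_1,\dots,\varphi_T) \in \mathbb{R}^{F\times T}$, the fit
minimizes

$$
\sum_{t=1}^T \lVert y - X_t\varphi_t\rVert^2
 + \beta_1\lVert\Phi\rVert_1
 + \beta_2\sum_{i=1}^F \lVert\Phi_{i\cdot}\rVert_2
 + \beta_3\lVert\Phi G\rVert_1 .
$$

The three penalties have distinct scientific roles:

* $\beta_1$ (elementwise L1) enforces within-task sparsity;
* $\beta_2$ (row-wise L2,1 group norm) makes selection a *per-feature*
  decision shared across all time points — a feature is in or out of the
  signature as a whole;
* $\beta_3$ penalizes the L1 norm of the fusion residuals $\Phi G$, where
  $G$ has unit diagonal and $-w_{r,t}$ off the diagonal. The weights
  $w_{r,t}$ are normalized Gaussian-kernel evaluations of the task index
  distance ($\sigma$ = bandwidth, default 1), so each task's coefficients
  are shrunk toward the kernel-weighted average of the other tasks':
  temporal smoothness of the signature. With two time points each column of
  $\Phi G$ is simply $\varphi_1 - \varphi_2$ (up to sign), a fused
  difference penalty.

The kernel must decay with distance for the weights to be meaningful, so the
standard Gaussian $K(x) = \tfrac{1}{\sigma\sqrt{2\pi}}
e^{-x^2/(2\sigma^2)}$ is used.

### Solver

The objective is convex but has three non-smooth terms coupled through $G$.
Two solvers are provided and cross-checked against each other in the test
suite:

* **Monotone accelerated proximal gradient (default, `solver = "apg"`).**
  The penalty is separable across coefficient *rows*, and for $T \le 2$ the
  row-wise proximal operator has an exact closed form obtained by composing
  the fused-difference prox, elementwise soft-thresholding and group
  soft-thresholding, in that order (the composition is exact for
  chain-structured fusion). For $T \ge 3$, where the dense fusion matrix
  breaks the chain structure, the row prox is solved by a short inner
  splitting iteration. The outer loop is MFISTA: an accelerated proximal
  gradient step whose candidate is accepted only if it does not increase the
  objective, with momentum restart otherwise. This gives a guaranteed
  non-increasing objective trace — the property the solver regression tests
  assert — and exact zeros in the reported coefficients.
* **Multiblock ADMM (`solver = "admm"`).** Splitting variables $Z_1 = \Phi$
  (L1 prox), $Z_2 = \Phi$ (group prox) and $P = \Phi G$ (fused prox) with
  scaled duals and augmented-Lagrangian penalty $\delta$ (default 10); the
  smooth block is a linear solve whose normal matrix is factorized once.
  ADMM is not a descent method: its objective trace shows small transient
  oscillations during the dual warm-up phase, which is why it is not the
  default even though both solvers agree on the optimum to well below test
  tolerances (the suite asserts agreement to a relative gap of $10^{-6}$,
  and agreement of the pure-L1 special case with an independent
  coordinate-descent LASSO to $10^{-4}$ per coefficient).

Both solvers start from $\Phi = 0$ with zero duals; the problem is convex,
so initialization affects only the path, and fits are deterministic.
Convergence uses `tol = 1e-6` (relative iterate change and objective change
for APG; primal and dual residuals for ADMM) with `max_iter = 2000` by
default. A feature is *selected* when any of its per-task coefficients
exceeds `selection_threshold = 1e-3` in absolute value, ordered by
descending maximum absolute coefficient with index ties.

Degenerate inputs are rejected up front: non-finite entries, misaligned
tasks, and all-zero feature columns (which cannot be standardized) raise
errors; a solver that exhausts `max_iter` returns its result with a
convergence flag and a warning rather than an exception.

### Target and penalty scale

The regression target of the selection stage is observed follow-up time —
censored values included, which biases the linear fit but is corrected
downstream by the boosting stage's censoring-aware loss. Two practical
choices are exposed through `flsgl_config()` / `pipeline_config()`:

* **`log_time`.** Under the proportional-hazards event model used by the
  generator (and plausibly by real survival data), *log* time is linearly
  related to the risk score while raw time is a curved transform of it. The
  pipeline therefore selects on log time by default; raw time remains the
  `fit_flsgl()` default for generic use.
* **`relative` penalties.** Absolute penalty weights are only meaningful
  relative to the scale of $\sum_t\lVert y - X_t\varphi_t\rVert^2$, which
  grows with the cohort size and the target's variance. With
  `relative = TRUE`, penalties are fractions of the data's penalty ceiling
  $\lambda_{\max} = 2\max_i \lVert (X_1'y,\dots,X_T'y)_i \rVert_2$ (the
  smallest group penalty that zeroes everything, the analogue of glmnet's
  `lambda.max`), making a setting like "45% of ceiling" transferable across
  folds and datasets. The pipeline default is a group-dominant mix
  $(\beta_1,\beta_2,\beta_3) = (0.05, 0.45, 0.05)\,\lambda_{\max}$: joint
  selection carries most of the regularization, with light elementwise and
  fusion shrinkage. Tuned absolute values from a nested grid search can be
  used instead via `grid =` in `run_experiment()`.

## Stage 2: component-wise gradient boosting survival

Given the pooled standardized values of the selected features (each
selected feature contributes one column per modality and time point), the
booster minimizes the negative Cox partial log-likelihood with Breslow tie
handling. Each stage computes pseudo-responses — the negative gradient of
the loss at the current additive score — fits a simple least-squares line to
every feature separately, and adds `learning_rate` times the single
best-fitting component to the score. Consequences:

* a model with $k$ stages references at most $k$ distinct features, so the
  booster is itself a second, censoring-aware selection step;
* the default budget of **15 stages with learning rate 1** keeps final
  models small (typically 1–8 distinct features at cohort scale);
* the training loss is non-increasing across stages in practice (asserted
  by the tests over many seeds), because each component is a damped,
  regression-scaled step along the negative gradient.

A regression-stump base learner is available (`base_learner = "stump"`) but
component-wise least squares is the default: it is the canonical
"component-wise" learner and keeps the additive score linear.

Survival probabilities come from the Breslow baseline cumulative hazard
$\hat H_0$ estimated on the training fold at the final scores:
$S_i(t) = \exp(-\hat H_0(t)e^{f_i})$. Horizons beyond the last training
time extrapolate $\hat H_0$ as constant, with a warning. A point estimate
of survival time is offered as the median of $S_i$ (a convention — the
mapping from risk score to a single time is not canonical).

## Evaluation

* **Harrell c-index**: comparable pairs are strictly-shorter-time pairs
  whose shorter member had the event; risk ties count one half; tied-time
  pairs are excluded. The implementation is cross-checked against
  `survival::concordance` (which additionally counts certain tied-time
  pairs) on tie-free data, and against exhaustive pair enumeration.
* **95% interval**: percentile interval of the per-repeat c-index across
  the 15 CV repeats. This is a spread-of-replicates convention, not a
  patient-level bootstrap.
* **IPCW Brier score and IPA** at a 24-month horizon: the Graf estimator
  with censoring weights from the reverse Kaplan–Meier curve; patients
  censored before the horizon contribute nothing, and terms whose censoring
  weight is zero are dropped with a warning. IPA is
  $100\,(1 - \mathrm{Brier}_{\text{model}}/\mathrm{Brier}_{\text{null}})$
  with the Kaplan–Meier curve as the null model, so the null scores 0 and a
  perfect model 100.
* **Risk stratification**: patients are split at the median of their
  repeat-averaged out-of-fold risk and the two Kaplan–Meier curves are
  compared by a log-rank test.
* **Model comparison**: Friedman rank test across models with CV repeats as
  blocks (midranks for ties; a fully tied score matrix is reported as
  statistic 0, p 1), and two-sided Wilcoxon signed-rank tests against a
  designated benchmark with zero differences dropped. Kaplan–Meier,
  log-rank, Friedman and Wilcoxon computations are delegated to the
  `survival` and `stats` packages behind these wrappers; the c-index, Cox
  gradient/loss, Breslow baseline and IPCW Brier/IPA are implemented here.

## Cross-validation harness

`run_experiment()` runs stratified k-fold cross-validation (default 10
folds) repeated 15 times with seeds `seed + repeat - 1`. Stratification
deals shuffled event and censored strata separately across folds, so fold
sizes differ by at most one and per-fold event counts by at most one from
proportional. Inside each training fold, in order: per-feature
standardization (training statistics only; columns constant on the training
rows are dropped for that fold), optional nested grid search (inner
stratified 3-fold CV maximizing pooled inner c-index, ties broken toward
stronger regularization), FLSGL selection per modality, pooling of selected
columns, boosting, and prediction of the held-out fold. A fold in which
nothing is selected falls back to the top single feature by absolute
coefficient, with a warning, so every fold produces predictions.

Four modes reuse the same harness: `multitask` (joint selection across both
time points), `single_task_pre` / `single_task_mid` (one time point), and
`delta` (mid − pre feature differences, the delta-radiomics benchmark).
"Ensembling" of the selected features means the booster consumes their
*values* (per modality and time point), not the per-task linear predictions;
the per-task linear outputs serve selection only, and the final risk is the
booster's.

## The synthetic cohort generator

Real trial data of this shape is not redistributable, so every experiment in
the package runs on `generate_cohort()`, which emulates the *structure* of a
longitudinal imaging trial: 45 patients; 110 features per modality and time
point in correlated blocks of 10 (within-block correlation 0.5), mimicking
redundant feature families; mid-treatment features evolving from
pre-treatment ones with correlation 0.7; a 5-feature planted signature with
effects in $\pm[0.7, 1]$, at most one per block (signatures span distinct
feature families), drifting at most 20% between time points; Weibull
proportional-hazards event times (shape 1.5 — a rising hazard — and scale 30
months, putting median survival near two years); and independent Weibull
censoring whose scale is calibrated by bisection to a 40% censoring
fraction (≈60% events). The true log-hazard is scaled to standard deviation
`hazard_scale = 2.5`; this value was fixed so that the planted signature is
actually recoverable from 200 patients (a designed property of the
generator — at weaker signal even a Cox-likelihood LASSO oracle cannot
reach high recovery, so recovery tests would measure luck, not method),
while cohort-scale *fitted* models still land in the concordance range
reported for real radiomics signatures (≈0.7), well below the oracle bound
the generator also reports.

What the generator does **not** emulate: non-Gaussian marginal feature
distributions, feature-outcome nonlinearities beyond the proportional
hazards link, informative censoring, scanner batch effects, missing
scans, and inter-feature correlation structure richer than equicorrelated
blocks. Passing tests on these cohorts therefore demonstrate correctness of
the machinery and the *relative* behaviour of the modes (multitask vs
single time point vs delta), not clinical performance on any real trial.

## Problem sizes used by the tests

The suite exercises: solver oracles at $N = 50$, $F = 30$ over 20 seeds and
three penalty levels; signature recovery at $N = 200$, $F = 110$, $T = 2$
over 10 seeds; the full 10-fold × 15-repeat pipeline on one 45-patient
cohort for the mode comparison; and 5-fold × 2-repeat runs on ten
pure-noise cohorts for null calibration. These sizes were chosen so each
property is measured with enough replication to be stable while the whole
suite stays quick to run.

## Known limitations

* The selection stage's least-squares target treats censored times as
  observed, which attenuates coefficients when censoring is heavy; only the
  boosting stage is censoring-aware. This mirrors the two-stage design the
  package implements, but a censoring-aware selection stage (e.g. Cox-loss
  FLSGL) would be a natural extension.
* With a single time point the group and fusion penalties collapse into the
  L1 term, so `single_task_*` modes are effectively LASSO + boosting.
* The percentile interval over CV repeats understates patient-level
  sampling uncertainty; repeats share the same cohort.
* The exact prox composition used by the default solver covers $T \le 2$;
  for $T \ge 3$ the row prox is iterative and the solver falls back to a
  (tight) numerical inner solve.
* Time-dependent ROC curves are not implemented; discrimination is
  summarized by the c-index and calibration-plus-discrimination by IPA.
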