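# flsglboost

Multitask survival modelling for longitudinal radiomics: joint feature
selection across imaging time points with a **fused Laplacian sparse group
LASSO (FLSGL)**, ensembled with **component-wise gradient boosting survival
(CWGBS)** under the Cox partial-likelihood loss, evaluated by stratified
repeated cross-validation.

## Who this is for

Analysts of early-phase imaging trials (or any small cohort with wide,
redundant feature tables measured at several time points and a
right-censored outcome) who want to ask: *does learning the pre- and
mid-treatment feature signatures jointly predict survival better than a
single time point, or than feature differences (delta radiomics)?* The
package provides the selection model, the boosting survival model, the
cross-validation harness that keeps every fitted quantity out-of-fold, the
usual survival metrics, and a seeded synthetic-cohort generator with known
ground truth so the whole pipeline is testable without any trial data.

## The model

Feature matrices $X_t \in \mathbb{R}^{N\times F}$ (one per time point
$t = 1..T$, standardized) and a shared target $y$ enter the penalized
multitask regression

$$
\min_\Phi \sum_{t=1}^T \lVert y - X_t\varphi_t\rVert^2
 + \beta_1\lVert\Phi\rVert_1
 + \beta_2\sum_{i=1}^F\lVert\Phi_{i\cdot}\rVert_2
 + \beta_3\lVert\Phi G\rVert_1,
$$

where $\Phi = (\varphi_1,\dots,\varphi_T)$ and $G$ encodes kernel-smoothed
task relations (unit diagonal, $-w_{r,t}$ off-diagonal, with Gaussian-kernel
weights normalized over $r \ne t$). The L1 term gives within-task sparsity,
the L2,1 row norm selects each feature jointly across time points, and the
fused term $\lVert\Phi G\rVert_1$ makes the signature vary smoothly over
time. Features selected by FLSGL (rows of $\Phi$ with any coefficient above
a threshold) feed a component-wise gradient boosting model: each stage fits
the Cox negative gradient with a single-feature least-squares learner (at
most 15 stages, learning rate 1), yielding a risk score and — through a
Breslow baseline hazard — per-patient survival curves. Metrics: Harrell
c-index with a percentile interval over CV repeats, IPCW Brier score and
index of prediction accuracy (IPA) at a 24-month horizon against a
Kaplan–Meier null, median-risk Kaplan–Meier stratification with a log-rank
test, and Friedman / Wilcoxon signed-rank model comparisons across repeats.

See the methods vignette
(`vignettes/multitask-radiomics-survival.Rmd`) for the solver design
(monotone accelerated proximal gradient with exact composite prox; a
multiblock ADMM alternative), penalty scaling, and every defaulted design
choice.

## Worked example

```r
library(flsglboost)

# a synthetic 45-patient cohort: 110 features x {pre, mid} x FDG-PET,
# 5-feature planted signature, ~60% events
cohort <- generate_cohort(seed = 1)

# joint selection across the two time points
tasks <- task_matrices(cohort$features)
fit <- fit_flsgl(lapply(tasks$FDG_PET, scale), cohort$outcomes$time,
                 pipeline_config())
fit
#> Fused Laplacian sparse group LASSO fit
#>   110 features x 2 tasks, n = 45
#>   penalties: beta1 = 4.40345, beta2 = 39.631, beta3 = 4.40345
#>   solver apg: 63 iterations, converged; objective 646.063
#>   selected features: 6

# the full cross-validated pipeline (selection + boosting, all in-fold)
ex <- run_experiment(cohort$features, cohort$outcomes, mode = "multitask",
                     folds = 10, repeats = 5, seed = 1)
ex
#> Cross-validated survival prediction experiment
#>   mode: multitask, selector: flsgl, 10-fold CV x 5 repeats
#>   mean c-index: 0.735 [0.713, 0.747], mean IPA: 29.2% at t = 24

risk_stratification(ex)$log_rank
#> # A tibble: 1 × 3
#>   statistic    df p_value
#>       <dbl> <dbl>   <dbl>
#> 1      8.83     1 0.00297
```

The mean c-index is the average over repeats of the pooled out-of-fold
concordance (bracketed: 2.5%/97.5% percentiles across repeats); IPA is the
percent reduction in IPCW Brier score at 24 months relative to the
Kaplan–Meier null (0 = no better than ignoring all features). The log-rank
row tests the separation of the Kaplan–Meier curves of the above-median and
below-median aggregated risk groups. `tidy()`, `glance()` and `autoplot()`
methods are available for fitted objects, experiments and comparisons, and
`compare_experiments()` runs the Friedman/Wilcoxon tests across modes
(`multitask`, `single_task_pre`, `single_task_mid`, `delta`).

A thin command-line front end (`inst/cli/flsglboost`) exposes `simulate`,
`fit`, `cv` and `compare` subcommands over CSV tables.

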