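#' Harrell concordance index
#'
#' Fraction of comparable patient pairs in which the patient with the
#' shorter observed time (who must have had the event) also has the higher
#' predicted risk. Ties in risk count one half; pairs with equal observed
#' times are not comparable.
#'
#' @param time,event Right-censored follow-up times and 0/1 event indicators.
#' @param risk Numeric risk scores (higher = worse prognosis).
#'
#' @return Concordance in `[0, 1]`.
#' @export
c_index <- function(time, event, risk) {
  check_survival_args(time, event)
  assert_that(length(risk) == length(time) && all(is.finite(risk)),
              "`risk` must be finite and match the outcomes")
  # pair (i, j) comparable iff time_i < time_j and event_i == 1
  shorter <- outer(time, time, `<`)
  comparable <- shorter & (event == 1)
  n_pairs <- sum(comparable)
  if (n_pairs == 0) {
    stop("no comparable pairs: concordance is undefined", call. = FALSE)
  }
  risk_diff <- outer(risk, risk, `-`)
  concordant <- sum(comparable & (risk_diff > 0))
  tied <- sum(comparable & (risk_diff == 0))
  (concordant + 0.5 * tied) / n_pairs
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, as a tidy step-function
#' table. A thin wrapper over [survival::survfit()].
#'
#' @param time,event Right-censored follow-up times and 0/1 event indicators.
#'
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`: the curve starts at `S(0) = 1` and drops only at event
#'   times.
#' @export
km_curve <- function(time, event) {
  check_survival_args(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tibble::tibble(time = c(0, fit$time),
                 n_risk = c(length(time), fit$n.risk),
                 n_event = c(0, fit$n.event),
                 n_censor = c(0, fit$n.censor),
                 survival = c(1, fit$surv))
}

# Right-continuous step function S(t) from a KM table; also used for the
# censoring distribution. Returns a function of t.
km_stepfun <- function(time, event) {
  curve <- km_curve(time, event)
  stats::stepfun(curve$time[-1], curve$survival, right = FALSE)
}

# Left limit S(t-) of a KM step function.
km_stepfun_left <- function(time, event) {
  curve <- km_curve(time, event)
  knots <- curve$time[-1]
  vals <- curve$survival
  function(t) {
    idx <- findInterval(t, knots, left.open = TRUE)
    vals[idx + 1]
  }
}

#' Inverse-probability-of-censoring-weighted Brier score
#'
#' Graf estimator of the expected squared error between a predicted survival
#' probability at a fixed horizon and the observed status, reweighted for
#' right censoring by the Kaplan-Meier estimate of the censoring
#' distribution fit on the training outcomes. Patients who die before the
#' horizon contribute `S_i^2 / G(T_i-)`; patients still at risk past the
#' horizon contribute `(1 - S_i)^2 / G(horizon)`; patients censored before
#' the horizon contribute nothing. With no censoring the score reduces to
#' the plain Brier score.
#'
#' @param time,event Test-set outcomes.
#' @param surv_prob Predicted probability of surviving past `horizon`, one
#'   per test patient.
#' @param horizon Evaluation time (same units as `time`).
#' @param train_time,train_event Outcomes used to estimate the censoring
#'   distribution; default to the test outcomes.
#'
#' @return Nonnegative scalar Brier score.
#' @export
ipcw_brier <- function(time, event, surv_prob, horizon,
                       train_time = time, train_event = event) {
  check_survival_args(time, event)
  assert_that(length(surv_prob) == length(time) &&
                all(surv_prob >= 0 & surv_prob <= 1),
              "`surv_prob` must be probabilities, one per test patient")
  assert_that(horizon > 0, "`horizon` must be positive")
  g_left <- km_stepfun_left(train_time, 1 - train_event)
  g_fun <- km_stepfun(train_time, 1 - train_event)

  died <- time <= horizon & event == 1
  alive <- time > horizon
  g_died <- g_left(time[died])
  g_h <- g_fun(horizon)
  if (any(g_died == 0) || (any(alive) && g_h == 0)) {
    warning("censoring survival is zero at some required times: ",
            "affected terms dropped", call. = FALSE)
  }
  contrib <- numeric(length(time))
  ok_d <- which(died)[g_died > 0]
  contrib[ok_d] <- (surv_prob[ok_d])^2 / g_left(time[ok_d])
  if (g_h > 0) {
    contrib[alive] <- (1 - surv_prob[alive])^2 / g_h
  }
  sum(contrib) / length(time)
}

#' Index of prediction accuracy
#'
#' Percent improvement of a model's Brier score over a null (reference)
#' model, `100 * (1 - brier_model / brier_null)`. The conventional null is
#' the Kaplan-Meier curve of the training data, which ignores all features;
#' the null model itself has IPA zero, a perfect model 100, and a model
#' worse than the null a negative value.
#'
#' @param brier_model,brier_null Brier scores at the same horizon.
#'
#' @return IPA in percent.
#' @export
ipa <- function(brier_model, brier_null) {
  assert_that(is.finite(brier_null) && brier_null > 0,
              "`brier_null` must be positive: IPA is undefined otherwise")
  100 * (1 - brier_model / brier_null)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square test (1 df) comparing the survival curves of
#' two groups; wraps [survival::survdiff()].
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Two-level grouping vector (factor, character or logical).
#'
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @export
log_rank_test <- function(time, event, group) {
  check_survival_args(time, event)
  group <- as.factor(group)
  assert_that(nlevels(droplevels(group)) == 2,
              "`group` must have exactly two levels")
  assert_that(sum(event) > 0, "log-rank test needs at least one event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  tibble::tibble(statistic = fit$chisq, df = 1,
                 p_value = stats::pchisq(fit$chisq, df = 1,
                                         lower.tail = FALSE))
}

#' Friedman rank test across models
#'
#' Nonparametric repeated-measures comparison of several models evaluated on
#' the same blocks (here: cross-validation repeats). Wraps
#' [stats::friedman.test()]; ranks within blocks use midranks for ties, so
#' the test is invariant to any monotone transform of the scores within a
#' block.
#'
#' @param scores `models x blocks` numeric matrix of performance scores
#'   (e.g. per-repeat c-index), with model names as row names.
#'
#' @return A one-row tibble with `statistic`, `df` and `p_value`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  assert_that(nrow(scores) >= 2 && ncol(scores) >= 2,
              "need at least 2 models and 2 blocks")
  # fully tied blocks carry no ranking information: the statistic is zero
  if (all(apply(scores, 2, function(col) diff(range(col)) == 0))) {
    return(tibble::tibble(statistic = 0, df = nrow(scores) - 1, p_value = 1))
  }
  # friedman.test expects blocks in rows and treatments in columns
  res <- stats::friedman.test(t(scores))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value)
}

#' Wilcoxon signed-rank test for paired model scores
#'
#' Two-sided paired comparison of two models' per-block scores; wraps
#' [stats::wilcox.test()] with zero differences dropped (the signed-rank
#' convention).
#'
#' @param a,b Paired numeric vectors (e.g. per-repeat c-index of two models).
#'
#' @return A one-row tibble with `statistic` (V, the positive-rank sum of
#'   `a - b`), `p_value` and `n_effective` (nonzero differences).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  assert_that(length(a) == length(b), "`a` and `b` must be paired")
  d <- a - b
  n_eff <- sum(d != 0)
  if (n_eff == 0) {
    stop("all paired differences are zero: test is degenerate", call. = FALSE)
  }
  res <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = NULL))
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = res$p.value,
                 n_effective = n_eff)
}

#' Summary metric report for survival predictions
#'
#' Computes the Harrell c-index with a percentile confidence interval over
#' replicate scores, plus the IPCW Brier score of the model and of the
#' Kaplan-Meier null at an evaluation horizon, and the resulting index of
#' prediction accuracy.
#'
#' @param time,event Test outcomes.
#' @param risk Risk scores (higher = worse).
#' @param surv_prob Predicted survival probability at `horizon`.
#' @param horizon Evaluation time, default 24 (months).
#' @param replicate_c Optional vector of per-replicate c-index values used
#'   for the 95% percentile interval (e.g. one value per CV repeat).
#' @param train_time,train_event Outcomes for the censoring and null-model
#'   Kaplan-Meier estimates; default to the test outcomes.
#'
#' @return A one-row tibble: `c_index`, `c_index_low`, `c_index_high`,
#'   `brier_model`, `brier_null`, `ipa_percent`, `horizon`.
#' @export
metric_report <- function(time, event, risk, surv_prob, horizon = 24,
                          replicate_c = NULL,
                          train_time = time, train_event = event) {
  ci <- c_index(time, event, risk)
  if (!is.null(replicate_c) && length(replicate_c) >= 2) {
    qs <- stats::quantile(replicate_c, c(0.025, 0.975), names = FALSE,
                          type = 7)
  } else {
    qs <- c(NA_real_, NA_real_)
  }
  bm <- ipcw_brier(time, event, surv_prob, horizon, train_time, train_event)
  km_null <- km_stepfun(train_time, train_event)(horizon)
  bn <- ipcw_brier(time, event, rep(km_null, length(time)), horizon,
                   train_time, train_event)
  tibble::tibble(c_index = ci, c_index_low = qs[1], c_index_high = qs[2],
                 brier_model = bm, brier_null = bn,
                 ipa_percent = ipa(bm, bn), horizon = horizon)
}
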