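#' Cox partial-likelihood loss
#'
#' Negative log partial likelihood of the Cox proportional-hazards model with
#' Breslow handling of tied event times, evaluated at a vector of additive
#' risk scores. Used as the boosting loss.
#'
#' @param risk_scores Numeric vector of linear risk scores (log-hazard).
#' @param time,event Right-censored follow-up times (> 0) and 0/1 event
#'   indicators.
#'
#' @return Scalar loss (lower is better). Depends on the scores only through
#'   their differences: adding a constant to every score leaves it unchanged.
#' @export
cox_loss <- function(risk_scores, time, event) {
  check_survival_args(time, event)
  assert_that(all(is.finite(risk_scores)) &&
                length(risk_scores) == length(time),
              "`risk_scores` must be finite and match the outcomes")
  assert_that(sum(event) > 0, "Cox partial likelihood needs at least one event")
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; f_s <- risk_scores[ord]
  # risk-set sums S(t_k) = sum_{j: time_j >= t_k} exp(f_j); ties share a set
  rev_cum <- rev(cumsum(rev(exp(f_s))))
  event_times <- unique(t_s[e_s == 1])
  loss <- 0
  for (tk in event_times) {
    in_tie <- which(t_s == tk & e_s == 1)
    d_k <- length(in_tie)
    s_k <- rev_cum[match(TRUE, t_s >= tk)]
    loss <- loss - sum(f_s[in_tie]) + d_k * log(s_k)
  }
  loss
}

#' Negative gradient of the Cox partial likelihood
#'
#' Pseudo-responses for gradient boosting: the negative gradient of
#' [cox_loss()] with respect to each patient's risk score, with Breslow tie
#' handling. For patient `i` this is
#' `event_i - exp(f_i) * sum_{k: t_k <= y_i} d_k / S(t_k)` over distinct
#' event times `t_k` with multiplicity `d_k` and risk-set sum `S`.
#'
#' @inheritParams cox_loss
#'
#' @return Numeric vector of pseudo-responses, invariant to adding a constant
#'   to all scores.
#' @export
cox_negative_gradient <- function(risk_scores, time, event) {
  check_survival_args(time, event)
  assert_that(all(is.finite(risk_scores)) &&
                length(risk_scores) == length(time),
              "`risk_scores` must be finite and match the outcomes")
  assert_that(sum(event) > 0, "Cox partial likelihood needs at least one event")
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  exp_f <- exp(risk_scores)
  rev_cum <- rev(cumsum(rev(exp_f[ord])))
  event_times <- unique(t_s[e_s == 1])
  d_k <- vapply(event_times, function(tk) sum(t_s == tk & e_s == 1), numeric(1))
  s_k <- vapply(event_times, function(tk) rev_cum[match(TRUE, t_s >= tk)],
                numeric(1))
  # cumulative hazard increments experienced by each patient:
  # sum over event times <= own time of d_k / S(t_k)
  cum_ratio <- cumsum(d_k / s_k)
  idx <- findInterval(time, event_times)
  haz <- ifelse(idx == 0, 0, cum_ratio[pmax(idx, 1)])
  event - exp_f * haz
}

#' Fit component-wise gradient boosting for survival
#'
#' Gradient boosting under the Cox partial-likelihood loss with
#' component-wise least squares as the base learner: at each stage the
#' pseudo-responses (negative gradient at the current additive score) are
#' regressed on every feature separately, the single feature with the lowest
#' squared error is selected, and `learning_rate` times its fitted simple
#' regression is added to the model. A model with `k` stages therefore
#' references at most `k` distinct features — the ensemble is itself a
#' feature selector. A Breslow baseline cumulative hazard is estimated on the
#' training data so survival probabilities can be predicted.
#'
#' @param x `N x F` matrix (or data frame) of standardized features.
#' @param time,event Right-censored follow-up times (> 0) and 0/1 event
#'   indicators.
#' @param n_estimators Maximum number of boosting stages (weak learners);
#'   default 15.
#' @param learning_rate Multiplier applied to each stage's fitted component;
#'   default 1.
#' @param base_learner `"ls"` (component-wise simple least squares, default)
#'   or `"stump"` (single-split regression stump per stage).
#'
#' @return An object of class `cwgbs`: `stages` (tibble with one row per
#'   boosting stage), `loss` (training Cox loss after each stage, preceded by
#'   the null-model loss), `baseline_hazard` (Breslow step function of
#'   cumulative hazard), `feature_names`, `learning_rate`, `base_learner`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60 * 5), 60, 5)
#' time <- rexp(60, rate = exp(x[, 1]) / 20)
#' event <- rbinom(60, 1, 0.7)
#' fit <- fit_cwgbs(x, time, event, n_estimators = 5)
#' fit$stages
fit_cwgbs <- function(x, time, event, n_estimators = 15, learning_rate = 1,
                      base_learner = c("ls", "stump")) {
  base_learner <- match.arg(base_learner)
  x <- as_feature_matrix(x)
  check_survival_args(time, event)
  assert_that(nrow(x) == length(time), "rows of `x` must match the outcomes")
  assert_that(sum(event) > 0,
              "no events: the Cox partial likelihood is degenerate")
  assert_that(n_estimators >= 1, "`n_estimators` must be >= 1")
  assert_that(learning_rate > 0, "`learning_rate` must be > 0")
  feature_names <- colnames(x) %||% paste0("f", seq_len(ncol(x)))

  col_var <- apply(x, 2, stats::var)
  usable <- which(col_var > .Machine$double.eps)
  if (length(usable) < ncol(x)) {
    warning("skipping ", ncol(x) - length(usable),
            " constant feature column(s)", call. = FALSE)
  }
  assert_that(length(usable) > 0, "all feature columns are constant")

  f_hat <- rep(0, nrow(x))
  stages <- vector("list", n_estimators)
  loss_trace <- numeric(n_estimators + 1)
  loss_trace[1] <- cox_loss(f_hat, time, event)

  col_means <- colMeans(x)
  centered <- sweep(x, 2, col_means)
  ss_x <- colSums(centered^2)

  for (m in seq_len(n_estimators)) {
    v <- cox_negative_gradient(f_hat, time, event)
    if (base_learner == "ls") {
      v_c <- v - mean(v)
      slopes <- drop(crossprod(centered, v_c)) / ss_x
      # RSS of v ~ a + b * x_j; minimized RSS = SS_v - slope^2 * SS_x
      rss <- sum(v_c^2) - slopes^2 * ss_x
      rss[-usable] <- Inf
      j <- which.min(rss)
      slope <- slopes[j]
      intercept <- mean(v) - slope * col_means[j]
      update <- intercept + slope * x[, j]
      stages[[m]] <- tibble::tibble(stage = m, feature = feature_names[j],
                                    feature_index = j, slope = slope,
                                    intercept = intercept,
                                    split = NA_real_, left = NA_real_,
                                    right = NA_real_)
    } else {
      best <- fit_best_stump(x, v, usable)
      j <- best$feature
      update <- ifelse(x[, j] <= best$split, best$left, best$right)
      stages[[m]] <- tibble::tibble(stage = m, feature = feature_names[j],
                                    feature_index = j, slope = NA_real_,
                                    intercept = NA_real_, split = best$split,
                                    left = best$left, right = best$right)
    }
    f_hat <- f_hat + learning_rate * update
    loss_trace[m + 1] <- cox_loss(f_hat, time, event)
  }

  structure(list(stages = dplyr::bind_rows(stages),
                 loss = loss_trace,
                 learning_rate = learning_rate,
                 base_learner = base_learner,
                 n_estimators = as.integer(n_estimators),
                 feature_names = feature_names,
                 baseline_hazard = breslow_baseline(f_hat, time, event),
                 train_risk = f_hat,
                 max_train_time = max(time)),
            class = "cwgbs")
}

# Best single-split stump for pseudo-responses v (squared-error criterion).
fit_best_stump <- function(x, v, usable) {
  best <- list(rss = Inf)
  for (j in usable) {
    xo <- sort(unique(x[, j]))
    if (length(xo) < 2) next
    cuts <- (xo[-1] + xo[-length(xo)]) / 2
    for (cut in cuts) {
      lmask <- x[, j] <= cut
      lm_ <- mean(v[lmask]); rm_ <- mean(v[!lmask])
      rss <- sum((v[lmask] - lm_)^2) + sum((v[!lmask] - rm_)^2)
      if (rss < best$rss) {
        best <- list(rss = rss, feature = j, split = cut, left = lm_,
                     right = rm_)
      }
    }
  }
  best
}

# Breslow estimator of the baseline cumulative hazard given final scores.
breslow_baseline <- function(risk_scores, time, event) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  rev_cum <- rev(cumsum(rev(exp(risk_scores[ord]))))
  event_times <- unique(t_s[e_s == 1])
  d_k <- vapply(event_times, function(tk) sum(t_s == tk & e_s == 1), numeric(1))
  s_k <- vapply(event_times, function(tk) rev_cum[match(TRUE, t_s >= tk)],
                numeric(1))
  h0 <- cumsum(d_k / s_k)
  stats::stepfun(event_times, c(0, h0), right = FALSE)
}

#' Predict from a component-wise gradient boosting model
#'
#' @param object A fitted [fit_cwgbs()] model.
#' @param newdata Feature matrix (or data frame) with the training columns.
#' @param type `"risk"` for the additive log-hazard score, `"survival"` for
#'   survival probabilities `S(t) = exp(-H0(t) * exp(risk))` at the times in
#'   `horizons`, or `"time"` for the median of each patient's predicted
#'   survival function (a point estimate of survival time, by convention;
#'   `Inf` when the curve never falls below one half).
#' @param horizons Numeric vector of evaluation times for
#'   `type = "survival"`.
#' @param ... Unused.
#'
#' @return For `"risk"` and `"time"`, a numeric vector of length `N`; for
#'   `"survival"`, an `N x length(horizons)` matrix of probabilities,
#'   non-increasing along each row.
#' @export
predict.cwgbs <- function(object, newdata,
                          type = c("risk", "survival", "time"),
                          horizons = NULL, ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  assert_that(ncol(x) == length(object$feature_names),
              "`newdata` columns do not match the training features")
  if (!is.null(colnames(x))) {
    assert_that(identical(colnames(x), object$feature_names),
                "`newdata` column names do not match the training features")
  }
  score <- rep(0, nrow(x))
  st <- object$stages
  for (m in seq_len(nrow(st))) {
    update <- if (object$base_learner == "ls") {
      st$intercept[m] + st$slope[m] * x[, st$feature_index[m]]
    } else {
      ifelse(x[, st$feature_index[m]] <= st$split[m], st$left[m], st$right[m])
    }
    score <- score + object$learning_rate * update
  }
  if (type == "risk") return(score)

  if (type == "survival") {
    assert_that(!is.null(horizons) && all(horizons >= 0),
                "`horizons` must be nonnegative times")
    if (any(horizons > object$max_train_time)) {
      warning("horizon beyond the last training time: ",
              "extrapolating the baseline hazard as constant", call. = FALSE)
    }
    h0 <- object$baseline_hazard(pmin(horizons, object$max_train_time))
    surv <- exp(-outer(exp(score), h0))
    dimnames(surv) <- list(rownames(x), paste0("t", horizons))
    return(surv)
  }

  # median survival time of S(t) = exp(-H0(t) exp(score))
  knots <- stats::knots(object$baseline_hazard)
  h0_at <- object$baseline_hazard(knots)
  vapply(score, function(sc) {
    s_curve <- exp(-h0_at * exp(sc))
    i <- match(TRUE, s_curve <= 0.5)
    if (is.na(i)) Inf else knots[i]
  }, numeric(1))
}

#' @export
print.cwgbs <- function(x, ...) {
  cat("Component-wise gradient boosting survival model\n")
  cat(sprintf("  %d stages (%s base learner), learning rate %g\n",
              nrow(x$stages), x$base_learner, x$learning_rate))
  cat(sprintf("  distinct features used: %d of %d\n",
              length(unique(x$stages$feature)), length(x$feature_names)))
  cat(sprintf("  training Cox loss: %.4f -> %.4f\n",
              x$loss[1], utils::tail(x$loss, 1)))
  invisible(x)
}
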