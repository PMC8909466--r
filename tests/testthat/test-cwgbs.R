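test_that("Cox negative gradient matches hand values and finite differences", {
  # uniform risk, all events, distinct times: 1 - cumulative sum of 1/(n-k+1)
  g0 <- cox_negative_gradient(rep(0, 4), 1:4, rep(1, 4))
  expect_equal(g0, 1 - cumsum(1 / (4:1)), tolerance = 1e-12)

  # central finite differences on seeded instances with ties and censoring
  for (seed in 1:3) {
    set.seed(seed)
    time <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7)
    event <- c(1, 0, 1, 1, 1, 0, 1, 0, 1, 1)
    f <- rnorm(10)
    analytic <- cox_negative_gradient(f, time, event)
    h <- 1e-5
    numeric_grad <- vapply(1:10, function(i) {
      fp <- f; fm <- f
      fp[i] <- f[i] + h; fm[i] <- f[i] - h
      -(cox_loss(fp, time, event) - cox_loss(fm, time, event)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(analytic - numeric_grad)), 1e-6)
    # score-shift invariance: the partial likelihood sees only differences
    expect_equal(cox_negative_gradient(f + 3.7, time, event), analytic,
                 tolerance = 1e-12)
  }
  expect_error(cox_negative_gradient(rnorm(3), 1:3, c(0, 0, 0)), "event")
})

test_that("gradient at zero scores equals coxph null martingale residuals", {
  set.seed(8)
  time <- rexp(20, 0.1)
  event <- rbinom(20, 1, 0.6); event[1] <- 1
  mr <- residuals(survival::coxph(survival::Surv(time, event) ~ 1,
                                  ties = "breslow"), type = "martingale")
  expect_equal(cox_negative_gradient(rep(0, 20), time, event), unname(mr),
               tolerance = 1e-10)
})

test_that("boosting decreases the training loss and is component-wise sparse", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 120
    x <- matrix(rnorm(n * 8), n, 8)
    colnames(x) <- paste0("f", 1:8)
    latent <- rexp(n, rate = exp(1.2 * x[, 2]) / 20)
    cens <- runif(n, 5, 80)
    fit <- fit_cwgbs(x, pmin(latent, cens), as.numeric(latent <= cens),
                     n_estimators = 15, learning_rate = 1)
    expect_true(all(diff(fit$loss) <= 1e-9))
    expect_lte(length(unique(fit$stages$feature)), 15)
    expect_equal(nrow(fit$stages), 15)
    # the single prognostic feature is found first
    expect_equal(fit$stages$feature[1], "f2")
  }
})

test_that("pure-noise features give near-flat loss decrease per stage", {
  drops <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 300
    x <- matrix(rnorm(n * 10), n, 10)
    time <- rexp(n, 0.05)
    event <- rbinom(n, 1, 0.7); event[1] <- 1
    fit <- fit_cwgbs(x, time, event, n_estimators = 5)
    max(-diff(fit$loss) / fit$loss[1])
  }, numeric(1))
  expect_lt(mean(drops), 0.01)
})

test_that("risk prediction equals explicit stage accumulation", {
  set.seed(12)
  x <- matrix(rnorm(50 * 6), 50, 6)
  time <- rexp(50, 0.1); event <- rbinom(50, 1, 0.7); event[1] <- 1
  fit <- fit_cwgbs(x, time, event, n_estimators = 7, learning_rate = 0.8)
  by_hand <- rep(0, 50)
  for (m in seq_len(nrow(fit$stages))) {
    st <- fit$stages[m, ]
    by_hand <- by_hand + 0.8 * (st$intercept + st$slope * x[, st$feature_index])
  }
  expect_equal(predict(fit, x, type = "risk"), by_hand, tolerance = 1e-12)
  # zero stages -> zero scores
  fit0 <- fit
  fit0$stages <- fit$stages[0, ]
  expect_equal(predict(fit0, x, type = "risk"), rep(0, 50))
})

test_that("survival probabilities follow the Breslow baseline", {
  # all-zero features, no censoring: S(t) = exp(-H0(t)) with Breslow
  # increments d_k / n_at_risk under uniform scores
  x <- matrix(rnorm(5), 5, 1) * 0 + cbind(c(0.01, -0.01, 0.02, 0, -0.02))
  time <- c(3, 5, 7, 11, 13); event <- rep(1, 5)
  fit <- fit_cwgbs(x, time, event, n_estimators = 1)
  # the single component has ~zero slope on this scale; risks ~ equal
  s <- predict(fit, x, type = "survival", horizons = c(0, 3, 5, 12))
  expect_equal(unname(s[, 1]), rep(1, 5))
  risk <- predict(fit, x, type = "risk")
  h0 <- cumsum(1 / rev(cumsum(rev(exp(risk[order(time)])))))
  expect_equal(unname(s[1, 2]), exp(-h0[1] * exp(risk[1])), tolerance = 1e-10)
  expect_equal(unname(s[1, 3]), exp(-h0[2] * exp(risk[1])), tolerance = 1e-10)
  expect_true(all(apply(s, 1, function(r) all(diff(r) <= 0))))
  expect_warning(predict(fit, x, type = "survival", horizons = 20),
                 "extrapolating")
})

test_that("median predicted survival time orders inversely with risk", {
  set.seed(14)
  n <- 150
  x <- matrix(rnorm(n * 4), n, 4)
  latent <- rexp(n, rate = exp(1.5 * x[, 1]) / 15)
  cens <- runif(n, 10, 90)
  fit <- fit_cwgbs(x, pmin(latent, cens), as.numeric(latent <= cens),
                   n_estimators = 10)
  risk <- predict(fit, x, type = "risk")
  tmed <- predict(fit, x, type = "time")
  finite <- is.finite(tmed)
  expect_gt(mean(finite), 0.5)
  expect_lt(cor(risk[finite], tmed[finite], method = "spearman"), -0.9)
})

test_that("stump base learner works and errors are informative", {
  set.seed(15)
  x <- matrix(rnorm(80 * 3), 80, 3)
  latent <- rexp(80, rate = exp(1.5 * (x[, 3] > 0)) / 10)
  fit <- fit_cwgbs(x, latent, rep(1, 80), n_estimators = 3,
                   base_learner = "stump")
  expect_equal(fit$stages$feature[1], "f3")
  expect_true(all(diff(fit$loss) <= 1e-9))
  # a single stump predicts exactly two risk levels
  fit1 <- fit_cwgbs(x, latent, rep(1, 80), n_estimators = 1,
                    base_learner = "stump")
  expect_equal(length(unique(predict(fit1, x, type = "risk"))), 2)

  expect_error(fit_cwgbs(x, latent, rep(0, 80)), "no events")
  expect_warning(fit_cwgbs(cbind(x, 1), latent, rep(1, 80), n_estimators = 2),
                 "constant")
})

test_that("synthetic Cox signal is learned out of sample", {
  cs <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 300; f <- 50
    x <- matrix(rnorm(n * f), n, f)
    beta <- c(rep(0.8, 5), rep(0, f - 5))
    latent <- rexp(n, rate = exp(drop(x %*% beta)) / 25)
    cens <- quantile(latent, 0.7) * runif(n, 0.5, 3)
    time <- pmin(latent, cens); event <- as.numeric(latent <= cens)
    tr <- 1:200; te <- 201:300
    fit <- fit_cwgbs(x[tr, ], time[tr], event[tr], n_estimators = 15)
    c_index(time[te], event[te], predict(fit, x[te, ], type = "risk"))
  }, numeric(1))
  expect_gt(mean(cs), 0.7)
})
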