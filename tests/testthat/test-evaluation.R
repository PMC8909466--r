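test_that("c-index matches exhaustive pair enumeration and edge cases", {
  ts <- toy_surv()
  set.seed(41)
  for (i in 1:5) {
    risk <- sample(c(rnorm(8), rnorm(1), 0))
    expect_equal(c_index(ts$time, ts$event, risk),
                 c_index_brute(ts$time, ts$event, risk), tolerance = 1e-12)
  }
  # perfect inverse ordering without censoring; all-tied risks
  time <- c(9, 7, 5, 3, 1)
  expect_equal(c_index(time, rep(1, 5), 1:5), 1)
  expect_equal(c_index(time, rep(1, 5), rep(2, 5)), 0.5)
  # antisymmetry on censoring-free data
  risk <- rnorm(5)
  expect_equal(c_index(time, rep(1, 5), risk),
               1 - c_index(time, rep(1, 5), -risk), tolerance = 1e-12)
  expect_error(c_index(c(1, 1), c(0, 0), c(1, 2)), "comparable")
})

test_that("c-index agrees with survival::concordance on tie-free data", {
  set.seed(42)
  for (i in 1:10) {
    n <- 30
    time <- rexp(n, 0.1) + seq(0, 1e-4, length.out = n)
    event <- rbinom(n, 1, 0.7); event[1] <- 1
    risk <- rnorm(n)
    ref <- survival::concordance(survival::Surv(time, event) ~ risk,
                                 reverse = TRUE)$concordance
    expect_equal(c_index(time, event, risk), unname(ref), tolerance = 1e-12)
  }
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # censored-in-the-middle fixture: S = 1, 2/3 on [2, 6), 0 after 6
  kc <- km_curve(c(2, 4, 6), c(1, 0, 1))
  expect_equal(kc$survival, c(1, 2/3, 2/3, 0), tolerance = 1e-12)
  expect_equal(kc$time, c(0, 2, 4, 6))

  ts <- toy_surv()
  kf <- flsglboost:::km_stepfun(ts$time, ts$event)
  for (at in c(0.5, 2, 5, 9, 13.5, 24, 30)) {
    expect_equal(kf(at), km_brute(ts$time, ts$event, at), tolerance = 1e-12)
  }
  # no censoring: empirical survival function; all censored: S = 1
  time <- c(1, 3, 5, 7)
  kf2 <- flsglboost:::km_stepfun(time, rep(1, 4))
  expect_equal(vapply(c(0, 2, 4, 6, 8), kf2, 1), c(1, .75, .5, .25, 0))
  kf3 <- flsglboost:::km_stepfun(time, rep(0, 4))
  expect_equal(vapply(c(0, 2, 4, 6, 8), kf3, 1), rep(1, 5))
})

test_that("IPCW Brier reduces to the plain Brier score without censoring", {
  set.seed(43)
  time <- rexp(40, 0.1)
  event <- rep(1, 40)
  sp <- runif(40)
  h <- median(time)
  plain <- mean((as.numeric(time > h) - sp)^2)
  expect_lt(abs(ipcw_brier(time, event, sp, h) - plain), 1e-12)
  # perfect 0/1 predictions score zero; constant one-half scores 0.25
  perfect <- as.numeric(time > h)
  expect_equal(ipcw_brier(time, event, perfect, h), 0)
  expect_equal(ipcw_brier(time, event, rep(0.5, 40), h), 0.25)
})

test_that("IPCW weighting is consistent under censoring", {
  set.seed(44)
  n <- 200
  latent <- rexp(n, 0.08)
  cens <- rexp(n, 0.04)
  time <- pmin(latent, cens); event <- as.numeric(latent <= cens)
  sp <- runif(n)
  h <- quantile(time, 0.5)
  b <- ipcw_brier(time, event, sp, h)
  expect_gte(b, 0)
  # hand-assembled Graf terms with the reverse KM
  g_left <- flsglboost:::km_stepfun_left(time, 1 - event)
  g_fun <- flsglboost:::km_stepfun(time, 1 - event)
  terms <- numeric(n)
  for (i in 1:n) {
    if (time[i] <= h && event[i] == 1) terms[i] <- sp[i]^2 / g_left(time[i])
    if (time[i] > h) terms[i] <- (1 - sp[i])^2 / g_fun(h)
  }
  expect_equal(b, mean(terms), tolerance = 1e-12)
})

test_that("IPA rescales the Brier score against the null model", {
  expect_equal(ipa(0.25, 0.25), 0)
  expect_equal(ipa(0, 0.3), 100)
  expect_equal(ipa(0.175, 0.25), 30)
  expect_lt(ipa(0.3, 0.2), 0) # worse than null is negative
  expect_error(ipa(0.1, 0), "undefined")
})

test_that("log-rank test matches the hand O-E tabulation", {
  ts <- toy_surv()
  group <- c(1, 1, 2, 1, 2, 2, 1, 2, 1, 2)
  res <- log_rank_test(ts$time, ts$event, group)
  brute <- log_rank_brute(ts$time, ts$event, group)
  expect_equal(res$statistic, unname(brute["statistic"]), tolerance = 1e-6)
  expect_equal(res$p_value, unname(brute["p"]), tolerance = 1e-6)
  # identical groups interleaved: statistic near zero, p near one
  time <- rep(c(2, 5, 9, 14), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  res2 <- log_rank_test(time, event, rep(1:2, each = 4))
  expect_lt(res2$statistic, 1e-10)
  expect_gt(res2$p_value, 0.999)
})

test_that("log-rank p is calibrated against a permutation oracle", {
  set.seed(45)
  time <- c(rexp(10, 0.05), rexp(10, 0.12))
  event <- rbinom(20, 1, 0.8); event[1] <- 1
  group <- rep(1:2, each = 10)
  obs <- log_rank_test(time, event, group)$statistic
  perm <- replicate(1000, {
    g <- sample(group)
    log_rank_brute(time, event, g)["statistic"]
  })
  p_perm <- mean(perm >= obs)
  p_asym <- log_rank_test(time, event, group)$p_value
  expect_lt(abs(p_perm - p_asym), 3 * sqrt(p_asym * (1 - p_asym) / 1000) + 0.02)
})

test_that("Friedman test matches hand rank sums and is rank-invariant", {
  scores <- rbind(model_a = c(0.70, 0.72, 0.68, 0.74),
                  model_b = c(0.66, 0.69, 0.65, 0.70),
                  model_c = c(0.61, 0.64, 0.66, 0.63))
  res <- friedman_test(scores)
  expect_equal(res$statistic, friedman_brute(scores), tolerance = 1e-6)
  expect_equal(res$p_value,
               pchisq(friedman_brute(scores), df = 2, lower.tail = FALSE),
               tolerance = 1e-6)
  # monotone transform within blocks leaves the statistic unchanged
  res2 <- friedman_test(exp(5 * scores))
  expect_equal(res2$statistic, res$statistic)
  # identical columns across models: statistic 0, p = 1
  same <- rbind(a = 1:4, b = 1:4, c = 1:4) * 0 + rep(1:4, each = 1)
  res3 <- friedman_test(rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)) * 0 + 0.5)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
})

test_that("Wilcoxon signed-rank matches exact sign-pattern enumeration", {
  a <- c(0.71, 0.69, 0.74, 0.66, 0.72, 0.70)
  b <- c(0.65, 0.70, 0.69, 0.64, 0.68, 0.67)
  res <- wilcoxon_signed_rank(a, b)
  brute <- wilcoxon_exact_brute(a, b)
  expect_equal(res$statistic, unname(brute["statistic"]))
  expect_equal(res$p_value, unname(brute["p"]), tolerance = 1e-6)
  # swapping the arguments flips the statistic to the mirrored rank sum
  res_swap <- wilcoxon_signed_rank(b, a)
  n <- 6
  expect_equal(res_swap$statistic, n * (n + 1) / 2 - res$statistic)
  expect_equal(res_swap$p_value, res$p_value, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(a, a), "degenerate")
})

test_that("metric_report combines concordance, Brier and IPA coherently", {
  set.seed(46)
  n <- 60
  latent <- rexp(n, 0.05)
  cens <- runif(n, 10, 100)
  time <- pmin(latent, cens); event <- as.numeric(latent <= cens)
  risk <- -log(latent) + rnorm(n, sd = 0.3)
  sp <- pmin(pmax(1 - (risk - min(risk)) / diff(range(risk)), 0.01), 0.99)
  rep_c <- c(0.68, 0.71, 0.73, 0.69, 0.75)
  mr <- metric_report(time, event, risk, sp, horizon = 24,
                      replicate_c = rep_c)
  expect_equal(mr$c_index, c_index(time, event, risk))
  expect_equal(mr$ipa_percent, 100 * (1 - mr$brier_model / mr$brier_null))
  expect_lte(mr$c_index_low, mr$c_index_high)
  expect_equal(mr$horizon, 24)
  # the null model's own IPA is zero
  km_null <- flsglboost:::km_stepfun(time, event)(24)
  mr_null <- metric_report(time, event, rep(0, n) + rnorm(n, sd = 1e-8),
                           rep(km_null, n), horizon = 24)
  expect_equal(mr_null$ipa_percent, 0, tolerance = 1e-10)
})
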