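# Independent oracles used across tests. These deliberately share no code
# with the package implementation.

# Coordinate-descent LASSO for the unnormalized objective
# ||y - X b||^2 + beta1 * ||b||_1 (no intercept; X standardized).
cd_lasso_oracle <- function(x, y, beta1, iters = 20000, tol = 1e-13) {
  f <- ncol(x)
  phi <- rep(0, f)
  xx <- colSums(x^2)
  r <- y
  for (i in seq_len(iters)) {
    old <- phi
    for (j in seq_len(f)) {
      rho <- sum(x[, j] * r) + xx[j] * phi[j]
      nj <- sign(rho) * max(abs(rho) - beta1 / 2, 0) / xx[j]
      r <- r - x[, j] * (nj - phi[j])
      phi[j] <- nj
    }
    if (max(abs(phi - old)) < tol) break
  }
  phi
}

# Exhaustive pairwise c-index.
c_index_brute <- function(time, event, risk) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        num <- num + if (risk[i] > risk[j]) 1 else if (risk[i] == risk[j]) 0.5 else 0
      }
    }
  }
  num / den
}

# Hand product-limit estimator (no package calls).
km_brute <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  for (tk in ut[ut <= at]) {
    d <- sum(time == tk & event == 1)
    r <- sum(time >= tk)
    s <- s * (1 - d / r)
  }
  s
}

# Hand two-group log-rank chi-square from the O-E tabulation.
log_rank_brute <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tk in ut) {
    at_risk <- time >= tk
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  c(statistic = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Exact two-sided signed-rank p by enumerating all sign patterns.
wilcoxon_exact_brute <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% rk
  mu <- n * (n + 1) / 4
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
  c(statistic = v_obs, p = p)
}

# Friedman chi-square from hand rank sums (no ties).
friedman_brute <- function(scores) {
  k <- nrow(scores) # treatments (models)
  b <- ncol(scores) # blocks
  ranks <- apply(scores, 2, rank)
  rj <- rowSums(ranks)
  12 / (b * k * (k + 1)) * sum((rj - b * (k + 1) / 2)^2)
}

# Small deterministic censored survival fixture.
toy_surv <- function() {
  list(time = c(2, 3, 5, 5, 8, 11, 13, 16, 20, 24),
       event = c(1, 0, 1, 1, 0, 1, 0, 1, 1, 0))
}

# Standardized Gaussian regression instance with a sparse signal.
toy_regression <- function(seed, n = 50, f = 30, sd_noise = 0.5) {
  set.seed(seed)
  x <- scale(matrix(rnorm(n * f), n, f))
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  beta <- c(2, -1.5, 1, rep(0, f - 3))
  y <- drop(x %*% beta + rnorm(n, sd = sd_noise))
  list(x = x, y = y, beta = beta)
}

f1_score <- function(selected, truth) {
  tp <- sum(selected %in% truth)
  2 * tp / (length(selected) + length(truth))
}
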