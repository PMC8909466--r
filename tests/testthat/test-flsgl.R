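test_that("gaussian kernel has the closed form, symmetry and monotone decay", {
  expect_equal(gaussian_kernel(0, 1), 1 / sqrt(2 * pi))
  expect_equal(gaussian_kernel(1, 1), exp(-0.5) / sqrt(2 * pi))
  expect_equal(gaussian_kernel(-2, 1), gaussian_kernel(2, 1))
  xs <- seq(0, 4, by = 0.5)
  expect_true(all(diff(gaussian_kernel(xs, 1)) < 0))
  expect_true(all(diff(gaussian_kernel(xs, 2)) < 0))
  expect_error(gaussian_kernel(1, 0), "positive")
  expect_error(gaussian_kernel(1, -1), "positive")
})

test_that("task weights are column-normalized, distance-decaying kernel ratios", {
  # single neighbour and symmetric-neighbour cases
  expect_equal(unname(task_weights(2, 1)[2, 1]), 1)
  expect_equal(unname(task_weights(2, 1)[1, 2]), 1)
  w3 <- task_weights(3, 1)
  expect_equal(unname(w3[1, 2]), 0.5)
  expect_equal(unname(w3[3, 2]), 0.5)
  # hand evaluation of the normalized kernel ratio for the edge column
  k1 <- gaussian_kernel(1, 1); k2 <- gaussian_kernel(2, 1)
  expect_equal(unname(w3[2, 1]), k1 / (k1 + k2), tolerance = 1e-12)
  expect_equal(unname(w3[3, 1]), k2 / (k1 + k2), tolerance = 1e-12)

  for (n_tasks in 2:10) {
    for (sigma in c(0.5, 1, 2)) {
      w <- task_weights(n_tasks, sigma)
      expect_equal(unname(colSums(w)), rep(1, n_tasks), tolerance = 1e-12)
      expect_true(all(w >= 0))
      expect_true(all(diag(w) == 0))
      # weights decay with task distance within each column
      for (t in seq_len(n_tasks)) {
        d <- abs(seq_len(n_tasks) - t)[-t]
        expect_true(all(diff(w[-t, t][order(d)]) <= 1e-12))
      }
    }
  }
  expect_error(task_weights(1), ">= 2")
})

test_that("fusion matrix realizes the kernel-weighted residual transform", {
  g2 <- fusion_matrix(2)
  expect_equal(g2, matrix(c(1, -1, -1, 1), 2))
  # identical task columns have zero fusion residual
  phi <- matrix(rnorm(10), 5, 2)
  phi[, 2] <- phi[, 1]
  expect_equal(phi %*% g2, matrix(0, 5, 2))
  # T = 3: matrix product equals the explicit weighted sum per column
  w <- task_weights(3, 1)
  g3 <- fusion_matrix(w)
  phi <- matrix(rnorm(12), 4, 3)
  for (t in 1:3) {
    explicit <- phi[, t] - rowSums(sapply((1:3)[-t], function(r) w[r, t] * phi[, r]))
    expect_equal(unname((phi %*% g3)[, t]), explicit, tolerance = 1e-12)
  }
})

test_that("objective assembles the four penalty terms", {
  set.seed(21)
  n <- 6; f <- 4
  xs <- list(matrix(rnorm(n * f), n, f), matrix(rnorm(n * f), n, f))
  y <- rnorm(n) + 5
  phi <- matrix(rnorm(f * 2), f, 2)
  cfg <- flsgl_config(beta1 = 0.7, beta2 = 1.3, beta3 = 0.4)
  g <- fusion_matrix(2)
  by_hand <- sum((y - xs[[1]] %*% phi[, 1])^2) +
    sum((y - xs[[2]] %*% phi[, 2])^2) +
    0.7 * sum(abs(phi)) +
    1.3 * sum(sqrt(rowSums(phi^2))) +
    0.4 * sum(abs(phi %*% g))
  expect_equal(flsgl_objective(phi, xs, y, cfg), by_hand, tolerance = 1e-12)
  # penalties vanish at zero; penalties off leaves the residual sum
  expect_equal(flsgl_objective(0 * phi, xs, y, cfg), 2 * sum(y^2))
  cfg0 <- flsgl_config(beta1 = 0, beta2 = 0, beta3 = 0)
  expect_equal(flsgl_objective(phi, xs, y, cfg0),
               sum((y - xs[[1]] %*% phi[, 1])^2) +
                 sum((y - xs[[2]] %*% phi[, 2])^2))
})

test_that("single-task pure-L1 fits match a coordinate-descent LASSO oracle", {
  for (seed in c(1, 2, 3)) {
    inst <- toy_regression(seed)
    for (b1 in c(1, 10, 40)) {
      cfg <- flsgl_config(beta1 = b1, beta2 = 0, beta3 = 0,
                          tol = 1e-9, max_iter = 50000)
      fit <- fit_flsgl(inst$x, inst$y, cfg)
      oracle <- cd_lasso_oracle(inst$x, inst$y, b1)
      expect_lt(max(abs(drop(fit$coefficients) - oracle)), 1e-4)
    }
  }
})

test_that("both solvers reach the same optimum of the full objective", {
  for (seed in 1:5) {
    inst <- toy_regression(seed)
    set.seed(seed + 100)
    xs <- list(inst$x, scale(matrix(rnorm(prod(dim(inst$x))), nrow(inst$x))))
    cfg <- flsgl_config(tol = 1e-8, max_iter = 20000)
    fa <- fit_flsgl(xs, inst$y, cfg, solver = "apg")
    fb <- fit_flsgl(xs, inst$y, cfg, solver = "admm")
    oa <- tail(fa$objective, 1); ob <- tail(fb$objective, 1)
    expect_lt(abs(oa - ob) / oa, 1e-6)
  }
})

test_that("objective trace is non-increasing and residual matrix consistent", {
  for (seed in 1:6) {
    inst <- toy_regression(seed)
    set.seed(seed + 200)
    xs <- list(inst$x, scale(matrix(rnorm(prod(dim(inst$x))), nrow(inst$x))))
    fit <- fit_flsgl(xs, inst$y, flsgl_config(tol = 1e-8, max_iter = 20000))
    expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[1]))
    expect_lt(max(abs(fit$residual_matrix - fit$coefficients %*% fit$fusion)),
              1e-10)
    expect_true(fit$converged)
  }
})

test_that("overwhelming L1 penalty produces exact zeros", {
  inst <- toy_regression(4)
  cfg <- flsgl_config(beta1 = 1e6, beta2 = 0, beta3 = 0)
  fit <- fit_flsgl(inst$x, inst$y, cfg)
  expect_identical(unname(fit$coefficients), matrix(0, 30, 1))
  expect_equal(nrow(selected_features(fit)), 0)
})

test_that("selection shrinks monotonically with beta1", {
  inst <- toy_regression(5)
  n_sel <- sapply(c(0.5, 2, 8, 32, 128), function(b1) {
    fit <- fit_flsgl(inst$x, inst$y, flsgl_config(beta1 = b1, beta2 = 0,
                                                  beta3 = 0))
    nrow(selected_features(fit))
  })
  expect_true(all(diff(n_sel) <= 0))
})

test_that("a strong fusion penalty pulls task coefficients together", {
  closer <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 60; f <- 10
    x1 <- scale(matrix(rnorm(n * f), n, f))
    x2 <- scale(matrix(rnorm(n * f), n, f))
    beta <- c(1.5, -1, rep(0, f - 2))
    y <- drop((x1 %*% beta + x2 %*% beta) / 2 + rnorm(n, sd = 0.3))
    gap <- function(b3) {
      fit <- fit_flsgl(list(x1, x2), y,
                       flsgl_config(beta1 = 1, beta2 = 0, beta3 = b3))
      sqrt(sum((fit$coefficients[, 1] - fit$coefficients[, 2])^2))
    }
    if (gap(200) < gap(0)) closer <- closer + 1
  }
  expect_gte(closer, 9)
})

test_that("fits are deterministic and linear predictions match brute force", {
  inst <- toy_regression(6)
  cfg <- flsgl_config(beta1 = 5, beta2 = 2, beta3 = 1)
  xs <- list(inst$x, inst$x[, sample(ncol(inst$x))])
  f1 <- fit_flsgl(xs, inst$y, cfg)
  f2 <- fit_flsgl(xs, inst$y, cfg)
  expect_identical(f1$coefficients, f2$coefficients)

  pred <- predict(f1, inst$x, task = 2)
  by_hand <- vapply(seq_len(nrow(inst$x)), function(i) {
    sum(inst$x[i, ] * f1$coefficients[, 2])
  }, numeric(1))
  expect_equal(pred, by_hand, tolerance = 1e-12)
  expect_equal(predict(f1, diag(ncol(inst$x)), task = 1),
               unname(f1$coefficients[, 1]))
  expect_error(predict(f1, inst$x, task = 7), "task")
})

test_that("selected_features orders by coefficient magnitude with index ties", {
  fit <- structure(list(coefficients = rbind(c(0, 0), c(0.5, -0.2),
                                             c(0.5, 0), c(0, 2)),
                        feature_names = c("a", "b", "c", "d"),
                        config = flsgl_config()),
                   class = "flsgl")
  sel <- selected_features(fit, threshold = 0.1)
  expect_equal(sel$feature, c("d", "b", "c"))
  expect_equal(sel$max_abs_coef, c(2, 0.5, 0.5))
})

test_that("degenerate inputs are rejected with informative errors", {
  inst <- toy_regression(7)
  bad <- inst$x; bad[, 3] <- 0
  expect_error(fit_flsgl(bad, inst$y), "all-zero")
  expect_error(fit_flsgl(list(inst$x, inst$x[-1, ]), inst$y), "same patients")
  expect_error(flsgl_config(beta1 = -1), ">= 0")
  expect_error(flsgl_config(tol = 0), "tol")
})

test_that("row prox for three or more tasks matches direct minimization", {
  set.seed(31)
  g <- fusion_matrix(4)
  cfg <- flsgl_config(beta1 = 0.8, beta2 = 1.1, beta3 = 0.6)
  v <- matrix(rnorm(8 * 4, sd = 2), 8, 4)
  pr <- flsglboost:::prox_sparse_group_fused(v, 0.37, cfg, g)
  for (i in seq_len(nrow(v))) {
    obj <- function(a) {
      0.5 * sum((a - v[i, ])^2) + 0.37 *
        (cfg$beta1 * sum(abs(a)) + cfg$beta2 * sqrt(sum(a^2)) +
           cfg$beta3 * sum(abs(crossprod(g, a))))
    }
    opt <- optim(pr[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
    expect_lte(obj(pr[i, ]), opt$value + 1e-8)
  }
})
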