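#' Gaussian kernel
#'
#' Gaussian density kernel used to weight the influence of one imaging time
#' point (task) on another as a function of their index distance.
#'
#' @param x Numeric vector of distances.
#' @param sigma Kernel bandwidth (> 0). Small values concentrate weight on
#'   immediate neighbours; large values smooth across distant time points.
#'
#' @return `(1 / (sigma * sqrt(2 * pi))) * exp(-x^2 / (2 * sigma^2))`,
#'   vectorized over `x`.
#' @export
#' @examples
#' gaussian_kernel(0, 1) # 1 / sqrt(2 * pi)
gaussian_kernel <- function(x, sigma = 1) {
  assert_that(is.numeric(sigma) && length(sigma) == 1 && sigma > 0,
              "`sigma` must be a single positive number")
  (1 / (sigma * sqrt(2 * pi))) * exp(-x^2 / (2 * sigma^2))
}

#' Kernel-smoothed task weights
#'
#' For each task (time point) `t`, the influence of every other task `r` is a
#' Gaussian kernel evaluation of the index distance `r - t`, normalized so the
#' weights over `r != t` sum to one. Column `t` of the returned matrix holds
#' the weights flowing into task `t`.
#'
#' @param n_tasks Number of tasks `T` (>= 2).
#' @param sigma Gaussian kernel bandwidth.
#'
#' @return A `T x T` matrix of nonnegative weights with zero diagonal and
#'   unit column sums over off-diagonal entries; `sigma` is attached as an
#'   attribute.
#' @export
#' @examples
#' task_weights(3, sigma = 1)
task_weights <- function(n_tasks, sigma = 1) {
  assert_that(is.numeric(n_tasks) && length(n_tasks) == 1 && n_tasks >= 2,
              "`n_tasks` must be >= 2: kernel smoothing needs neighbour tasks")
  n_tasks <- as.integer(n_tasks)
  d <- abs(outer(seq_len(n_tasks), seq_len(n_tasks), `-`))
  k <- gaussian_kernel(d, sigma)
  diag(k) <- 0
  w <- sweep(k, 2, colSums(k), `/`)
  structure(w, sigma = sigma)
}

#' Fusion (transformation) matrix
#'
#' Builds the `T x T` matrix `G` with unit diagonal and `-w[r, t]` off the
#' diagonal, so that column `t` of `Phi %*% G` is the fusion residual
#' `phi_t - sum_{r != t} w[r, t] * phi_r`. Penalizing `|Phi G|_1` encourages
#' each task's coefficients to agree with the kernel-weighted average of its
#' neighbours, i.e. temporal smoothness of the signature.
#'
#' @param weights Weight matrix from [task_weights()], or a single task count
#'   to build default weights with `sigma`.
#' @param sigma Bandwidth used when `weights` is given as a task count.
#'
#' @return The `T x T` fusion matrix `G`.
#' @export
fusion_matrix <- function(weights, sigma = 1) {
  if (length(weights) == 1 && is.numeric(weights)) {
    if (weights == 1) return(matrix(1, 1, 1)) # single task: empty neighbour sum
    weights <- task_weights(weights, sigma)
  }
  g <- diag(nrow(weights)) - weights
  attr(g, "sigma") <- NULL
  g
}

#' FLSGL solver configuration
#'
#' Collects the penalty weights and solver constants of the fused Laplacian
#' sparse group LASSO. Defaults are the tuned values used for the longitudinal
#' radiomics application: `beta1 = 4.8` (LASSO), `beta2 = 2.2` (group LASSO
#' across time points), `beta3 = 4.2` (fusion residual sparsity), kernel
#' bandwidth `sigma = 1`, and ADMM augmented-Lagrangian penalty `delta = 10`.
#'
#' @param beta1,beta2,beta3 Nonnegative penalty weights for the elementwise
#'   L1 norm, the row-wise L2,1 group norm, and the L1 norm of the fusion
#'   residual matrix `Phi G`.
#' @param sigma Gaussian kernel bandwidth for the task weights.
#' @param delta ADMM augmented-Lagrangian penalty parameter.
#' @param max_iter Maximum number of ADMM iterations.
#' @param tol Primal/dual residual tolerance for convergence.
#' @param selection_threshold Absolute coefficient threshold used by
#'   [selected_features()].
#' @param log_time If `TRUE`, regress on `log(time)` instead of raw follow-up
#'   time when targets are supplied as survival times.
#' @param relative If `TRUE`, `beta1`..`beta3` are interpreted as fractions
#'   of the data's penalty ceiling `lambda_max` (the smallest group penalty
#'   that zeroes every coefficient, `2 * max_i ||[X_t' y_t]_i||_2` over
#'   feature rows), which makes penalty settings transferable across sample
#'   sizes and target scales. If `FALSE` (default) they are absolute weights
#'   on the unnormalized objective.
#'
#' @return An object of class `flsgl_config`.
#' @export
flsgl_config <- function(beta1 = 4.8, beta2 = 2.2, beta3 = 4.2,
                         sigma = 1, delta = 10,
                         max_iter = 2000, tol = 1e-6,
                         selection_threshold = 1e-3,
                         log_time = FALSE, relative = FALSE) {
  assert_that(all(c(beta1, beta2, beta3) >= 0), "penalties must be >= 0")
  assert_that(sigma > 0, "`sigma` must be > 0")
  assert_that(delta > 0, "`delta` must be > 0")
  assert_that(tol > 0, "`tol` must be > 0")
  assert_that(max_iter >= 1, "`max_iter` must be >= 1")
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 sigma = sigma, delta = delta,
                 max_iter = as.integer(max_iter), tol = tol,
                 selection_threshold = selection_threshold,
                 log_time = log_time, relative = relative),
            class = "flsgl_config")
}

# Validate and normalize the task inputs of fit_flsgl / flsgl_objective:
# a list of N x F matrices (one per task) and one target vector per task.
normalize_tasks <- function(x, y) {
  if (!is.list(x)) x <- list(x)
  x <- lapply(x, as_feature_matrix)
  n_tasks <- length(x)
  assert_that(n_tasks >= 1, "at least one task is required")
  dims <- vapply(x, dim, integer(2))
  assert_that(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
              "all tasks must share the same patients (rows) and features (columns)")
  assert_that(all(vapply(x, function(m) all(is.finite(m)), logical(1))),
              "feature matrices must be finite with no missing values")
  zero_col <- vapply(x, function(m) any(colSums(abs(m)) == 0), logical(1))
  assert_that(!any(zero_col),
              "degenerate all-zero feature column: standardize or drop it first")
  if (!is.list(y)) y <- rep(list(as.numeric(y)), n_tasks)
  assert_that(length(y) == n_tasks, "need one target vector per task")
  assert_that(all(vapply(y, length, integer(1)) == dims[1, 1]),
              "target length must equal the number of rows of each task")
  assert_that(all(vapply(y, function(v) all(is.finite(v)), logical(1))),
              "targets must be finite")
  feature_names <- colnames(x[[1]]) %||% paste0("f", seq_len(dims[2, 1]))
  task_names <- names(x) %||% paste0("task", seq_len(n_tasks))
  if (any(task_names == "")) task_names <- paste0("task", seq_len(n_tasks))
  list(x = x, y = y, n = dims[1, 1], n_features = dims[2, 1],
       n_tasks = n_tasks, feature_names = feature_names,
       task_names = task_names)
}

#' FLSGL objective function
#'
#' Evaluates the penalized multitask least-squares objective
#' `sum_t |y_t - X_t phi_t|^2 + beta1 |Phi|_1 + beta2 sum_i |Phi[i, ]|_2 +
#' beta3 |Phi G|_1` for a given coefficient matrix. Used for convergence
#' monitoring and solver regression tests.
#'
#' @param phi `F x T` coefficient matrix.
#' @param x List of `N x F` task feature matrices (or a single matrix).
#' @param y Target vector of length `N` (shared across tasks) or a list of
#'   per-task target vectors.
#' @param config An [flsgl_config()].
#'
#' @return The scalar objective value.
#' @export
flsgl_objective <- function(phi, x, y, config = flsgl_config()) {
  tasks <- normalize_tasks(x, y)
  phi <- as.matrix(phi)
  assert_that(nrow(phi) == tasks$n_features && ncol(phi) == tasks$n_tasks,
              "`phi` must be F x T for these tasks")
  g <- fusion_matrix(tasks$n_tasks, config$sigma)
  fit_err <- sum(vapply(seq_len(tasks$n_tasks), function(t) {
    sum((tasks$y[[t]] - tasks$x[[t]] %*% phi[, t])^2)
  }, numeric(1)))
  fit_err +
    config$beta1 * sum(abs(phi)) +
    config$beta2 * sum(sqrt(rowSums(phi^2))) +
    config$beta3 * sum(abs(phi %*% g))
}

#' Fit the fused Laplacian sparse group LASSO
#'
#' Multitask linear regression of a shared target (typically observed
#' follow-up time) on per-time-point feature matrices, with three convex
#' penalties: elementwise L1 (sparsity within each task), row-wise L2,1
#' (joint selection of a feature across all time points) and L1 on the
#' kernel-fused residuals `Phi G` (temporal smoothness of the coefficients).
#'
#' Two solvers are provided. The default, `"apg"`, is a monotone accelerated
#' proximal gradient method (MFISTA): the nonsmooth penalty is separable
#' across coefficient rows and its proximal operator is evaluated in closed
#' form for one or two time points by composing the fused-difference prox,
#' elementwise soft-thresholding and row-wise group soft-thresholding (the
#' composition is exact for chain-structured fusion); for three or more time
#' points the row prox is solved by a short inner splitting iteration. The
#' monotone acceptance step guarantees a non-increasing objective trace.
#' `"admm"` is a multiblock ADMM with splitting variables for the L1, group
#' and fused blocks coordinated by scaled dual ascent; its objective trace
#' can oscillate transiently, but both solvers reach the same optimum of this
#' convex objective.
#'
#' Features are expected to be standardized (zero mean, unit variance per
#' column) so the penalties act comparably across features; the
#' cross-validation pipeline performs that standardization on training folds.
#'
#' @param x A single `N x F` matrix (one task) or a list of row-aligned
#'   `N x F` matrices, one per time point.
#' @param y Numeric target vector of length `N`, shared across tasks (the
#'   usual case: one overall-survival time per patient), or a list of
#'   per-task targets.
#' @param config An [flsgl_config()].
#' @param solver `"apg"` (monotone accelerated proximal gradient, default)
#'   or `"admm"` (multiblock ADMM).
#'
#' @return An object of class `flsgl` with elements `coefficients` (`F x T`
#'   matrix `Phi`), `residual_matrix` (`P = Phi G` at convergence), `fusion`
#'   (`G`), `objective` (per-iteration trace of the penalized objective),
#'   `converged`, `n_iter`, `feature_names`, `task_names`, `solver` and the
#'   `config` used. Deterministic given the inputs: both solvers start from
#'   zero coefficients (and zero duals), and the objective is convex.
#' @export
#' @examples
#' set.seed(1)
#' x <- scale(matrix(rnorm(50 * 8), 50, 8))
#' y <- x[, 1] - 0.5 * x[, 2] + rnorm(50, sd = 0.1)
#' fit <- fit_flsgl(x, y, flsgl_config(beta1 = 2, beta2 = 0, beta3 = 0))
#' selected_features(fit)
fit_flsgl <- function(x, y, config = flsgl_config(), solver = c("apg", "admm")) {
  solver <- match.arg(solver)
  tasks <- normalize_tasks(x, y)
  if (config$log_time) tasks$y <- lapply(tasks$y, log)
  if (isTRUE(config$relative)) {
    lam_max <- flsgl_penalty_scale(tasks$x, tasks$y)
    config$beta1 <- config$beta1 * lam_max
    config$beta2 <- config$beta2 * lam_max
    config$beta3 <- config$beta3 * lam_max
    config$relative <- FALSE
  }
  g <- fusion_matrix(tasks$n_tasks, config$sigma)

  res <- if (solver == "apg") {
    fit_flsgl_apg(tasks, g, config)
  } else {
    fit_flsgl_admm(tasks, g, config)
  }
  if (!res$converged) {
    warning("FLSGL solver (", solver, ") did not reach tolerance ",
            config$tol, " within ", config$max_iter, " iterations",
            call. = FALSE)
  }
  coef_out <- res$coefficients
  dimnames(coef_out) <- list(tasks$feature_names, tasks$task_names)
  structure(list(coefficients = coef_out,
                 residual_matrix = res$residual_matrix,
                 fusion = g,
                 weights = if (tasks$n_tasks >= 2) {
                   task_weights(tasks$n_tasks, config$sigma)
                 },
                 objective = res$objective,
                 converged = res$converged,
                 n_iter = res$n_iter,
                 solver = solver,
                 n = tasks$n, n_features = tasks$n_features,
                 n_tasks = tasks$n_tasks,
                 feature_names = tasks$feature_names,
                 task_names = tasks$task_names,
                 config = config),
            class = "flsgl")
}

#' Penalty ceiling of an FLSGL problem
#'
#' The smallest group-LASSO penalty that forces every coefficient to zero:
#' `2 * max_i ||(X_1' y_1, ..., X_T' y_T)_i||_2` over feature rows `i`, with
#' per-task targets centered. Relative penalty fractions
#' (`flsgl_config(relative = TRUE)`) are multiplied by this value, which
#' plays the role glmnet's `lambda.max` plays for the LASSO path.
#'
#' @param x Task feature matrix or list of matrices (standardized).
#' @param y Target vector or list of per-task targets.
#'
#' @return Positive scalar.
#' @export
flsgl_penalty_scale <- function(x, y) {
  tasks <- if (is.list(x) && !is.data.frame(x) && is.list(y) &&
               length(y) == length(x) && !is.data.frame(y)) {
    list(x = lapply(x, as_feature_matrix), y = lapply(y, as.numeric))
  } else {
    tl <- normalize_tasks(x, y)
    list(x = tl$x, y = tl$y)
  }
  xty <- vapply(seq_along(tasks$x), function(t) {
    drop(crossprod(tasks$x[[t]], tasks$y[[t]] - mean(tasks$y[[t]])))
  }, numeric(ncol(tasks$x[[1]])))
  xty <- matrix(xty, ncol = length(tasks$x))
  2 * max(sqrt(rowSums(xty^2)))
}

# Proximal operator of s * (b1 |v|_1 + b2 |v|_2 + b3 |G' v|_1) applied to
# every row of the F x T matrix v. Exact closed form for T <= 2 (compose
# fused prox, soft-threshold, group soft-threshold); short inner ADMM for
# T >= 3 where the dense fusion breaks the chain structure.
prox_sparse_group_fused <- function(v, s, config, g) {
  n_tasks <- ncol(v)
  b1 <- config$beta1; b2 <- config$beta2; b3 <- config$beta3
  if (n_tasks == 1) {
    # |G' v|_1 collapses to |v| when there is a single task
    return(group_soft_threshold(soft_threshold(v, s * (b1 + b3)), s * b2))
  }
  if (n_tasks == 2) {
    # each row of Phi G is (v1 - v2, v2 - v1): a two-point fused chain
    lam <- 2 * s * b3
    mid <- (v[, 1] + v[, 2]) / 2
    half <- soft_threshold((v[, 1] - v[, 2]) / 2, lam)
    fused <- cbind(mid + half, mid - half)
    return(group_soft_threshold(soft_threshold(fused, s * b1), s * b2))
  }
  prox_row_inner(v, s, config, g)
}

# Inner splitting solve of the row prox for T >= 3, vectorized across rows.
prox_row_inner <- function(v, s, config, g, rho = 1, iters = 300L) {
  b1 <- s * config$beta1; b2 <- s * config$beta2; b3 <- s * config$beta3
  inv_small <- solve(diag(ncol(v)) * (1 + rho) + rho * g %*% t(g))
  a <- v; d <- b <- ud <- ub <- 0 * v
  b <- a %*% g
  for (i in seq_len(iters)) {
    a <- (v + rho * (d - ud) + rho * (b - ub) %*% t(g)) %*% inv_small
    ag <- a %*% g
    d_new <- group_soft_threshold(soft_threshold(a + ud, b1 / rho), b2 / rho)
    b <- soft_threshold(ag + ub, b3 / rho)
    ud <- ud + a - d_new
    ub <- ub + ag - b
    if (max(abs(d_new - d)) < 1e-13 && i > 5) {
      d <- d_new
      break
    }
    d <- d_new
  }
  d
}

# Monotone accelerated proximal gradient (MFISTA) on the FLSGL objective.
fit_flsgl_apg <- function(tasks, g, config) {
  n_feat <- tasks$n_features
  n_tasks <- tasks$n_tasks
  xtx <- lapply(tasks$x, crossprod)
  xty <- vapply(seq_len(n_tasks),
                function(t) drop(crossprod(tasks$x[[t]], tasks$y[[t]])),
                numeric(n_feat))
  xty <- matrix(xty, n_feat, n_tasks)
  lip <- 2 * max(vapply(xtx, function(m) {
    eigen(m, symmetric = TRUE, only.values = TRUE)$values[1]
  }, numeric(1)))
  step <- 1 / lip

  grad <- function(phi) {
    out <- matrix(0, n_feat, n_tasks)
    for (t in seq_len(n_tasks)) {
      out[, t] <- 2 * (xtx[[t]] %*% phi[, t] - xty[, t])
    }
    out
  }

  x_cur <- matrix(0, n_feat, n_tasks)
  y_cur <- x_cur
  f_cur <- flsgl_objective_fast(x_cur, tasks, g, config)
  t_cur <- 1
  objective <- numeric(config$max_iter)
  converged <- FALSE
  n_iter <- config$max_iter

  for (it in seq_len(config$max_iter)) {
    z <- prox_sparse_group_fused(y_cur - step * grad(y_cur), step, config, g)
    f_z <- flsgl_objective_fast(z, tasks, g, config)
    # monotone acceptance: keep the better of the accelerated candidate and
    # the incumbent, so the trace cannot increase
    if (f_z <= f_cur) {
      x_new <- z
      f_new <- f_z
    } else {
      x_new <- x_cur
      f_new <- f_cur
      t_cur <- 1 # restart momentum when the candidate overshoots
    }
    t_new <- (1 + sqrt(1 + 4 * t_cur^2)) / 2
    y_cur <- x_new + (t_cur / t_new) * (z - x_new) +
      ((t_cur - 1) / t_new) * (x_new - x_cur)
    step_change <- max(abs(z - x_cur))
    x_cur <- x_new
    f_prev <- f_cur
    f_cur <- f_new
    t_cur <- t_new
    objective[it] <- f_cur
    if (step_change <= config$tol * max(1, max(abs(x_cur))) &&
        abs(f_prev - f_cur) <= config$tol * max(1, abs(f_cur))) {
      converged <- TRUE
      n_iter <- it
      break
    }
  }
  list(coefficients = x_cur,
       residual_matrix = x_cur %*% g,
       objective = objective[seq_len(n_iter)],
       converged = converged,
       n_iter = n_iter)
}

# Multiblock ADMM with scaled duals: splits Z1 = Phi (L1 prox), Z2 = Phi
# (group prox) and P = Phi G (fused L1 prox); the smooth least-squares block
# is a linear solve whose normal matrix is factorized once.
fit_flsgl_admm <- function(tasks, g, config) {
  n_feat <- tasks$n_features
  n_tasks <- tasks$n_tasks
  ggt <- g %*% t(g)
  delta <- config$delta

  nv <- n_feat * n_tasks
  m <- kronecker(ggt, diag(n_feat)) * delta + diag(2 * delta, nv)
  xty <- matrix(0, n_feat, n_tasks)
  for (t in seq_len(n_tasks)) {
    idx <- (t - 1) * n_feat + seq_len(n_feat)
    m[idx, idx] <- m[idx, idx] + 2 * crossprod(tasks$x[[t]])
    xty[, t] <- crossprod(tasks$x[[t]], tasks$y[[t]])
  }
  ch <- chol(m)

  phi <- matrix(0, n_feat, n_tasks)
  z1 <- z2 <- u1 <- u2 <- phi
  p <- u3 <- phi %*% g
  objective <- numeric(config$max_iter)
  converged <- FALSE
  n_iter <- config$max_iter

  for (it in seq_len(config$max_iter)) {
    rhs <- 2 * xty + delta * ((z1 - u1) + (z2 - u2) + (p - u3) %*% t(g))
    phi <- matrix(backsolve(ch, forwardsolve(t(ch), as.vector(rhs))),
                  n_feat, n_tasks)
    z1_old <- z1; z2_old <- z2; p_old <- p
    z1 <- soft_threshold(phi + u1, config$beta1 / delta)
    z2 <- group_soft_threshold(phi + u2, config$beta2 / delta)
    phig <- phi %*% g
    p <- soft_threshold(phig + u3, config$beta3 / delta)
    u1 <- u1 + phi - z1
    u2 <- u2 + phi - z2
    u3 <- u3 + phig - p

    # trace at the sparse consensus iterate (what the fit reports)
    cons <- z1
    cons[sqrt(rowSums(z2^2)) == 0, ] <- 0
    objective[it] <- flsgl_objective_fast(cons, tasks, g, config)
    r_primal <- sqrt(frobenius(phi - z1)^2 + frobenius(phi - z2)^2 +
                       frobenius(phig - p)^2)
    s_dual <- delta * sqrt(frobenius(z1 - z1_old)^2 +
                             frobenius(z2 - z2_old)^2 +
                             frobenius((p - p_old) %*% t(g))^2)
    scale_ref <- max(1, frobenius(phi))
    if (r_primal <= config$tol * scale_ref && s_dual <= config$tol * scale_ref) {
      converged <- TRUE
      n_iter <- it
      break
    }
  }
  coef_out <- z1
  coef_out[sqrt(rowSums(z2^2)) == 0, ] <- 0
  list(coefficients = coef_out,
       residual_matrix = p,
       objective = objective[seq_len(n_iter)],
       converged = converged,
       n_iter = n_iter)
}

# Objective without revalidation, for the per-iteration trace.
flsgl_objective_fast <- function(phi, tasks, g, config) {
  fit_err <- 0
  for (t in seq_len(tasks$n_tasks)) {
    fit_err <- fit_err + sum((tasks$y[[t]] - tasks$x[[t]] %*% phi[, t])^2)
  }
  fit_err +
    config$beta1 * sum(abs(phi)) +
    config$beta2 * sum(sqrt(rowSums(phi^2))) +
    config$beta3 * sum(abs(phi %*% g))
}

#' Predict the linear multitask response
#'
#' Evaluates `X phi_t` for one task's feature matrix, the primary linear
#' prediction of the multitask regression.
#'
#' @param object A fitted [fit_flsgl()] model.
#' @param newdata `N x F` feature matrix (or data frame), standardized with
#'   the training transform.
#' @param task Task index or task name.
#' @param ... Unused.
#'
#' @return Numeric vector of length `N`.
#' @export
predict.flsgl <- function(object, newdata, task = 1, ...) {
  x <- as_feature_matrix(newdata)
  if (is.character(task)) {
    task <- match(task, object$task_names)
  }
  assert_that(!is.na(task) && task >= 1 && task <= object$n_tasks,
              "unknown task index or name")
  assert_that(ncol(x) == object$n_features,
              "`newdata` must have the same features as the training data")
  drop(x %*% object$coefficients[, task])
}

#' Features selected by an FLSGL fit
#'
#' A feature is selected when any of its per-task coefficients exceeds the
#' threshold in absolute value, i.e. the row of `Phi` is active for at least
#' one time point.
#'
#' @param object A fitted [fit_flsgl()] model.
#' @param threshold Absolute coefficient threshold; defaults to the value in
#'   the fit's config.
#'
#' @return A tibble with columns `feature` and `max_abs_coef`, ordered by
#'   descending maximum absolute coefficient (ties broken by feature index).
#' @export
selected_features <- function(object, threshold = NULL) {
  assert_that(inherits(object, "flsgl"), "`object` must be an flsgl fit")
  threshold <- threshold %||% object$config$selection_threshold
  assert_that(threshold >= 0, "`threshold` must be >= 0")
  max_abs <- apply(abs(object$coefficients), 1, max)
  keep <- which(max_abs > threshold)
  ord <- keep[order(-max_abs[keep], keep)]
  tibble::tibble(feature = object$feature_names[ord],
                 max_abs_coef = unname(max_abs[ord]))
}

#' @export
print.flsgl <- function(x, ...) {
  n_sel <- nrow(selected_features(x))
  cat("Fused Laplacian sparse group LASSO fit\n")
  cat(sprintf("  %d features x %d tasks, n = %d\n",
              x$n_features, x$n_tasks, x$n))
  cat(sprintf("  penalties: beta1 = %g, beta2 = %g, beta3 = %g\n",
              x$config$beta1, x$config$beta2, x$config$beta3))
  cat(sprintf("  solver %s: %d iterations, %s; objective %.6g\n",
              x$solver, x$n_iter,
              if (x$converged) "converged" else "NOT converged",
              utils::tail(x$objective, 1)))
  cat(sprintf("  selected features: %d\n", n_sel))
  invisible(x)
}
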