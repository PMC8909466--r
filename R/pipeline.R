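#' Stratified k-fold assignment
#'
#' Deterministic, event-stratified fold assignment: patients are shuffled
#' within the event and censored strata separately and dealt out so that
#' fold sizes differ by at most one and per-fold event counts differ by at
#' most one from proportional allocation — the prevalence of survival events
#' is similar in every training and testing subset.
#'
#' @param event 0/1 event indicator vector.
#' @param k Number of folds (`2 <= k <= length(event)`).
#' @param seed Integer seed; the same seed always yields the same
#'   assignment.
#'
#' @return Integer vector of fold labels in `1..k`.
#' @export
stratified_kfold <- function(event, k, seed = 1) {
  n <- length(event)
  assert_that(k >= 2 && k <= n, "`k` must be between 2 and the cohort size")
  assert_that(all(event %in% c(0, 1)), "`event` must be a 0/1 indicator")
  fold <- integer(n)
  with_seed(seed, {
    counts <- integer(k)
    for (stratum in c(1, 0)) {
      idx <- which(event == stratum)
      if (length(idx) == 0) next
      idx <- idx[sample.int(length(idx))]
      # deal the shuffled stratum across folds, least-loaded folds first so
      # total fold sizes stay within one of each other
      order_folds <- order(counts, seq_len(k))
      assign_to <- rep(order_folds, length.out = length(idx))
      fold[idx] <- assign_to
      counts <- counts + tabulate(assign_to, nbins = k)
    }
  })
  fold
}

#' Delta features between two time points
#'
#' Elementwise feature differences `mid - pre` for row-aligned patient
#' feature matrices with identical feature names: the classical
#' delta-radiomics predictor construction, producing a single-task dataset.
#'
#' @param pre,mid `N x F` matrices (or data frames) for the two time points,
#'   same patients in the same order and the same feature columns.
#'
#' @return An `N x F` matrix of differences.
#' @export
delta_features <- function(pre, mid) {
  pre <- as_feature_matrix(pre)
  mid <- as_feature_matrix(mid)
  assert_that(all(dim(pre) == dim(mid)),
              "`pre` and `mid` must have identical dimensions")
  if (!is.null(colnames(pre)) && !is.null(colnames(mid))) {
    assert_that(identical(colnames(pre), colnames(mid)),
                "`pre` and `mid` must have identical feature columns")
  }
  if (!is.null(rownames(pre)) && !is.null(rownames(mid))) {
    assert_that(identical(rownames(pre), rownames(mid)),
                "`pre` and `mid` must be row-aligned on the same patients")
  }
  mid - pre
}

# Per-mode task construction: returns list(modality -> list(taskname -> N x F
# matrix)) of raw (unstandardized) matrices.
prepare_tasks <- function(features, mode, modalities = NULL,
                          timepoints = NULL) {
  tm <- task_matrices(features)
  modalities <- modalities %||% attr(tm, "modalities")
  assert_that(all(modalities %in% attr(tm, "modalities")),
              "unknown modality requested")
  out <- list()
  for (mod in modalities) {
    tps <- timepoints %||% names(tm[[mod]])
    tps <- intersect(tps, names(tm[[mod]]))
    if (mode == "multitask") {
      assert_that(length(tps) >= 2,
                  "multitask mode needs at least two time points")
      out[[mod]] <- tm[[mod]][tps]
    } else if (mode == "single_task_pre") {
      out[[mod]] <- tm[[mod]][tps[1]]
    } else if (mode == "single_task_mid") {
      assert_that(length(tps) >= 2,
                  "single_task_mid needs a second time point")
      out[[mod]] <- tm[[mod]][tps[2]]
    } else if (mode == "delta") {
      assert_that(length(tps) >= 2, "delta mode needs both time points")
      out[[mod]] <- stats::setNames(
        list(delta_features(tm[[mod]][[tps[1]]], tm[[mod]][[tps[2]]])),
        "delta")
    } else {
      stop("unknown mode: ", mode, call. = FALSE)
    }
  }
  out
}

# Standardize one task matrix with train-fold statistics; drops columns that
# are constant on the training rows. Returns train and test pieces.
standardize_task <- function(m, train_idx, test_idx) {
  mu <- colMeans(m[train_idx, , drop = FALSE])
  sd_ <- apply(m[train_idx, , drop = FALSE], 2, stats::sd)
  keep <- which(sd_ > 1e-12)
  scale_cols <- function(rows) {
    sweep(sweep(m[rows, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], `/`)
  }
  list(train = scale_cols(train_idx), test = scale_cols(test_idx),
       keep = keep, center = mu[keep], scale = sd_[keep])
}

# Fit the selector + booster on one train/test split of prepared tasks.
# Returns test risk, survival at horizon, and the selected feature table.
fit_fold <- function(tasks, train_idx, test_idx, time, event, params) {
  sel_list <- list()
  train_cols <- list()
  test_cols <- list()
  y_train <- time[train_idx]
  for (mod in names(tasks)) {
    std <- lapply(tasks[[mod]], standardize_task, train_idx = train_idx,
                  test_idx = test_idx)
    if (params$selector == "none") {
      sel_feats <- colnames(std[[1]]$train)
    } else {
      cfg <- params$config
      if (params$selector == "lasso") {
        cfg$beta2 <- 0
        cfg$beta3 <- 0
      }
      x_list <- lapply(std, `[[`, "train")
      fit <- fit_flsgl(x_list, y_train, cfg, solver = params$solver)
      sel <- selected_features(fit)
      if (nrow(sel) == 0) {
        # a fold must still produce a prediction: fall back to the single
        # feature with the largest absolute coefficient
        warning("no features selected in a fold; falling back to top-1 by |coefficient|",
                call. = FALSE)
        max_abs <- apply(abs(fit$coefficients), 1, max)
        sel_feats <- fit$feature_names[which.max(max_abs)]
      } else {
        sel_feats <- sel$feature
      }
    }
    sel_list[[mod]] <- tibble::tibble(modality = mod, feature = sel_feats)
    for (tp in names(std)) {
      cols <- intersect(sel_feats, colnames(std[[tp]]$train))
      if (length(cols) == 0) next
      lbl <- paste(mod, tp, cols, sep = "__")
      tr <- std[[tp]]$train[, cols, drop = FALSE]
      te <- std[[tp]]$test[, cols, drop = FALSE]
      colnames(tr) <- colnames(te) <- lbl
      train_cols[[length(train_cols) + 1]] <- tr
      test_cols[[length(test_cols) + 1]] <- te
    }
  }
  x_train <- do.call(cbind, train_cols)
  x_test <- do.call(cbind, test_cols)
  booster <- fit_cwgbs(x_train, time[train_idx], event[train_idx],
                       n_estimators = params$n_estimators,
                       learning_rate = params$learning_rate)
  surv <- suppressWarnings(
    predict(booster, x_test, type = "survival", horizons = params$horizon))
  list(risk = predict(booster, x_test, type = "risk"),
       surv_horizon = drop(surv),
       selected = dplyr::bind_rows(sel_list),
       n_features_used = ncol(x_train))
}

#' Nested grid search over FLSGL penalties
#'
#' Inner stratified cross-validation over a penalty grid, selecting the
#' combination with the highest inner-validation pooled c-index. Ties are
#' broken toward stronger regularization (larger `beta1`), then grid order.
#' Run inside training folds only, so hyperparameter tuning never sees test
#' patients.
#'
#' @param features Wide feature table (training patients only).
#' @param outcomes Outcome table (`patient_id`, `time`, `event`) aligned
#'   with `features`.
#' @param grid Data frame of candidate `beta1`, `beta2`, `beta3` rows.
#' @param mode Experiment mode (see [run_experiment()]).
#' @param config Base [flsgl_config()]; each grid row overrides its
#'   penalties.
#' @param inner_folds Number of inner CV folds (default 3).
#' @param seed Seed for the inner fold assignment.
#' @param ... Passed to the fold fitter: `modalities`, `timepoints`,
#'   `n_estimators`, `learning_rate`, `horizon`, `solver`, `selector`.
#'
#' @return The winning grid row as a one-row tibble with its
#'   `inner_c_index`.
#' @export
nested_grid_search <- function(features, outcomes, grid, mode = "multitask",
                               config = pipeline_config(), inner_folds = 3,
                               seed = 1, ...) {
  grid <- tibble::as_tibble(grid)
  assert_that(nrow(grid) >= 1, "`grid` must be nonempty")
  if (nrow(grid) == 1) {
    return(dplyr::mutate(grid, inner_c_index = NA_real_))
  }
  dots <- list(...)
  params <- list(selector = dots$selector %||% "flsgl",
                 solver = dots$solver %||% "apg",
                 n_estimators = dots$n_estimators %||% 15,
                 learning_rate = dots$learning_rate %||% 1,
                 horizon = dots$horizon %||% 24)
  tasks <- prepare_tasks(features, mode, dots$modalities, dots$timepoints)
  time <- outcomes$time; event <- outcomes$event

  fold <- stratified_kfold(event, inner_folds, seed)
  attempt <- 0
  while (any(vapply(seq_len(inner_folds),
                    function(f) sum(event[fold != f]) == 0, logical(1))) &&
         attempt < 10) {
    # degenerate inner split (an event-free training part): reshuffle
    attempt <- attempt + 1
    fold <- stratified_kfold(event, inner_folds, seed + attempt)
  }

  scores <- vapply(seq_len(nrow(grid)), function(gi) {
    cfg <- config
    cfg$beta1 <- grid$beta1[gi]
    cfg$beta2 <- grid$beta2[gi] %||% cfg$beta2
    cfg$beta3 <- grid$beta3[gi] %||% cfg$beta3
    p <- params
    p$config <- cfg
    risk <- numeric(length(time))
    for (f in seq_len(inner_folds)) {
      res <- fit_fold(tasks, which(fold != f), which(fold == f),
                      time, event, p)
      risk[fold == f] <- res$risk
    }
    c_index(time, event, risk)
  }, numeric(1))

  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  cand <- cand[order(-grid$beta1[cand], cand)][1]
  dplyr::mutate(grid[cand, ], inner_c_index = scores[cand])
}

#' Run a repeated cross-validated survival prediction experiment
#'
#' The full pipeline on one cohort: stratified k-fold cross-validation
#' repeated with different seeds; inside every training fold, per-feature
#' standardization, FLSGL feature selection per modality (multitask across
#' time points, single time point, or delta differences, depending on
#' `mode`), pooling of the selected features' standardized values across
#' modalities and time points, and a component-wise gradient boosting
#' survival model producing test-fold risk scores and survival
#' probabilities at the evaluation horizon. All fitting — standardization,
#' selection, hyperparameter search and boosting — is confined to training
#' folds.
#'
#' @param features Wide feature table: `patient_id` plus
#'   `<modality>__<timepoint>__<feature>` columns.
#' @param outcomes Tibble with `patient_id`, `time` (> 0) and `event` (0/1),
#'   aligned with `features` by `patient_id`.
#' @param mode `"multitask"` (joint selection across time points, default),
#'   `"single_task_pre"`, `"single_task_mid"`, or `"delta"` (mid - pre
#'   differences).
#' @param modalities Modalities to use; default all present.
#' @param timepoints Time points to use; default all present, in table
#'   order (first = pre-treatment).
#' @param selector `"flsgl"` (default), `"lasso"` (FLSGL with the group and
#'   fusion penalties off — plain L1), or `"none"` (no selection; all
#'   features enter the booster, as in a small clinical-variable benchmark).
#' @param config Base [flsgl_config()].
#' @param grid Optional data frame of `beta1`, `beta2`, `beta3` candidates
#'   for [nested_grid_search()] inside each training fold; `NULL` (default)
#'   uses `config`'s penalties directly.
#' @param inner_folds Inner CV folds for the grid search.
#' @param n_estimators,learning_rate Booster settings (defaults 15 and 1).
#' @param horizon Evaluation horizon for survival probabilities and the
#'   Brier/IPA metrics (default 24 months).
#' @param folds,repeats Outer CV structure (defaults 10 and 15).
#' @param seed Base seed; repeat `r` uses `seed + r - 1`.
#' @param solver FLSGL solver (see [fit_flsgl()]).
#'
#' @return An object of class `cv_experiment`: `predictions` (tibble with
#'   `repeat_id`, `fold`, `patient_id`, `risk`, `surv_horizon`), `metrics`
#'   (per-repeat `c_index`, `brier_model`, `brier_null`, `ipa_percent`),
#'   `selected` (per repeat x fold selected features), `tuned` (per-fold
#'   winning grid rows when a grid was searched), `outcomes`, and the
#'   experiment settings.
#' @export
run_experiment <- function(features, outcomes,
                           mode = c("multitask", "single_task_pre",
                                    "single_task_mid", "delta"),
                           modalities = NULL, timepoints = NULL,
                           selector = c("flsgl", "lasso", "none"),
                           config = pipeline_config(), grid = NULL,
                           inner_folds = 3,
                           n_estimators = 15, learning_rate = 1,
                           horizon = 24, folds = 10, repeats = 15,
                           seed = 1, solver = c("apg", "admm")) {
  mode <- match.arg(mode)
  selector <- match.arg(selector)
  solver <- match.arg(solver)
  assert_that(is.data.frame(outcomes) &&
                all(c("patient_id", "time", "event") %in% names(outcomes)),
              "`outcomes` needs columns patient_id, time, event")
  assert_that(identical(outcomes$patient_id, features$patient_id),
              "`features` and `outcomes` must be aligned on patient_id")
  check_survival_args(outcomes$time, outcomes$event)

  tasks <- prepare_tasks(features, mode, modalities, timepoints)
  time <- outcomes$time; event <- outcomes$event
  n <- length(time)
  params <- list(selector = selector, config = config, solver = solver,
                 n_estimators = n_estimators, learning_rate = learning_rate,
                 horizon = horizon)

  pred_rows <- list()
  sel_rows <- list()
  tuned_rows <- list()
  metric_rows <- list()

  for (r in seq_len(repeats)) {
    rep_seed <- seed + r - 1
    fold <- stratified_kfold(event, folds, rep_seed)
    risk <- surv <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      p <- params
      if (!is.null(grid) && nrow(grid) > 1) {
        win <- nested_grid_search(features[tr, ], outcomes[tr, ], grid,
                                  mode = mode, config = config,
                                  inner_folds = inner_folds,
                                  seed = rep_seed * 100 + f,
                                  modalities = modalities,
                                  timepoints = timepoints,
                                  selector = selector, solver = solver,
                                  n_estimators = n_estimators,
                                  learning_rate = learning_rate,
                                  horizon = horizon)
        p$config$beta1 <- win$beta1
        p$config$beta2 <- win$beta2 %||% p$config$beta2
        p$config$beta3 <- win$beta3 %||% p$config$beta3
        tuned_rows[[length(tuned_rows) + 1]] <-
          dplyr::mutate(win, repeat_id = r, fold = f)
      }
      res <- fit_fold(tasks, tr, te, time, event, p)
      risk[te] <- res$risk
      surv[te] <- res$surv_horizon
      pred_rows[[length(pred_rows) + 1]] <- tibble::tibble(
        repeat_id = r, fold = f, patient_id = outcomes$patient_id[te],
        risk = res$risk, surv_horizon = res$surv_horizon)
      sel_rows[[length(sel_rows) + 1]] <-
        dplyr::mutate(res$selected, repeat_id = r, fold = f)
    }
    bm <- ipcw_brier(time, event, surv, horizon)
    km_null <- km_stepfun(time, event)(horizon)
    bn <- ipcw_brier(time, event, rep(km_null, n), horizon)
    metric_rows[[r]] <- tibble::tibble(
      repeat_id = r, c_index = c_index(time, event, risk),
      brier_model = bm, brier_null = bn, ipa_percent = ipa(bm, bn))
  }

  structure(list(predictions = dplyr::bind_rows(pred_rows),
                 metrics = dplyr::bind_rows(metric_rows),
                 selected = dplyr::bind_rows(sel_rows),
                 tuned = dplyr::bind_rows(tuned_rows),
                 outcomes = outcomes,
                 mode = mode, selector = selector, horizon = horizon,
                 folds = folds, repeats = repeats, seed = seed,
                 config = config),
            class = "cv_experiment")
}

#' Compare cross-validated models
#'
#' Friedman rank test across all models' per-repeat c-index values
#' (repeats are the blocks), plus pairwise Wilcoxon signed-rank tests of
#' every model against a designated benchmark.
#'
#' @param ... Named [run_experiment()] results (at least two), all run with
#'   the same `repeats`.
#' @param benchmark Name of the benchmark model for the Wilcoxon
#'   comparisons; default the last one.
#'
#' @return An object of class `model_comparison`: `scores` (models x
#'   repeats c-index matrix), `friedman` (one-row tibble), `wilcoxon`
#'   (one row per non-benchmark model), `summary` (per-model mean c-index
#'   and IPA).
#' @export
compare_experiments <- function(..., benchmark = NULL) {
  models <- list(...)
  if (length(models) == 1 && is.list(models[[1]]) &&
      !inherits(models[[1]], "cv_experiment")) {
    models <- models[[1]]
  }
  assert_that(length(models) >= 2 && !is.null(names(models)) &&
                all(nzchar(names(models))),
              "supply at least two named cv_experiment objects")
  assert_that(all(vapply(models, inherits, logical(1), "cv_experiment")),
              "all arguments must be cv_experiment objects")
  reps <- vapply(models, function(m) nrow(m$metrics), integer(1))
  assert_that(length(unique(reps)) == 1,
              "all models must have the same number of repeats")
  scores <- t(vapply(models, function(m) m$metrics$c_index,
                     numeric(reps[1])))
  rownames(scores) <- names(models)
  benchmark <- benchmark %||% names(models)[length(models)]
  assert_that(benchmark %in% names(models), "unknown benchmark model")

  wil <- dplyr::bind_rows(lapply(
    setdiff(names(models), benchmark), function(nm) {
      out <- wilcoxon_signed_rank(scores[nm, ], scores[benchmark, ])
      dplyr::mutate(out, model = nm, benchmark = benchmark,
                    .before = 1)
    }))
  summary_tbl <- dplyr::bind_rows(lapply(names(models), function(nm) {
    m <- models[[nm]]$metrics
    tibble::tibble(model = nm, mean_c_index = mean(m$c_index),
                   c_index_low = stats::quantile(m$c_index, 0.025,
                                                 names = FALSE),
                   c_index_high = stats::quantile(m$c_index, 0.975,
                                                  names = FALSE),
                   mean_ipa = mean(m$ipa_percent))
  }))
  structure(list(scores = scores, friedman = friedman_test(scores),
                 wilcoxon = wil, summary = summary_tbl,
                 benchmark = benchmark),
            class = "model_comparison")
}

#' Median-risk stratification of pooled test predictions
#'
#' Aggregates each patient's out-of-fold risk predictions across repeats
#' (mean), splits the cohort at the median aggregated risk, and tests the
#' separation of the two Kaplan-Meier curves with a log-rank test.
#'
#' @param experiment A [run_experiment()] result.
#'
#' @return A list: `groups` (tibble with `patient_id`, `risk`, `group`),
#'   `log_rank` (one-row tibble), `curves` (tidy KM curves per group).
#' @export
risk_stratification <- function(experiment) {
  assert_that(inherits(experiment, "cv_experiment"),
              "`experiment` must be a cv_experiment")
  agg <- dplyr::summarise(
    dplyr::group_by(experiment$predictions, .data$patient_id),
    risk = mean(.data$risk), .groups = "drop")
  agg <- dplyr::left_join(agg, experiment$outcomes, by = "patient_id")
  agg$group <- ifelse(agg$risk > stats::median(agg$risk),
                      "high_risk", "low_risk")
  curves <- dplyr::bind_rows(lapply(split(agg, agg$group), function(d) {
    dplyr::mutate(km_curve(d$time, d$event), group = d$group[1])
  }))
  list(groups = agg[c("patient_id", "risk", "group")],
       log_rank = log_rank_test(agg$time, agg$event, agg$group),
       curves = curves)
}

#' @export
print.cv_experiment <- function(x, ...) {
  cat("Cross-validated survival prediction experiment\n")
  cat(sprintf("  mode: %s, selector: %s, %d-fold CV x %d repeats\n",
              x$mode, x$selector, x$folds, x$repeats))
  cat(sprintf("  mean c-index: %.3f [%.3f, %.3f], mean IPA: %.1f%% at t = %g\n",
              mean(x$metrics$c_index),
              stats::quantile(x$metrics$c_index, 0.025),
              stats::quantile(x$metrics$c_index, 0.975),
              mean(x$metrics$ipa_percent), x$horizon))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison across CV repeats\n")
  print(x$summary)
  cat(sprintf("Friedman chi-square = %.3f (df = %d), p = %.4g\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p_value))
  if (nrow(x$wilcoxon)) {
    cat("Wilcoxon signed-rank vs benchmark:\n")
    print(x$wilcoxon)
  }
  invisible(x)
}

#' Default FLSGL configuration for the cross-validation pipeline
#'
#' Penalties expressed as fractions of the training data's penalty ceiling
#' ([flsgl_penalty_scale()]), so they transfer across fold sizes and target
#' scales: a group-dominant mix (joint selection of a feature across time
#' points) with light elementwise and fusion penalties, and a log-time
#' selection target (under a proportional-hazards event model, log time is
#' linearly related to the risk score). The booster downstream consumes the
#' raw censored outcomes.
#'
#' @param ... Overrides passed to [flsgl_config()].
#'
#' @return An [flsgl_config()].
#' @export
pipeline_config <- function(...) {
  defaults <- list(beta1 = 0.05, beta2 = 0.45, beta3 = 0.05,
                   relative = TRUE, log_time = TRUE)
  args <- utils::modifyList(defaults, list(...))
  do.call(flsgl_config, args)
}
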