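#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy an FLSGL fit
#'
#' @param x A [fit_flsgl()] result.
#' @param ... Unused.
#'
#' @return A tibble with one row per feature and task: `feature`, `task`,
#'   `estimate`, `selected`.
#' @export
tidy.flsgl <- function(x, ...) {
  out <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(x$coefficients),
                  feature = x$feature_names),
    -"feature", names_to = "task", values_to = "estimate")
  sel <- selected_features(x)$feature
  dplyr::mutate(out, selected = .data$feature %in% sel)
}

#' @rdname tidy.flsgl
#' @export
glance.flsgl <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = x$n_features, n_tasks = x$n_tasks,
                 n_selected = nrow(selected_features(x)),
                 objective = utils::tail(x$objective, 1),
                 n_iter = x$n_iter, converged = x$converged,
                 solver = x$solver)
}

#' Tidy a boosting model
#'
#' @param x A [fit_cwgbs()] result.
#' @param ... Unused.
#'
#' @return The stage table: one row per boosting stage with the chosen
#'   feature and its fitted component.
#' @export
tidy.cwgbs <- function(x, ...) {
  x$stages
}

#' @rdname tidy.cwgbs
#' @export
glance.cwgbs <- function(x, ...) {
  tibble::tibble(n_stages = nrow(x$stages),
                 n_features_used = length(unique(x$stages$feature)),
                 learning_rate = x$learning_rate,
                 base_learner = x$base_learner,
                 loss_initial = x$loss[1],
                 loss_final = utils::tail(x$loss, 1))
}

#' Tidy a cross-validation experiment
#'
#' @param x A [run_experiment()] result.
#' @param ... Unused.
#'
#' @return Per-repeat metrics: `repeat_id`, `c_index`, `brier_model`,
#'   `brier_null`, `ipa_percent`.
#' @export
tidy.cv_experiment <- function(x, ...) {
  x$metrics
}

#' @rdname tidy.cv_experiment
#' @export
glance.cv_experiment <- function(x, ...) {
  tibble::tibble(mode = x$mode, selector = x$selector,
                 folds = x$folds, repeats = x$repeats,
                 mean_c_index = mean(x$metrics$c_index),
                 c_index_low = stats::quantile(x$metrics$c_index, 0.025,
                                               names = FALSE),
                 c_index_high = stats::quantile(x$metrics$c_index, 0.975,
                                                names = FALSE),
                 mean_ipa = mean(x$metrics$ipa_percent),
                 horizon = x$horizon)
}

#' Tidy a model comparison
#'
#' @param x A [compare_experiments()] result.
#' @param ... Unused.
#'
#' @return The pairwise Wilcoxon table (one row per model vs the benchmark).
#' @export
tidy.model_comparison <- function(x, ...) {
  x$wilcoxon
}

#' @rdname tidy.model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  dplyr::mutate(x$friedman, benchmark = x$benchmark)
}

#' Plot FLSGL coefficients
#'
#' Heatmap of the selected features' coefficients across tasks.
#'
#' @param object A [fit_flsgl()] result.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.flsgl <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$selected, ]
  if (nrow(td) == 0) td <- tidy(object)[seq_len(min(10, object$n_features)), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$task, y = .data$feature,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026") +
    ggplot2::labs(x = "task (time point)", y = NULL,
                  fill = "coefficient",
                  title = "FLSGL selected coefficients") +
    ggplot2::theme_minimal()
}

#' Plot the boosting loss trace
#'
#' Training Cox partial-likelihood loss after each boosting stage.
#'
#' @param object A [fit_cwgbs()] result.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.cwgbs <- function(object, ...) {
  d <- tibble::tibble(stage = seq_along(object$loss) - 1, loss = object$loss)
  ggplot2::ggplot(d, ggplot2::aes(.data$stage, .data$loss)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "boosting stage", y = "training Cox loss",
                  title = "Component-wise gradient boosting") +
    ggplot2::theme_minimal()
}

#' Plot risk-stratified Kaplan-Meier curves
#'
#' Kaplan-Meier curves of the two groups obtained by splitting the cohort
#' at the median aggregated out-of-fold risk, annotated with the log-rank
#' p-value.
#'
#' @param object A [run_experiment()] result.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.cv_experiment <- function(object, ...) {
  rs <- risk_stratification(object)
  ggplot2::ggplot(rs$curves,
                  ggplot2::aes(.data$time, .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival",
                  colour = NULL,
                  title = sprintf("Median-risk stratification (%s)",
                                  object$mode),
                  subtitle = sprintf("log-rank p = %.3g",
                                     rs$log_rank$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot per-repeat model scores
#'
#' Boxplots of the per-repeat c-index for each compared model.
#'
#' @param object A [compare_experiments()] result.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.model_comparison <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object$scores),
                  model = rownames(object$scores)),
    -"model", names_to = "repeat_id", values_to = "c_index")
  ggplot2::ggplot(d, ggplot2::aes(.data$model, .data$c_index)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "c-index per CV repeat",
                  title = "Model comparison",
                  subtitle = sprintf("Friedman p = %.3g",
                                     object$friedman$p_value)) +
    ggplot2::theme_minimal()
}
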