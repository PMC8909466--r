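#' Generate a synthetic longitudinal radiomics cohort
#'
#' Seeded generator of radiomics-like survival cohorts with known ground
#' truth, shaped like an early-phase lung-cancer imaging trial: a few dozen
#' patients, about a hundred correlated features per modality at
#' pre-treatment and mid-treatment time points, a sparse prognostic signal
#' that varies smoothly across time points, and right-censored overall
#' survival.
#'
#' Features are drawn from a block-correlated Gaussian (blocks mimic
#' redundant radiomic feature families: shape, intensity, texture);
#' mid-treatment features are a correlated evolution of the pre-treatment
#' ones. A sparse coefficient vector on `n_informative` features defines the
#' true linear risk (averaged over modalities and time points); survival
#' times follow a Weibull proportional-hazards model on that risk, and an
#' independent Weibull censoring time is calibrated by bisection on its
#' scale so the realized censoring fraction matches `censoring_rate`.
#'
#' @param n_patients Cohort size (default 45).
#' @param n_features Features per modality and time point (default 110).
#' @param n_timepoints Imaging time points (default 2: pre, mid).
#' @param n_informative Number of truly prognostic features (default 5).
#' @param modalities Character vector of modality names.
#' @param feature_correlation Within-block feature correlation in `[0, 1)`
#'   (default 0.5, blocks of `block_size`).
#' @param block_size Size of the correlated feature blocks (default 10).
#' @param timepoint_correlation Correlation between a feature at pre- and
#'   mid-treatment (default 0.7).
#' @param coefficient_smoothness Maximum relative change of a true
#'   coefficient between adjacent time points (default 0.2; 0 = identical
#'   coefficients, larger = more temporal drift).
#' @param hazard_scale Standard deviation of the true log-hazard (linear
#'   risk) across patients; controls signal strength (default 2.5).
#' @param weibull_shape,weibull_scale Baseline event-time distribution
#'   (shape 1.5: rising hazard; scale 30 months: median survival near two
#'   years).
#' @param censoring_rate Target fraction of censored patients (default 0.4,
#'   i.e. 60% events).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#'
#' @return An object of class `synthetic_cohort`: `features` (wide tibble,
#'   `patient_id` plus `<modality>__<timepoint>__<feature>` columns),
#'   `outcomes` (tibble `patient_id`, `time`, `event`), and `truth` (list
#'   with the informative-feature indices and names, the true coefficient
#'   matrix per modality, and each patient's true linear risk), plus the
#'   generator settings.
#' @export
#' @examples
#' cohort <- generate_cohort(n_patients = 30, n_features = 20, seed = 7)
#' cohort$outcomes
#' oracle_risk_cindex(cohort)
generate_cohort <- function(n_patients = 45, n_features = 110,
                            n_timepoints = 2, n_informative = 5,
                            modalities = "FDG_PET",
                            feature_correlation = 0.5, block_size = 10,
                            timepoint_correlation = 0.7,
                            coefficient_smoothness = 0.2,
                            hazard_scale = 2.5,
                            weibull_shape = 1.5, weibull_scale = 30,
                            censoring_rate = 0.4, seed = 1) {
  assert_that(n_informative <= n_features,
              "`n_informative` cannot exceed `n_features`")
  assert_that(censoring_rate >= 0 && censoring_rate < 1,
              "`censoring_rate` must be in [0, 1)")
  assert_that(feature_correlation >= 0 && feature_correlation < 1,
              "`feature_correlation` must be in [0, 1)")
  timepoint_names <- c("pre", "mid", if (n_timepoints > 2) {
    paste0("tp", seq(3, n_timepoints))
  })[seq_len(n_timepoints)]
  feature_names <- sprintf("feat%03d", seq_len(n_features))

  with_seed(seed, {
    # plant at most one informative feature per correlated block: prognostic
    # radiomic signatures span distinct feature families rather than several
    # redundant features of one family
    n_blocks <- ceiling(n_features / block_size)
    if (n_informative <= n_blocks) {
      blocks <- sample.int(n_blocks, n_informative)
      support <- sort(vapply(blocks, function(b) {
        members <- intersect(seq((b - 1) * block_size + 1, b * block_size),
                             seq_len(n_features))
        members[sample.int(length(members), 1)]
      }, integer(1)))
    } else {
      support <- sort(sample.int(n_features, n_informative))
    }

    # temporally smooth sparse coefficients, shared support across tasks
    phi_star <- matrix(0, n_features, n_timepoints,
                       dimnames = list(feature_names, timepoint_names))
    if (n_informative > 0) {
      base <- stats::runif(n_informative, 0.7, 1) *
        sample(c(-1, 1), n_informative, replace = TRUE)
      phi_star[support, 1] <- base
      if (n_timepoints > 1) {
        for (t in seq(2, n_timepoints)) {
          drift <- stats::runif(n_informative, -coefficient_smoothness,
                                coefficient_smoothness)
          phi_star[support, t] <- phi_star[support, t - 1] * (1 + drift)
        }
      }
    }

    draw_block_gaussian <- function() {
      z <- matrix(stats::rnorm(n_patients * n_features), n_patients)
      n_blocks <- ceiling(n_features / block_size)
      shared <- matrix(stats::rnorm(n_patients * n_blocks), n_patients)
      block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_features)]
      sqrt(feature_correlation) * shared[, block_of] +
        sqrt(1 - feature_correlation) * z
    }

    tasks <- list() # tasks[[modality]][[timepoint]] = N x F matrix
    risk_sum <- rep(0, n_patients)
    n_terms <- 0
    truth_phi <- list()
    for (mod in modalities) {
      x_prev <- NULL
      tasks[[mod]] <- list()
      for (t in seq_len(n_timepoints)) {
        x_t <- if (is.null(x_prev)) {
          draw_block_gaussian()
        } else {
          timepoint_correlation * x_prev +
            sqrt(1 - timepoint_correlation^2) * draw_block_gaussian()
        }
        colnames(x_t) <- feature_names
        tasks[[mod]][[timepoint_names[t]]] <- x_t
        risk_sum <- risk_sum + drop(x_t %*% phi_star[, t])
        n_terms <- n_terms + 1
        x_prev <- x_t
      }
      truth_phi[[mod]] <- phi_star
    }
    risk <- risk_sum / n_terms
    if (stats::sd(risk) > 0) {
      risk <- risk / stats::sd(risk) * hazard_scale
    }

    # Weibull proportional hazards: S(t|risk) = exp(-(t/scale)^shape * e^risk)
    u <- stats::runif(n_patients)
    event_time <- weibull_scale *
      (-log(u) / exp(risk))^(1 / weibull_shape)

    if (censoring_rate > 0) {
      uc <- stats::runif(n_patients)
      cens_quantile <- (-log(uc))^(1 / weibull_shape)
      frac_at <- function(scl) mean(scl * cens_quantile < event_time)
      lo <- 1e-6; hi <- max(event_time) * 1e3
      for (i in 1:200) {
        midp <- sqrt(lo * hi)
        if (frac_at(midp) > censoring_rate) lo <- midp else hi <- midp
      }
      # the realized fraction is a step function of the scale: take the
      # bracket end closest to the target
      cand <- c(lo, sqrt(lo * hi), hi)
      best <- cand[which.min(abs(vapply(cand, frac_at, 1) - censoring_rate))]
      cens_time <- best * cens_quantile
    } else {
      cens_time <- rep(Inf, n_patients)
    }
    achieved <- mean(cens_time < event_time)
    if (abs(achieved - censoring_rate) > 0.05) {
      warning("achieved censoring fraction ", round(achieved, 3),
              " differs from target ", censoring_rate, call. = FALSE)
    }
    obs_time <- pmin(event_time, cens_time)
    event <- as.numeric(event_time <= cens_time)

    patient_id <- sprintf("P%03d", seq_len(n_patients))
    wide <- tibble::tibble(patient_id = patient_id)
    for (mod in modalities) {
      for (tp in timepoint_names) {
        m <- tasks[[mod]][[tp]]
        colnames(m) <- paste(mod, tp, feature_names, sep = "__")
        wide <- dplyr::bind_cols(wide, tibble::as_tibble(m))
      }
    }

    structure(list(
      features = wide,
      outcomes = tibble::tibble(patient_id = patient_id,
                                time = obs_time, event = event),
      truth = list(support = support,
                   support_features = feature_names[support],
                   phi_star = truth_phi,
                   true_risk = risk,
                   latent_event_time = event_time),
      modalities = modalities,
      timepoints = timepoint_names,
      feature_names = feature_names,
      n_patients = n_patients,
      settings = list(n_features = n_features,
                      n_informative = n_informative,
                      feature_correlation = feature_correlation,
                      block_size = block_size,
                      timepoint_correlation = timepoint_correlation,
                      coefficient_smoothness = coefficient_smoothness,
                      hazard_scale = hazard_scale,
                      weibull_shape = weibull_shape,
                      weibull_scale = weibull_scale,
                      censoring_rate = censoring_rate,
                      seed = seed)),
      class = "synthetic_cohort")
  })
}

#' Oracle concordance of the true risk
#'
#' Harrell c-index of the generator's true linear risk against the generated
#' outcomes: an upper-bound reference for any fitted model on the same
#' cohort.
#'
#' @param cohort A [generate_cohort()] result.
#'
#' @return Concordance in `[0, 1]`.
#' @export
oracle_risk_cindex <- function(cohort) {
  assert_that(inherits(cohort, "synthetic_cohort"),
              "`cohort` must be a synthetic_cohort")
  if (stats::sd(cohort$truth$true_risk) == 0) {
    return(0.5) # no signal: every risk tie, concordance is one half
  }
  c_index(cohort$outcomes$time, cohort$outcomes$event,
          cohort$truth$true_risk)
}

#' Extract per-task feature matrices from a wide feature table
#'
#' Splits a wide feature table with `<modality>__<timepoint>__<feature>`
#' columns into a nested list of `N x F` matrices indexed by modality and
#' time point.
#'
#' @param features Wide feature data frame (first column `patient_id` or
#'   plain feature columns).
#'
#' @return Named list: `tasks[[modality]][[timepoint]]` matrices, plus
#'   attributes `modalities`, `timepoints`, `feature_names`.
#' @export
task_matrices <- function(features) {
  assert_that(is.data.frame(features), "`features` must be a data frame")
  cols <- setdiff(names(features), "patient_id")
  parts <- strsplit(cols, "__", fixed = TRUE)
  assert_that(all(lengths(parts) == 3),
              "feature columns must be named <modality>__<timepoint>__<feature>")
  info <- tibble::tibble(col = cols,
                         modality = vapply(parts, `[`, "", 1),
                         timepoint = vapply(parts, `[`, "", 2),
                         feature = vapply(parts, `[`, "", 3))
  out <- list()
  for (mod in unique(info$modality)) {
    out[[mod]] <- list()
    for (tp in unique(info$timepoint[info$modality == mod])) {
      sel <- info[info$modality == mod & info$timepoint == tp, ]
      m <- as.matrix(features[sel$col])
      colnames(m) <- sel$feature
      rownames(m) <- features$patient_id
      out[[mod]][[tp]] <- m
    }
  }
  attr(out, "modalities") <- unique(info$modality)
  attr(out, "timepoints") <- unique(info$timepoint)
  attr(out, "feature_names") <- unique(info$feature)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic longitudinal radiomics cohort\n")
  cat(sprintf("  %d patients, %d features x %d time point(s) x %d modality(ies)\n",
              x$n_patients, x$settings$n_features, length(x$timepoints),
              length(x$modalities)))
  cat(sprintf("  events: %d (%.0f%%), informative features: %d\n",
              sum(x$outcomes$event), 100 * mean(x$outcomes$event),
              x$settings$n_informative))
  invisible(x)
}
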