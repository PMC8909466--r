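#' Read an FLSGL configuration file
#'
#' Declarative YAML (or JSON) configuration with any of the keys accepted by
#' [flsgl_config()] — `beta1`, `beta2`, `beta3`, `sigma`, `delta`, `tol`,
#' `max_iter`, `selection_threshold`, `log_time`, `relative` — plus an
#' optional `seed`. Unknown keys are rejected.
#'
#' @param path File path.
#'
#' @return A list with elements `config` ([flsgl_config()]) and `seed`.
#' @export
read_flsgl_config <- function(path) {
  assert_that(file.exists(path), paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  seed <- vals$seed
  vals$seed <- NULL
  known <- names(formals(flsgl_config))
  unknown <- setdiff(names(vals), known)
  assert_that(length(unknown) == 0,
              paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  list(config = do.call(flsgl_config, vals), seed = seed)
}

#' Read a cohort from delimited text tables
#'
#' @param features_path CSV with a `patient_id` column and
#'   `<modality>__<timepoint>__<feature>` feature columns.
#' @param outcomes_path CSV with `patient_id`, `time`, `event` columns.
#'
#' @return A list with tibbles `features` and `outcomes`, row-aligned on
#'   `patient_id`.
#' @export
read_cohort <- function(features_path, outcomes_path) {
  features <- tibble::as_tibble(utils::read.csv(features_path,
                                                check.names = FALSE))
  outcomes <- tibble::as_tibble(utils::read.csv(outcomes_path))
  assert_that("patient_id" %in% names(features) &&
                all(c("patient_id", "time", "event") %in% names(outcomes)),
              "tables must carry patient_id (features) and patient_id/time/event (outcomes)")
  outcomes <- outcomes[match(features$patient_id, outcomes$patient_id), ]
  assert_that(!anyNA(outcomes$patient_id),
              "every patient in the feature table needs an outcome row")
  list(features = features, outcomes = outcomes)
}

#' Write a synthetic cohort to delimited text tables
#'
#' Emits the feature table, the outcome table, and a ground-truth JSON
#' (support indices, true coefficients, seed) for recovery experiments.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#'
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  assert_that(inherits(cohort, "synthetic_cohort"),
              "`cohort` must be a synthetic_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("features.csv", "outcomes.csv", "truth.json"))
  utils::write.csv(cohort$features, paths[1], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths[2], row.names = FALSE)
  truth <- list(support = cohort$truth$support,
                support_features = cohort$truth$support_features,
                phi_star = lapply(cohort$truth$phi_star, function(m) {
                  stats::setNames(as.data.frame(m), colnames(m))
                }),
                true_risk = cohort$truth$true_risk,
                settings = cohort$settings)
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
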