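# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

soft_threshold <- function(x, lambda) {
  sign(x) * pmax(abs(x) - lambda, 0)
}

# Row-wise group soft-thresholding: shrink each row's Euclidean norm.
group_soft_threshold <- function(x, lambda) {
  norms <- sqrt(rowSums(x^2))
  scale <- ifelse(norms > lambda, 1 - lambda / norms, 0)
  x * scale
}

frobenius <- function(x) sqrt(sum(x^2))

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

check_survival_args <- function(time, event) {
  assert_that(length(time) == length(event),
              "`time` and `event` must have the same length")
  assert_that(all(is.finite(time)) && all(time > 0),
              "follow-up times must be finite and strictly positive")
  assert_that(all(event %in% c(0, 1)),
              "`event` must be a 0/1 indicator")
  invisible(TRUE)
}

# Coerce a data frame (with optional patient_id column) or matrix to a
# numeric matrix of features.
as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("patient_id" %in% names(x)) x <- x[setdiff(names(x), "patient_id")]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
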