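## Internal helpers: argument checking and reproducible stream splitting.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("pollselect_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("pollselect_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a single finite number")
  if (x < lower || x > upper)
    stop_config(name, " must lie in [", lower, ", ", upper, "]")
  invisible(x)
}

#' Derive per-stage random seeds from one master seed
#'
#' All randomness in the package flows from a single user-supplied seed.
#' Stage seeds are drawn from a generator seeded with the master seed, so
#' each pipeline stage (plants, visits, seeds, bootstrap, permutation) gets
#' an independent, reproducible stream and adding a stage never perturbs
#' the draws of earlier stages with a different name.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @return A single integer seed, below 2^31.
#' @keywords internal
stage_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  ## deterministic label hash, independent of the RNG state
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 1009L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed((as.integer(seed) %% 1000003L) * 2011L + h %% 1000003L)
  sample.int(2147483646L, 1L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
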