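# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed package error
#'
#' @param msg message text.
#' @param class short error class suffix, e.g. "invalid_parameter".
#' @noRd
bld_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("bld_error_", class), "bld_error")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded operations do not
#' perturb surrounding randomness. A NULL seed evaluates the code as-is.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# scalar numeric check used by constructors
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive <- function(x, what) {
  if (!is_number(x) || x <= 0) {
    bld_abort(sprintf("%s must be a single positive finite number", what),
              "invalid_parameter")
  }
  invisible(x)
}

check_counts <- function(counts) {
  if (length(counts) == 0 || !is.numeric(counts) || any(!is.finite(counts)) ||
      any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    bld_abort("counts must be non-negative finite integers", "invalid_counts")
  }
  counts <- as.numeric(round(counts))
  if (sum(counts) <= 0) bld_abort("count vector is all zero", "empty_sample")
  counts
}
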