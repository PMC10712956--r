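# Internal helpers: condition classes and seeded evaluation.

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = "mitotherm_validation_error"))
}

abort_qc <- function(msg) {
  stop(errorCondition(msg, class = "mitotherm_qc_error"))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random
#' number generator state afterwards, so simulations are reproducible
#' without disturbing the global stream. With `seed = NULL` the code runs
#' against the current RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_validation("seed must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# scalar numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is_number(x) || x < min || x > max) {
    abort_validation(sprintf("%s must be a single finite number in [%s, %s]",
                             name, format(min), format(max)))
  }
  invisible(x)
}

# coefficient of determination; a zero-variance response is a perfect fit
rsq <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  max(0, 1 - sum((y - yhat)^2) / ss_tot)
}
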