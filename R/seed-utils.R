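#' Evaluate an expression under a local RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit.  All stochastic operations in the
#' package route their randomness through this helper so that a single seed
#' argument makes them reproducible without disturbing the session RNG.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream of child seeds from one master seed
#'
#' Deterministic derivation used to give every trial (and every auditory-nerve
#' fiber within a trial) its own independent random stream.  Derived seeds stay
#' below 2^31 so they remain valid R integers.
#'
#' @param master_seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(master_seed, n) {
  with_local_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) stopf("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stopf("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}
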