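# Decoding ramping activity by coincidence with nested fast/slow
# oscillations: the integration-period lattice
# Integration Period = p * tau_slow + q * tau_fast.

#' Nested oscillator hierarchy
#'
#' A slow oscillation whose excitation phase (first half-cycle) carries
#' `n_nested` nested fast (gamma) cycles; each fast cycle opens an excitation
#' window of `excitation_window` ms centred on its start.
#'
#' @param tau_slow slow-oscillation period (ms).
#' @param tau_fast fast-oscillation period (ms); must be shorter.
#' @param excitation_window window width (ms); the ~3 ms excitable state of
#'   a gamma cycle motivates the default.
#' @param n_nested fast cycles per excitation phase; defaults to the number
#'   of complete fast cycles fitting in the slow half-cycle.
#' @return an object of class `oscillator_hierarchy`.
#' @export
oscillator_hierarchy <- function(tau_slow, tau_fast, excitation_window = 3,
                                 n_nested = NULL) {
  check_scalar(tau_slow, "tau_slow", positive = TRUE)
  check_scalar(tau_fast, "tau_fast", positive = TRUE)
  if (tau_slow <= tau_fast) stopf("'tau_slow' must exceed 'tau_fast'")
  check_scalar(excitation_window, "excitation_window", positive = TRUE)
  if (excitation_window > tau_fast)
    stopf("'excitation_window' must not exceed 'tau_fast'")
  if (is.null(n_nested)) n_nested <- floor((tau_slow / 2) / tau_fast)
  if (n_nested < 1) stopf("no fast cycle fits in the excitation phase")
  structure(list(tau_slow = tau_slow, tau_fast = tau_fast,
                 excitation_window = excitation_window,
                 n_nested = as.integer(n_nested)),
            class = "oscillator_hierarchy")
}

#' Ramping-activity specification
#'
#' A neuron whose activity ramps linearly from `start_time` at `slope` until
#' it reaches `threshold` - an integrator whose limit of integration is set
#' by the oscillators.
#'
#' @param start_time ramp onset (ms).
#' @param slope ramp slope (a.u./ms), `> 0`.
#' @param threshold firing threshold (a.u.), `> 0`.
#' @return an object of class `ramp_spec`.
#' @export
ramp_spec <- function(start_time = 0, slope, threshold) {
  check_scalar(start_time, "start_time", nonneg = TRUE)
  check_scalar(slope, "slope", positive = TRUE)
  check_scalar(threshold, "threshold", positive = TRUE)
  structure(list(start_time = start_time, slope = slope,
                 threshold = threshold),
            class = "ramp_spec")
}

#' Integration period of a lattice point
#'
#' Exact arithmetic `p * tau_slow + q * tau_fast`; `q` must index an
#' existing nested fast cycle (`q < n_nested`).
#'
#' @param p,q non-negative integers.
#' @param h an [oscillator_hierarchy()].
#' @return time in ms.
#' @export
#' @examples
#' h <- oscillator_hierarchy(100, 25, n_nested = 3)
#' integration_period(2, 3, oscillator_hierarchy(100, 25, n_nested = 4))  # 275
integration_period <- function(p, q, h) {
  if (p < 0 || q < 0) stopf("'p' and 'q' must be >= 0")
  if (q >= h$n_nested)
    stopf("q = %d indexes no nested cycle (n_nested = %d)", q, h$n_nested)
  p * h$tau_slow + q * h$tau_fast
}

# all excitation-window centres up to a horizon, with their lattice indices
lattice_windows <- function(h, horizon) {
  p_max <- ceiling(horizon / h$tau_slow)
  p <- rep(0:p_max, each = h$n_nested)
  q <- rep(0:(h$n_nested - 1), p_max + 1)
  data.frame(p = p, q = q, center = p * h$tau_slow + q * h$tau_fast)
}

#' Decode a ramp against the nested-oscillation lattice
#'
#' The ramp crosses its threshold at `t* = start_time + threshold/slope`;
#' the coincidence-detecting neuron fires at the earliest excitation-window
#' centre at or after `t*` among the nested fast cycles, and the lattice
#' indices `(p, q)` of that window encode the integration period.
#'
#' @param ramp a [ramp_spec()].
#' @param h an [oscillator_hierarchy()].
#' @param horizon simulated horizon (ms); a ramp not crossing within it
#'   yields a no-coincidence result.
#' @return object of class `decode_result`: `coincidence_time` (ms), `p`,
#'   `q`, `lattice_residual` (ms), `crossed` (logical).
#' @export
#' @examples
#' h <- oscillator_hierarchy(100, 25, n_nested = 3)
#' decode_ramp(ramp_spec(0, slope = 1, threshold = 130), h)  # 150 ms: p=1, q=2
decode_ramp <- function(ramp, h, horizon = 10 * h$tau_slow) {
  t_star <- ramp$start_time + ramp$threshold / ramp$slope
  if (t_star > horizon) {
    return(structure(list(coincidence_time = NA_real_, p = NA_integer_,
                          q = NA_integer_, lattice_residual = NA_real_,
                          crossed = FALSE),
                     class = "decode_result"))
  }
  wins <- lattice_windows(h, horizon + h$tau_slow)
  i <- which(wins$center >= t_star - 1e-9)[1]
  structure(list(coincidence_time = wins$center[i],
                 p = wins$p[i], q = wins$q[i],
                 lattice_residual = abs(wins$center[i] -
                                          (wins$p[i] * h$tau_slow +
                                             wins$q[i] * h$tau_fast)),
                 crossed = TRUE),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  if (!x$crossed) {
    cat("<decode_result> no coincidence (ramp did not cross)\n")
  } else {
    cat(sprintf("<decode_result> t = %.3f ms = %d * tau_slow + %d * tau_fast\n",
                x$coincidence_time, x$p, x$q))
  }
  invisible(x)
}
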