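# The periodicity-analysis network: trigger, oscillator, integrator,
# coincidence detector and inhibitor, the integer coincidence equation
# m * tau_m = n * tau_c - k * tau_k, and the carrier-by-modulation
# response-matrix experiment.

#' A periodicity-analysis unit
#'
#' One column of the periodicity network: a trigger fired by each envelope
#' peak of an amplitude-modulated signal, an oscillator emitting up to
#' `n_osc_spikes` spikes at intervals `tau_k` after each trigger, an
#' integrator emitting one event `integrator_n` carrier periods after each
#' trigger, and a coincidence detector firing when an oscillator spike and an
#' integrator event fall within `coincidence_window` of each other.  The
#' inhibitor vetoes coincidences attributable to harmonics (solutions of the
#' coincidence equation with m > 1).
#'
#' @param cf characteristic frequency (Hz); the carrier period at the unit's
#'   place is `tau_c = 1000/cf` ms.
#' @param tau_k oscillator period (ms).
#' @param integrator_n integration spans this many carrier periods.
#' @param n_osc_spikes oscillator spikes emitted per trigger (beyond the
#'   trigger-synchronous spike); defaults to the largest count usable within
#'   one modulation period at the unit's tuning.
#' @param coincidence_window full width of the coincidence window (ms).
#' @param inhibition_enabled veto harmonic (m > 1) coincidences.
#' @return an object of class `periodicity_unit`.
#' @export
#' @examples
#' u <- periodicity_unit(cf = 4000, tau_k = 0.4, integrator_n = 8)
#' bmf_of_unit(u)$bmf  # ~833 Hz: 1 / (8 * 0.25 - 2 * 0.4) ms
periodicity_unit <- function(cf, tau_k, integrator_n = 8,
                             n_osc_spikes = NULL,
                             coincidence_window = 0.05,
                             inhibition_enabled = FALSE) {
  check_scalar(cf, "cf", positive = TRUE)
  check_scalar(tau_k, "tau_k", positive = TRUE)
  if (integrator_n < 1) stopf("'integrator_n' must be >= 1")
  tau_c <- 1000 / cf
  if (is.null(n_osc_spikes)) {
    # largest k with k*tau_k < n*tau_c - k*tau_k (the oscillator must fit
    # inside the modulation period it is tuned to)
    k <- floor((integrator_n * tau_c) / (2 * tau_k))
    if (k * 2 * tau_k >= integrator_n * tau_c - 1e-12) k <- k - 1
    n_osc_spikes <- max(0L, as.integer(k))
  }
  structure(list(cf = cf, tau_c = tau_c, tau_k = tau_k,
                 integrator_n = as.integer(integrator_n),
                 n_osc_spikes = as.integer(n_osc_spikes),
                 coincidence_window = coincidence_window,
                 inhibition_enabled = isTRUE(inhibition_enabled)),
            class = "periodicity_unit")
}

#' @rdname periodicity_unit
#' @param ratio target CF/BMF ratio.
#' @details `tuned_unit()` constructs a unit whose best modulation frequency
#'   is exactly `cf / ratio`, using `integrator_n = ratio + 2` carrier
#'   periods and two oscillator spikes at the carrier period
#'   (`tau_k = tau_c`), so `tau_m = (ratio + 2) tau_c - 2 tau_c =
#'   ratio * tau_c`.
#' @export
tuned_unit <- function(cf, ratio = 6, coincidence_window = 0.05,
                       inhibition_enabled = FALSE) {
  periodicity_unit(cf = cf, tau_k = 1000 / cf, integrator_n = ratio + 2,
                   n_osc_spikes = 2, coincidence_window = coincidence_window,
                   inhibition_enabled = inhibition_enabled)
}

#' Enumerate solutions of the coincidence equation
#'
#' Exhaustive enumeration of small-integer triples `(m, n, k)` with
#' `1 <= m, n <= max_int`, `0 <= k <= max_int`, giving the modulation
#' periods `tau_m = (n * tau_c - k * tau_k) / m` at which a coincidence unit
#' with carrier period `tau_c` and oscillator period `tau_k` can respond.
#' Only modulations slower than the carrier (`tau_m > tau_c`) are kept, and
#' each solution satisfies `|m tau_m - (n tau_c - k tau_k)| <= tol` by
#' substitution.
#'
#' @param tau_c carrier period (ms).
#' @param tau_k oscillator period (ms).
#' @param max_int bound on the small integers.
#' @param tol residual tolerance (ms).
#' @return data frame of class `coincidence_solutions` with columns `m`,
#'   `n`, `k`, `tau_m`, `residual`, sorted by `(m, residual, tau_m)`.
#' @export
solve_coincidence <- function(tau_c, tau_k, max_int = 10, tol = 0.05) {
  check_scalar(tau_c, "tau_c", positive = TRUE)
  check_scalar(tau_k, "tau_k", positive = TRUE)
  if (max_int < 1) stopf("'max_int' must be >= 1")
  g <- expand.grid(m = seq_len(max_int), n = seq_len(max_int),
                   k = 0:max_int)
  g$tau_m <- (g$n * tau_c - g$k * tau_k) / g$m
  g$residual <- abs(g$m * g$tau_m - (g$n * tau_c - g$k * tau_k))
  g <- g[g$tau_m > tau_c & g$residual <= tol, , drop = FALSE]
  g <- g[order(g$m, g$residual, g$tau_m, g$n, g$k), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("coincidence_solutions", "data.frame")
  g
}

#' Best modulation frequency of a periodicity unit
#'
#' The unit responds once per modulation cycle (the fundamental, m = 1,
#' solution) at every modulation period `tau_m = n tau_c - k tau_k` whose
#' oscillator offset fits within the cycle; the best modulation frequency is
#' the largest such response rate, i.e. the smallest such `tau_m`, reached
#' with the largest usable oscillator spike count.
#'
#' @param unit a [periodicity_unit()].
#' @return list with `bmf` (Hz), `tau_m` (ms), `k` (oscillator spikes used)
#'   and `tuned` (logical; `FALSE` when no m = 1 solution exists, the
#'   "untuned" case, in which the other fields are `NA`).
#' @export
bmf_of_unit <- function(unit) {
  n <- unit$integrator_n
  for (k in seq(unit$n_osc_spikes, 0)) {
    tau_m <- n * unit$tau_c - k * unit$tau_k
    if (tau_m > unit$tau_c + 1e-12 && k * unit$tau_k < tau_m) {
      return(list(bmf = 1000 / tau_m, tau_m = tau_m, k = k, tuned = TRUE))
    }
  }
  list(bmf = NA_real_, tau_m = NA_real_, k = NA_integer_, tuned = FALSE)
}

#' Coincidence response of one unit to one AM stimulus
#'
#' Runs the unit on idealized event times: triggers at the analytic envelope
#' peaks, oscillator spikes at `tau_k` intervals after each trigger
#' (restarted by the next trigger), one integrator event `integrator_n`
#' carrier periods after each trigger.  A coincidence is counted for every
#' integrator event that lands within half a coincidence window of an
#' oscillator spike; with inhibition enabled, coincidences whose oscillator
#' spike belongs to a trigger more than one modulation cycle later
#' (harmonic, m > 1, solutions) are vetoed.
#'
#' @param stimulus an [am_spec()].
#' @param unit a [periodicity_unit()].
#' @param duration stimulus duration (ms); defaults to the stimulus record's.
#' @param seed unused for the deterministic idealized events; kept so that
#'   stochastic trigger variants remain interface-compatible.
#' @return integer coincidence-spike count.
#' @export
unit_response <- function(stimulus, unit, duration = stimulus$duration,
                          seed = NULL) {
  if (!inherits(stimulus, "am_spec")) stopf("'stimulus' must be an am_spec")
  tau_m <- stimulus$tau_m
  if (duration < tau_m) stopf("duration (%g ms) is below one modulation period", duration)
  if (stimulus$depth <= 0) return(0L)  # flat envelope: no trigger events
  triggers <- seq(tau_m / 4, duration, by = tau_m)
  n_trig <- length(triggers)
  # oscillator spikes: ticks j = 0..n_osc after each trigger, cut off by the
  # next trigger
  js <- 0:unit$n_osc_spikes
  osc_t <- as.vector(outer(js * unit$tau_k, triggers, `+`))
  osc_trig <- rep(seq_len(n_trig), each = length(js))
  keep <- rep(js * unit$tau_k, n_trig) < tau_m - 1e-12
  osc_t <- osc_t[keep]; osc_trig <- osc_trig[keep]
  ord <- order(osc_t)
  osc_t <- osc_t[ord]; osc_trig <- osc_trig[ord]

  integ_t <- triggers + unit$integrator_n * unit$tau_c
  ok <- integ_t <= duration
  integ_t <- integ_t[ok]
  integ_trig <- seq_len(n_trig)[ok]
  if (!length(integ_t) || !length(osc_t)) return(0L)

  half <- unit$coincidence_window / 2
  # nearest oscillator spike for every integrator event
  pos <- findInterval(integ_t, osc_t)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(osc_t))
  d_lo <- abs(integ_t - osc_t[lo])
  d_hi <- abs(integ_t - osc_t[hi])
  use_hi <- d_hi < d_lo
  nearest <- ifelse(use_hi, hi, lo)
  dist <- pmin(d_lo, d_hi)
  hit <- dist <= half + 1e-12
  if (unit$inhibition_enabled) {
    m <- osc_trig[nearest] - integ_trig
    hit <- hit & m <= 1
  }
  sum(hit)
}

#' Carrier-by-modulation response matrix
#'
#' Simulates every combination of `length(cf_list)` periodicity units (rows,
#' one per characteristic frequency, each tuned to a best modulation
#' frequency of CF/`cf_bmf_ratio`) and as many modulation frequencies
#' (columns, defaulting to the units' best modulation frequencies), the
#' classic 16 x 16 / 256-stimulus experiment.  Cells where the requested
#' modulation would be faster than the carrier are 0.
#'
#' @param n_units number of units (and modulation frequencies).
#' @param cf_list characteristic frequencies (Hz); default log-spaced over
#'   three octaves starting at 960 Hz (a convention; the spacing puts the
#'   second harmonic of each best modulation frequency exactly five columns
#'   up).
#' @param cf_bmf_ratio CF/BMF ratio of every unit.
#' @param inhibition enable the harmonic-suppressing inhibitor.
#' @param seed forwarded to [unit_response()].
#' @param duration stimulus duration (ms).
#' @param coincidence_window coincidence window (ms).
#' @return object of class `response_matrix`: `carrier_freqs`, `mod_freqs`,
#'   `response` (units x modulations count matrix), `inhibition_enabled`.
#' @export
response_matrix <- function(n_units = 16, cf_list = NULL, cf_bmf_ratio = 6,
                            inhibition = FALSE, seed = NULL,
                            duration = 150, coincidence_window = 0.05) {
  if (is.null(cf_list))
    cf_list <- 960 * 2 ^ ((seq_len(n_units) - 1) / 5)
  if (length(cf_list) != n_units) stopf("'cf_list' must have %d entries", n_units)
  mod_freqs <- cf_list / cf_bmf_ratio
  resp <- matrix(0L, n_units, n_units,
                 dimnames = list(cf = sprintf("%.0f", cf_list),
                                 fm = sprintf("%.1f", mod_freqs)))
  for (i in seq_len(n_units)) {
    u <- tuned_unit(cf_list[i], ratio = cf_bmf_ratio,
                    coincidence_window = coincidence_window,
                    inhibition_enabled = inhibition)
    for (j in seq_len(n_units)) {
      tau_m <- 1000 / mod_freqs[j]
      if (tau_m <= u$tau_c) next
      st <- am_spec(tau_c = u$tau_c, tau_m = tau_m, depth = 1,
                    duration = duration)
      resp[i, j] <- unit_response(st, u, seed = seed)
    }
  }
  structure(list(carrier_freqs = cf_list, mod_freqs = mod_freqs,
                 response = resp, inhibition_enabled = inhibition),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d x %d, inhibition %s\n",
              nrow(x$response), ncol(x$response),
              if (x$inhibition_enabled) "on" else "off"))
  invisible(x)
}
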