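# Chemical synapse transmission: quantal release into a leaky-integrator
# transmitter pool, tanh conductance, delay with adjustable jitter.

# Truncated-normal delay sampler.  Jitter cannot make transmission faster
# than the physical minimum synaptic delay (0.15 ms) or one integration
# step, whichever is larger.  The window is symmetric about the mean - the
# lower edge is the physical floor, the upper edge its mirror image - so
# that jitter leaves the mean delay, and with it the population clock,
# unbiased.  Draws outside the window are rejected and redrawn.
MIN_SYNAPTIC_DELAY <- 0.15

delay_window <- function(delay_mean, dt) {
  lo <- max(dt, min(MIN_SYNAPTIC_DELAY, delay_mean / 2))
  c(lo, 2 * delay_mean - lo)
}

draw_delays <- function(n, delay_mean, delay_jitter_sd, floor_ms) {
  if (n == 0) return(numeric(0))
  if (delay_jitter_sd == 0) return(rep(delay_mean, n))
  win <- delay_window(delay_mean, floor_ms)
  out <- stats::rnorm(n, delay_mean, delay_jitter_sd)
  bad <- which(out < win[1] | out > win[2])
  guard <- 0L
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), delay_mean, delay_jitter_sd)
    bad <- bad[out[bad] < win[1] | out[bad] > win[2]]
    guard <- guard + 1L
    if (guard > 1000L) {  # pathological parameters: clamp the stragglers
      out[bad] <- delay_mean
      break
    }
  }
  out
}

#' Moments of the truncated delay distribution
#'
#' Mean and SD of the normal distribution truncated to the symmetric window
#' about `delay_mean` from which jittered synaptic delays are drawn (lower
#' edge: the larger of one time step and the 0.15 ms minimum synaptic delay;
#' upper edge: its mirror image).  The mean is `delay_mean` exactly; the SD
#' is below `delay_jitter_sd` when the jitter is large relative to the
#' window, and approaches it as the jitter gets small.  Used as the
#' independent reference for the delay-statistics tests.
#'
#' @param params a [synapse_params()].
#' @param dt time step (ms).
#' @return named numeric vector with `mean` and `sd`.
#' @export
delay_moments <- function(params, dt = 0.025) {
  mu <- params$delay_mean
  s <- params$delay_jitter_sd
  if (s == 0) return(c(mean = mu, sd = 0))
  win <- delay_window(mu, dt)
  a <- (mu - win[1]) / s  # symmetric half-width in SD units
  mass <- 2 * stats::pnorm(a) - 1
  v <- s^2 * (1 - 2 * a * stats::dnorm(a) / mass)
  c(mean = mu, sd = sqrt(v))
}

#' Transmit a presynaptic spike train through a chemical synapse
#'
#' For each presynaptic spike a delay is drawn from
#' `Normal(delay_mean, delay_jitter_sd)` truncated to the symmetric window
#' described in [delay_moments()], and
#' `quanta_per_spike` units are deposited into the transmitter pool `c`.  The
#' pool decays as `dc/dt = -c / transmitter_decay_tau` and the postsynaptic
#' current is `weight * tanh(c / saturation_scale)`.  With jitter 0 the
#' output is fully deterministic; with a seed in `params` it is reproducible.
#'
#' @param presyn a [spike_train()].
#' @param params a [synapse_params()].
#' @param dt time step (ms).
#' @param t_stop output grid end (ms); defaults to the train's `t_stop`.
#' @param trial which trial of `presyn` to transmit.
#' @return an object of class `psc` with fields `times` (ms grid) and
#'   `current`.
#' @export
#' @examples
#' tr <- spike_train(list(c(5)), t_stop = 20)
#' psc <- transmit(tr, synapse_params(weight = 10), dt = 0.025)
#' psc$times[which(psc$current != 0)[1]]  # support starts at 5 + 0.4 ms
transmit <- function(presyn, params, dt, t_stop = presyn$t_stop, trial = 1) {
  if (!is.numeric(dt) || dt <= 0) stopf("'dt' must be > 0")
  spikes <- presyn$trials[[trial]]
  n_steps <- ceiling(t_stop / dt)
  times <- seq_len(n_steps) * dt
  current <- numeric(n_steps)
  if (length(spikes) == 0 || params$weight == 0) {
    return(structure(list(times = times, current = current), class = "psc"))
  }
  delays <- with_local_seed(params$seed,
                            draw_delays(length(spikes), params$delay_mean,
                                        params$delay_jitter_sd, dt))
  arrive <- pmax(1L, round((spikes + delays) / dt))
  decay <- exp(-dt / params$transmitter_decay_tau)
  conc <- numeric(1)
  dep <- numeric(n_steps)
  ok <- arrive <= n_steps
  for (a in arrive[ok]) dep[a] <- dep[a] + params$quanta_per_spike
  for (k in seq_len(n_steps)) {
    conc <- conc + dep[k]
    current[k] <- params$weight * tanh(conc / params$saturation_scale)
    conc <- conc * decay
  }
  structure(list(times = times, current = current), class = "psc")
}

#' Realized synaptic delays for a presynaptic train
#'
#' Exposes the per-spike delays that [transmit()] draws under the same seed,
#' for testing and diagnostics.  As the spike count grows the sample mean and
#' SD approach the truncated-normal values given by [delay_moments()].
#'
#' @inheritParams transmit
#' @return numeric vector of delays (ms), one per presynaptic spike.
#' @export
realized_delays <- function(presyn, params, dt = 0.025, trial = 1) {
  spikes <- presyn$trials[[trial]]
  with_local_seed(params$seed,
                  draw_delays(length(spikes), params$delay_mean,
                              params$delay_jitter_sd, dt))
}
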