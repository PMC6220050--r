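# Stimulus waveforms and synthetic auditory-nerve spike trains.

#' Construct a stimulus waveform
#'
#' @param samples numeric amplitude sequence (arbitrary units).
#' @param sample_interval sampling interval in seconds.
#' @param label free-text label.
#' @return an object of class `waveform` with fields `samples`,
#'   `sample_interval` (s) and `duration` (s).
#' @export
waveform <- function(samples, sample_interval, label = "") {
  check_scalar(sample_interval, "sample_interval", positive = TRUE)
  if (!is.numeric(samples)) stopf("'samples' must be numeric")
  structure(list(samples = as.numeric(samples),
                 sample_interval = sample_interval,
                 duration = length(samples) * sample_interval,
                 label = label),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s: %d samples @ %.1f us, %.2f ms\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$sample_interval * 1e6,
              x$duration * 1e3))
  invisible(x)
}

#' Time axis of a waveform in milliseconds
#' @param w a [waveform()].
#' @return numeric vector of sample times (ms), starting at 0.
#' @export
waveform_times <- function(w) {
  (seq_along(w$samples) - 1) * w$sample_interval * 1e3
}

#' Tone-burst specification
#'
#' @param frequency carrier frequency (Hz), e.g. the unit's characteristic
#'   frequency.
#' @param duration burst duration (ms).
#' @param rise_fall linear onset/offset ramp time (ms); must satisfy
#'   `duration > 2 * rise_fall`.
#' @param level level in dB re threshold; `-Inf` means zero amplitude.
#' @return an object of class `tone_burst_spec`.
#' @export
tone_burst_spec <- function(frequency = 2890, duration = 25,
                            rise_fall = 1.6, level = 30) {
  check_scalar(frequency, "frequency", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(rise_fall, "rise_fall", nonneg = TRUE)
  if (duration <= 2 * rise_fall)
    stopf("'duration' must exceed 2 * rise_fall (%g <= %g)",
          duration, 2 * rise_fall)
  if (!identical(level, -Inf)) check_scalar(level, "level")
  structure(list(frequency = frequency, duration = duration,
                 rise_fall = rise_fall, level = level),
            class = "tone_burst_spec")
}

#' Generate a gated tone burst
#'
#' A sinusoid at `spec$frequency` with linear onset/offset ramps of
#' `spec$rise_fall` ms.  Peak amplitude is `10^(level/20)` relative to a unit
#' reference, a monotone mapping of level; `level = -Inf` yields silence.
#'
#' @param spec a [tone_burst_spec()].
#' @param sample_interval sampling interval in seconds (default 25 us, the
#'   engine step).
#' @return a [waveform()].
#' @export
#' @examples
#' w <- make_tone_burst(tone_burst_spec(frequency = 2890))
#' range(waveform_times(w))
make_tone_burst <- function(spec, sample_interval = 25e-6) {
  if (!inherits(spec, "tone_burst_spec")) stopf("'spec' must be a tone_burst_spec")
  n <- round(spec$duration * 1e-3 / sample_interval)
  t_ms <- (seq_len(n) - 1) * sample_interval * 1e3
  amp <- if (identical(spec$level, -Inf)) 0 else 1
  s <- amp * sin(2 * pi * spec$frequency * t_ms * 1e-3)
  env <- rep(1, n)
  if (spec$rise_fall > 0) {
    env <- pmin(1, t_ms / spec$rise_fall,
                (spec$duration - t_ms - sample_interval * 1e3) / spec$rise_fall)
    env <- pmax(env, 0)
  }
  waveform(s * env, sample_interval,
           label = sprintf("tone %.0f Hz, %g ms", spec$frequency, spec$duration))
}

#' Amplitude-modulated tone specification
#'
#' Natural sounds carry two time scales: a fast carrier (period `tau_c`) and
#' a slow envelope (modulation period `tau_m`).
#'
#' @param tau_c carrier period (ms).
#' @param tau_m modulation period (ms); must exceed `tau_c`.
#' @param depth modulation depth in `[0, 1]`.
#' @param duration stimulus duration (ms).
#' @return an object of class `am_spec`.
#' @export
am_spec <- function(tau_c, tau_m, depth = 1, duration = 25) {
  check_scalar(tau_c, "tau_c", positive = TRUE)
  check_scalar(tau_m, "tau_m", positive = TRUE)
  if (tau_m <= tau_c)
    stopf("modulation period tau_m (%g) must exceed carrier period tau_c (%g)",
          tau_m, tau_c)
  if (depth < 0 || depth > 1) stopf("'depth' must be in [0, 1]")
  check_scalar(duration, "duration", positive = TRUE)
  structure(list(tau_c = tau_c, tau_m = tau_m, depth = depth,
                 duration = duration),
            class = "am_spec")
}

#' Generate an amplitude-modulated tone
#'
#' `s(t) = (1 + depth * sin(2 pi t / tau_m)) * sin(2 pi t / tau_c)`, scaled to
#' unit peak.
#'
#' @param spec an [am_spec()].
#' @param sample_interval sampling interval in seconds.
#' @return a [waveform()].
#' @export
make_am <- function(spec, sample_interval = 25e-6) {
  if (!inherits(spec, "am_spec")) stopf("'spec' must be an am_spec")
  n <- round(spec$duration * 1e-3 / sample_interval)
  t_ms <- (seq_len(n) - 1) * sample_interval * 1e3
  s <- (1 + spec$depth * sin(2 * pi * t_ms / spec$tau_m)) *
    sin(2 * pi * t_ms / spec$tau_c)
  peak <- max(abs(s))
  if (peak > 0) s <- s / peak
  waveform(s, sample_interval,
           label = sprintf("AM tau_c=%g ms tau_m=%g ms depth=%g",
                           spec$tau_c, spec$tau_m, spec$depth))
}

#' Step-current drive
#'
#' Piecewise-constant drive used in the reduced simulation mode in which the
#' auditory-nerve input is a signal step.
#'
#' @param amplitude current amplitude (a.u.).
#' @param t_on,t_off step support in ms; `t_off > t_on >= 0`.
#' @param duration total waveform duration (ms); defaults to `t_off + 5`.
#' @param sample_interval sampling interval in seconds.
#' @return a [waveform()].
#' @export
step_drive <- function(amplitude, t_on, t_off, duration = t_off + 5,
                       sample_interval = 25e-6) {
  check_scalar(amplitude, "amplitude")
  check_scalar(t_on, "t_on", nonneg = TRUE)
  check_scalar(t_off, "t_off", positive = TRUE)
  if (t_off <= t_on) stopf("'t_off' (%g) must exceed 't_on' (%g)", t_off, t_on)
  n <- round(duration * 1e-3 / sample_interval)
  t_ms <- (seq_len(n) - 1) * sample_interval * 1e3
  waveform(amplitude * as.numeric(t_ms >= t_on & t_ms < t_off),
           sample_interval, label = sprintf("step [%g, %g] ms", t_on, t_off))
}

# ---------------------------------------------------------------------------
# Spike trains

#' Construct a spike train
#'
#' The universal currency between modules: ordered spike times of one unit
#' across one or more trials, in ms relative to stimulus onset.
#'
#' @param trials list of numeric vectors of spike times (ms), one per trial;
#'   a single numeric vector is treated as one trial.
#' @param t_stop end of the observation window (ms).
#' @param unit_id unit identifier.
#' @param refractory optional declared absolute refractory period (ms); when
#'   given, consecutive spikes closer than this are rejected.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(trials, t_stop, unit_id = "unit", refractory = NULL) {
  if (is.numeric(trials)) trials <- list(trials)
  check_scalar(t_stop, "t_stop", positive = TRUE)
  trials <- lapply(trials, as.numeric)
  for (i in seq_along(trials)) {
    tt <- trials[[i]]
    if (any(is.na(tt))) stopf("trial %d contains NA spike times", i)
    if (is.unsorted(tt, strictly = TRUE))
      stopf("spike times in trial %d are not strictly increasing", i)
    if (length(tt) && (tt[1] < 0 || tt[length(tt)] > t_stop))
      stopf("spike times in trial %d fall outside [0, t_stop]", i)
    if (!is.null(refractory) && length(tt) > 1 &&
        any(diff(tt) < refractory - 1e-9))
      stopf("trial %d violates the declared refractory period (%g ms)",
            i, refractory)
  }
  structure(list(unit_id = unit_id, trials = trials, t_stop = t_stop,
                 refractory = refractory),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d trial(s), %d spikes, t_stop %.1f ms\n",
              x$unit_id, length(x$trials),
              sum(lengths(x$trials)), x$t_stop))
  invisible(x)
}

#' Number of spikes in a train, pooled over trials
#' @param train a [spike_train()].
#' @return integer count.
#' @export
n_spikes <- function(train) sum(lengths(train$trials))

#' Generate auditory-nerve fiber spike trains
#'
#' Per fiber, an inhomogeneous stochastic point process: the instantaneous
#' rate is the half-wave-rectified waveform (normalized to its peak) times
#' `release_rate_at_peak`, times an adaptation factor that decays
#' exponentially from 1 to `adaptation_floor` after stimulus onset, plus the
#' spontaneous rate.  Spikes are drawn per sample (Bernoulli with p =
#' rate * dt) and thinned by the absolute dead time.  Bit-identical across
#' runs for a given seed.
#'
#' @param w a [waveform()] stimulus.
#' @param params an [an_fiber_params()].
#' @param n_trials number of independent trials.
#' @return list of [spike_train()], one per fiber, each with `n_trials`
#'   trials.
#' @export
#' @examples
#' w <- make_tone_burst(tone_burst_spec())
#' trains <- an_spikes(w, an_fiber_params(seed = 1))
#' sapply(trains, n_spikes)
an_spikes <- function(w, params, n_trials = 1) {
  if (!inherits(w, "waveform")) stopf("'w' must be a waveform")
  if (!inherits(params, "an_fiber_params")) stopf("'params' must be an_fiber_params")
  if (length(w$samples) == 0) stopf("waveform is empty")
  dt_ms <- w$sample_interval * 1e3
  t_ms <- waveform_times(w)
  drive <- pmax(w$samples, 0)
  pk <- max(drive)
  if (pk > 0) drive <- drive / pk
  if (!params$phase_locking) {
    # envelope drive: rectified waveform smoothed over ~1 ms
    k <- max(1L, round(1 / dt_ms))
    drive <- stats::filter(drive, rep(1 / k, k), sides = 2)
    drive[is.na(drive)] <- 0
    drive <- as.numeric(drive)
    if (max(drive) > 0) drive <- drive / max(drive)
  }
  adapt <- params$adaptation_floor + (1 - params$adaptation_floor) *
    exp(-t_ms / params$adaptation_time_constant)
  rate_ms <- (params$release_rate_at_peak * drive * adapt +
                params$spontaneous_rate) / 1000  # events per ms
  p <- pmin(rate_ms * dt_ms, 1)
  dead_steps <- round(params$refractory / dt_ms)
  seeds <- derive_seeds(if (is.null(params$seed)) 0L else params$seed,
                        params$n_fibers * n_trials)
  out <- vector("list", params$n_fibers)
  idx <- 0L
  for (f in seq_len(params$n_fibers)) {
    trials <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      idx <- idx + 1L
      ev <- with_local_seed(seeds[idx], which(stats::runif(length(p)) < p))
      if (length(ev) > 1 && dead_steps > 0) {
        keep <- ev[1]
        last <- ev[1]
        for (e in ev[-1]) {
          if (e - last > dead_steps) {
            keep <- c(keep, e)
            last <- e
          }
        }
        ev <- keep
      }
      trials[[tr]] <- t_ms[ev]
    }
    out[[f]] <- spike_train(trials, t_stop = w$duration * 1e3,
                            unit_id = sprintf("an%d", f),
                            refractory = params$refractory)
  }
  out
}

#' Vector strength of a spike train to a reference frequency
#'
#' `VS = |mean(exp(2 pi i f t))|` over all spikes pooled across trials; 1 for
#' perfect phase locking, ~0 for phase-random firing.
#'
#' @param train a [spike_train()].
#' @param frequency reference frequency in Hz.
#' @return numeric scalar in `[0, 1]`, `NA` for an empty train.
#' @export
vector_strength <- function(train, frequency) {
  tt <- unlist(train$trials)
  if (!length(tt)) return(NA_real_)
  ph <- 2 * pi * frequency * tt * 1e-3
  sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
}
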