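# Single-neuron dynamics: leaky integrate-and-fire choppers and the onset
# (trigger) neuron.

#' Initial state for a leaky integrate-and-fire neuron
#'
#' @param membrane_potential initial membrane potential (a.u.).
#' @param time initial time (ms).
#' @return an object of class `lif_state`.
#' @export
lif_state <- function(membrane_potential = 0, time = 0) {
  structure(list(membrane_potential = membrane_potential,
                 last_spike_time = -Inf, time = time),
            class = "lif_state")
}

#' Advance a LIF neuron by one Euler step
#'
#' Forward-Euler update `V <- V + dt/tau * (E_leak - V + I)`.  During the
#' absolute refractory period the membrane is clamped at the reset potential,
#' so inputs arriving in that window are skipped without leaving a cumulative
#' trace - this is what lets slow choppers skip suprathreshold pacemaker
#' inputs.  After it, a spike is emitted as soon as V reaches the effective
#' threshold `threshold + A * exp(-(t - t_last)/tau_rel)` (the exponentially
#' decaying relative refractory increment).  On a spike the potential is
#' reset and the spike time recorded at the crossing step.
#'
#' @param state a [lif_state()].
#' @param input_current input current (a.u.).
#' @param dt time step (ms); the engine default is 0.025 ms.
#' @param params a [lif_params()].
#' @return list with elements `state` (updated [lif_state()]) and `spiked`
#'   (logical).
#' @export
lif_step <- function(state, input_current, dt, params) {
  if (!is.numeric(dt) || dt <= 0) stopf("'dt' must be > 0")
  t_new <- state$time + dt
  since <- t_new - state$last_spike_time
  clamped <- is.finite(state$last_spike_time) &&
    since <= params$absolute_refractory + 1e-12
  if (clamped) {
    v <- params$reset
  } else {
    v <- state$membrane_potential +
      dt / params$membrane_time_constant *
      (params$leak_reversal - state$membrane_potential + input_current)
  }
  thr <- params$threshold
  if (is.finite(state$last_spike_time))
    thr <- thr + params$relative_refractory_amplitude *
      exp(-since / params$relative_refractory_tau)
  spiked <- !clamped && v >= thr
  if (spiked) {
    v <- params$reset
    state$last_spike_time <- t_new
  }
  state$membrane_potential <- v
  state$time <- t_new
  list(state = state, spiked = spiked)
}

#' Closed-form interspike interval of a LIF neuron under constant drive
#'
#' With reset at 0, leak reversal 0, no refractoriness and constant
#' suprathreshold current I, the membrane follows
#' `V(t) = I (1 - exp(-t/tau))` and the period is
#' `T = tau * log(I / (I - threshold))`.
#'
#' @param current constant input current (a.u.), `> threshold`.
#' @param params a [lif_params()].
#' @return period in ms.
#' @export
lif_isi_closed_form <- function(current, params) {
  if (current <= params$threshold) return(Inf)
  params$membrane_time_constant *
    log((current - params$reset) / (current - params$threshold))
}

# ---------------------------------------------------------------------------
# Onset / trigger neuron

#' Response of the onset (trigger) neuron to a drive
#'
#' In `single_spike` mode the onset neuron fires exactly once, at drive onset
#' (first non-zero sample) plus `spike_latency`; an all-zero drive yields an
#' empty train ("no onset").  In `hh` mode the four-current
#' Hodgkin-Huxley-type model is integrated by the Euler method; its
#' low-threshold potassium current makes the response phasic (at default
#' conductances a sustained step elicits at most two spikes).
#'
#' @param drive a [waveform()].
#' @param params an [onset_params()].
#' @return a [spike_train()] with one trial.
#' @export
#' @examples
#' onset_response(step_drive(1, 5, 30), onset_params(spike_latency = 0.1))
onset_response <- function(drive, params) {
  if (!inherits(drive, "waveform")) stopf("'drive' must be a waveform")
  if (length(drive$samples) == 0) stopf("drive is empty")
  t_stop <- drive$duration * 1e3
  if (params$mode == "single_spike") {
    i <- which(abs(drive$samples) > 0)
    if (!length(i)) return(spike_train(list(numeric(0)), t_stop, "onset"))
    t_spk <- waveform_times(drive)[i[1]] + params$spike_latency
    if (t_spk > t_stop) t_spk <- t_stop
    return(spike_train(list(t_spk), t_stop, "onset"))
  }
  spk <- hh_onset_spikes(drive, params$hh_conductances)
  spike_train(list(spk), t_stop, "onset")
}

# Type-II (onset) ventral cochlear nucleus model: sodium, low-threshold
# potassium, leak and an excitatory input current; Euler integration at a
# fine internal step.  Voltages in mV, conductances nS, currents pA, C in pF.
hh_onset_spikes <- function(drive, g, dt_ms = 0.0025) {
  minf <- function(v) 1 / (1 + exp(-(v + 38) / 7))
  taum <- function(v) 10 / (5 * exp((v + 60) / 18) + 36 * exp(-(v + 60) / 25)) + 0.04
  hinf <- function(v) 1 / (1 + exp((v + 65) / 6))
  tauh <- function(v) 100 / (7 * exp((v + 60) / 11) + 10 * exp(-(v + 60) / 25)) + 0.6
  winf <- function(v) (1 / (1 + exp(-(v + 48) / 6)))^0.25
  tauw <- function(v) 100 / (6 * exp((v + 60) / 6) + 16 * exp(-(v + 60) / 45)) + 1.5
  zinf <- function(v) 0.5 + 0.5 / (1 + exp((v + 71) / 10))
  tauz <- function(v) 1000 / (exp((v + 60) / 20) + exp(-(v + 60) / 8)) + 50

  t_drive <- waveform_times(drive)
  horizon <- drive$duration * 1e3
  n <- floor(horizon / dt_ms)
  # piecewise-constant lookup of the drive on the fine grid
  idx <- pmin(length(drive$samples),
              1L + floor((seq_len(n) - 1) * dt_ms / (drive$sample_interval * 1e3)))
  i_ext <- g$input_gain * 1000 * pmax(drive$samples[idx], 0)  # pA

  v <- -64
  m <- minf(v); h <- hinf(v); w <- winf(v); z <- zinf(v)
  above <- FALSE
  spikes <- numeric(0)
  for (k in seq_len(n)) {
    i_na <- g$g_na * m^3 * h * (v - g$e_na)
    i_klt <- g$g_klt * w^4 * z * (v - g$e_k)
    i_lk <- g$g_leak * (v - g$e_leak)
    v <- v + dt_ms * (i_ext[k] - i_na - i_klt - i_lk) / g$cap
    m <- m + dt_ms * (minf(v) - m) / taum(v)
    h <- h + dt_ms * (hinf(v) - h) / tauh(v)
    w <- w + dt_ms * (winf(v) - w) / tauw(v)
    z <- z + dt_ms * (zinf(v) - z) / tauz(v)
    if (!above && v >= -20) {
      spikes <- c(spikes, k * dt_ms)
      above <- TRUE
    } else if (above && v < -30) {
      above <- FALSE
    }
  }
  spikes
}
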