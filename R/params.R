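# Parameter records for neurons, synapses and auditory-nerve fibers.
#
# Voltages are expressed in threshold units: leak reversal 0, spike threshold
# 1.  Times are milliseconds throughout.  Defaults that the source model does
# not pin down numerically (threshold, reset, synaptic weights, transmitter
# kinetics) are calibration constants chosen so that the documented circuit
# constraints hold: the summed auditory-nerve weight is one eighth of a
# chopper-chopper weight, auditory-nerve input alone depolarizes but never
# fires a chopper, and one network spike on top of that depolarization fires
# it within one integration step.

# Central calibration constants (see the methods vignette for the reasoning).
.cal <- list(
  w_chopper      = 24,       # chopper-chopper / onset-chopper synaptic weight
  an_weight_div  = 8,        # summed AN weight = w_chopper / an_weight_div
  w_slow         = 250,      # pacemaker -> slow chopper weight (suprathreshold alone)
  an_step_level  = 0.95 / 3, # default step amplitude: AN current 0.95 threshold units
  tau_fast       = 0.8,      # fast chopper membrane time constant [ms]
  tau_slow       = 2.0,      # slow chopper membrane time constant [ms]
  level_ref_rate = 250       # AN release rate [events/s] at 0 dB re threshold
)

#' Leaky integrate-and-fire parameters for chopper neurons
#'
#' Fast choppers use a membrane time constant of 0.8 ms; slow choppers use
#' larger time constants and longer absolute refractory periods.  The relative
#' refractory period is an exponentially decaying increment added to the
#' threshold after each spike.
#'
#' @param membrane_time_constant membrane time constant (ms).
#' @param threshold spike threshold (potential a.u.; 1 by convention).
#' @param reset post-spike reset potential (a.u.).
#' @param leak_reversal leak reversal potential (a.u.; 0 by convention).
#' @param absolute_refractory absolute refractory period (ms); during it the
#'   membrane is clamped at `reset`, so suprathreshold inputs are skipped.
#' @param relative_refractory_amplitude initial threshold increment after a
#'   spike (a.u.).
#' @param relative_refractory_tau decay time constant of that increment (ms).
#' @return an object of class `lif_params`.
#' @export
#' @examples
#' lif_params()                       # fast chopper defaults
#' lif_params(membrane_time_constant = 2, absolute_refractory = 1)  # slow
lif_params <- function(membrane_time_constant = 0.8,
                       threshold = 1,
                       reset = 0.5,
                       leak_reversal = 0,
                       absolute_refractory = 0.1,
                       relative_refractory_amplitude = 0.05,
                       relative_refractory_tau = 0.3) {
  check_scalar(membrane_time_constant, "membrane_time_constant", positive = TRUE)
  check_scalar(absolute_refractory, "absolute_refractory", nonneg = TRUE)
  check_scalar(threshold, "threshold")
  check_scalar(reset, "reset")
  if (threshold <= reset) stopf("'threshold' must exceed 'reset'")
  check_scalar(relative_refractory_amplitude, "relative_refractory_amplitude",
               nonneg = TRUE)
  check_scalar(relative_refractory_tau, "relative_refractory_tau", positive = TRUE)
  structure(list(membrane_time_constant = membrane_time_constant,
                 threshold = threshold, reset = reset,
                 leak_reversal = leak_reversal,
                 absolute_refractory = absolute_refractory,
                 relative_refractory_amplitude = relative_refractory_amplitude,
                 relative_refractory_tau = relative_refractory_tau),
            class = "lif_params")
}

#' @rdname lif_params
#' @export
fast_chopper_params <- function() lif_params()

#' @rdname lif_params
#' @param ... overrides passed on to [lif_params()].
#' @export
slow_chopper_params <- function(absolute_refractory, ...) {
  lif_params(membrane_time_constant = .cal$tau_slow,
             absolute_refractory = absolute_refractory, ...)
}

#' Onset (trigger) neuron parameters
#'
#' The onset neuron receives broadband input and initiates chopping.  In
#' `single_spike` mode (the default, and the mode used throughout the circuit
#' experiments) it emits exactly one spike at drive onset plus
#' `spike_latency`.  In `hh` mode it integrates a four-current
#' Hodgkin-Huxley-type model (sodium, low-threshold potassium, leak,
#' excitatory synaptic) whose low-threshold potassium current produces the
#' phasic onset response; conductances follow the classic ventral cochlear
#' nucleus type-II formulation and are configurable.
#'
#' @param mode `"single_spike"` or `"hh"`.
#' @param spike_latency latency from drive onset to the emitted spike (ms).
#' @param hh_conductances named list: `g_na`, `g_klt`, `g_leak` (nS),
#'   `e_na`, `e_k`, `e_leak` (mV), `cap` (pF), `input_gain` (nA per unit of
#'   drive amplitude).
#' @return an object of class `onset_params`.
#' @export
onset_params <- function(mode = c("single_spike", "hh"),
                         spike_latency = 0.1,
                         hh_conductances = list(g_na = 1000, g_klt = 200,
                                                g_leak = 2, e_na = 55,
                                                e_k = -70, e_leak = -65,
                                                cap = 12, input_gain = 2)) {
  mode <- match.arg(mode)
  check_scalar(spike_latency, "spike_latency", nonneg = TRUE)
  structure(list(mode = mode, spike_latency = spike_latency,
                 hh_conductances = hh_conductances),
            class = "onset_params")
}

#' Chemical synapse parameters
#'
#' Transmission is quantal: each presynaptic spike deposits
#' `quanta_per_spike` units into a transmitter pool after an axonal plus
#' diffusion delay drawn from a normal distribution (mean `delay_mean`, SD
#' `delay_jitter_sd`, truncated to a window symmetric about the mean whose
#' lower edge is the physical minimum delay - causality - and whose upper
#' edge mirrors it, so the mean delay is unbiased).  The pool decays as a leaky integrator with time constant
#' `transmitter_decay_tau`, and the postsynaptic current is
#' `weight * tanh(pool / saturation_scale)` - a saturating conductance.
#'
#' @param weight signed synaptic weight (negative = inhibitory).
#' @param delay_mean mean delay (ms); 0.4 ms is the network clock default.
#' @param delay_jitter_sd delay jitter SD (ms); 0 gives deterministic
#'   transmission, 0.26 is the value used in the stochastic chopper protocol.
#' @param transmitter_decay_tau transmitter pool decay time constant (ms).
#'   Network (chopper-chopper) synapses default to a very short value, the
#'   impulse-coupling regime; auditory-nerve synapses use ~1 ms.
#' @param saturation_scale concentration scale of the tanh saturation.
#' @param quanta_per_spike quanta deposited per presynaptic spike.
#' @param seed optional seed making jittered delays reproducible.
#' @return an object of class `synapse_params`.
#' @export
synapse_params <- function(weight,
                           delay_mean = 0.4,
                           delay_jitter_sd = 0,
                           transmitter_decay_tau = 0.005,
                           saturation_scale = 0.8,
                           quanta_per_spike = 1,
                           seed = NULL) {
  check_scalar(weight, "weight")
  check_scalar(delay_mean, "delay_mean", positive = TRUE)
  check_scalar(delay_jitter_sd, "delay_jitter_sd", nonneg = TRUE)
  check_scalar(transmitter_decay_tau, "transmitter_decay_tau", positive = TRUE)
  check_scalar(saturation_scale, "saturation_scale", positive = TRUE)
  check_scalar(quanta_per_spike, "quanta_per_spike", positive = TRUE)
  structure(list(weight = weight, delay_mean = delay_mean,
                 delay_jitter_sd = delay_jitter_sd,
                 transmitter_decay_tau = transmitter_decay_tau,
                 saturation_scale = saturation_scale,
                 quanta_per_spike = quanta_per_spike,
                 seed = seed),
            class = "synapse_params")
}

#' Auditory-nerve fiber generator parameters
#'
#' A phenomenological stand-in for the cochlea / hair-cell / auditory-nerve
#' chain: each fiber is an inhomogeneous stochastic point process whose
#' instantaneous rate follows the half-wave-rectified stimulus waveform
#' (phase locking) times a single-exponential adaptation factor (vesicle
#' depletion), thinned by an absolute dead time of about 1 ms.
#'
#' The peak rate and spontaneous rate are conventions, not values fixed by
#' the underlying physiology model; see the methods vignette.
#'
#' @param n_fibers number of fibers converging on one chopper (default 5).
#' @param release_rate_at_peak driven rate (events/s) at the rectified
#'   waveform peak, before adaptation and refractory thinning.
#' @param spontaneous_rate stimulus-independent rate (events/s).
#' @param adaptation_time_constant adaptation decay time constant (ms).
#' @param adaptation_floor steady-state fraction of the unadapted rate.
#' @param refractory absolute dead time (ms).
#' @param phase_locking if `FALSE`, the rate follows the waveform envelope
#'   (rectified and cycle-averaged) rather than the fine structure.
#' @param seed integer seed for reproducibility.
#' @return an object of class `an_fiber_params`.
#' @export
an_fiber_params <- function(n_fibers = 5,
                            release_rate_at_peak = 8000,
                            spontaneous_rate = 0,
                            adaptation_time_constant = 10,
                            adaptation_floor = 0.6,
                            refractory = 1,
                            phase_locking = TRUE,
                            seed = NULL) {
  if (!is.numeric(n_fibers) || n_fibers < 1) stopf("'n_fibers' must be >= 1")
  check_scalar(release_rate_at_peak, "release_rate_at_peak", nonneg = TRUE)
  check_scalar(spontaneous_rate, "spontaneous_rate", nonneg = TRUE)
  check_scalar(adaptation_time_constant, "adaptation_time_constant", positive = TRUE)
  check_scalar(refractory, "refractory", positive = TRUE)
  if (adaptation_floor < 0 || adaptation_floor > 1)
    stopf("'adaptation_floor' must be in [0, 1]")
  structure(list(n_fibers = as.integer(n_fibers),
                 release_rate_at_peak = release_rate_at_peak,
                 spontaneous_rate = spontaneous_rate,
                 adaptation_time_constant = adaptation_time_constant,
                 adaptation_floor = adaptation_floor,
                 refractory = refractory,
                 phase_locking = isTRUE(phase_locking),
                 seed = seed),
            class = "an_fiber_params")
}

#' Map stimulus level to an auditory-nerve release-rate gain
#'
#' Level in dB re threshold is mapped onto the peak release rate as
#' `rate = level_ref_rate * 10^(level/20)`; "30 dB above threshold" thus
#' scales the reference rate by about 31.6.  The mapping is a documented
#' convention of this package.
#'
#' @param level_db level in dB re threshold.
#' @return peak release rate in events/s.
#' @export
level_to_rate <- function(level_db) {
  if (identical(level_db, -Inf)) return(0)
  check_scalar(level_db, "level_db")
  .cal$level_ref_rate * 10 ^ (level_db / 20)
}
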