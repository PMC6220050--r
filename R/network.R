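# Circuit construction and the clock-driven simulation engine: fast-chopper
# pacemaker ring, slow-chopper interval bank, onset trigger, auditory-nerve
# fan-in, optional inhibitory synapses.

#' Declarative network specification
#'
#' @param neurons named list mapping unit id to [lif_params()] or
#'   [onset_params()].
#' @param synapses list of entries `list(pre =, post =, params =)` where
#'   `params` is a [synapse_params()].
#' @param inputs list of external input entries created by
#'   [input_current()], [input_an()], [input_spikes()] or [input_onset()].
#' @param topology_label free-text label.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(neurons = list(), synapses = list(),
                         inputs = list(), topology_label = "") {
  ids <- names(neurons)
  for (s in synapses) {
    if (!(s$pre %in% ids) || !(s$post %in% ids))
      stopf("synapse %s -> %s references an unknown unit", s$pre, s$post)
    if (identical(s$pre, s$post))
      stopf("self-synapse on '%s' is not allowed", s$pre)
  }
  for (inp in inputs)
    if (!(inp$target %in% ids))
      stopf("input targets unknown unit '%s'", inp$target)
  structure(list(neurons = neurons, synapses = synapses, inputs = inputs,
                 topology_label = topology_label),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s: %d neurons, %d synapses, %d external inputs\n",
              if (nzchar(x$topology_label)) x$topology_label else "(unlabelled)",
              length(x$neurons), length(x$synapses), length(x$inputs)))
  invisible(x)
}

#' External input entries
#'
#' `input_current()` injects `weight * amplitude` directly as membrane
#' current (the reduced mode in which the auditory nerve is a signal step).
#' `input_an()` generates fresh auditory-nerve fiber trains for every trial
#' and feeds each fiber through its own chemical synapse.  `input_spikes()`
#' feeds fixed spike trains through a synapse.  `input_onset()` supplies the
#' broadband drive from which an onset unit computes its trigger spike.
#'
#' @param target id of the receiving unit.
#' @param w a [waveform()].
#' @param weight current weight (a.u. per unit amplitude).
#' @param fiber_params an [an_fiber_params()].
#' @param synapse a [synapse_params()] template (applied per fiber / train).
#' @param trains list of [spike_train()].
#' @return an input entry for [network_spec()].
#' @export
input_current <- function(target, w, weight) {
  list(type = "current", target = target, waveform = w, weight = weight)
}

#' @rdname input_current
#' @export
input_an <- function(target, w, fiber_params, synapse) {
  list(type = "an", target = target, waveform = w,
       fiber_params = fiber_params, synapse = synapse)
}

#' @rdname input_current
#' @export
input_spikes <- function(target, trains, synapse) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  list(type = "spikes", target = target, trains = trains, synapse = synapse)
}

#' @rdname input_current
#' @export
input_onset <- function(target, w) {
  list(type = "onset_drive", target = target, waveform = w)
}

#' Engine configuration
#'
#' @param duration simulated time per trial (ms).
#' @param dt time step (ms); 0.025 ms resolves all relevant time scales.
#' @param n_trials number of trials.
#' @param master_seed integer master seed; per-trial seeds are derived from
#'   it deterministically, so trials are independent and order-invariant.
#' @param record_state record membrane-potential traces of the first trial.
#' @return an object of class `engine_config`.
#' @export
engine_config <- function(duration, dt = 0.025, n_trials = 1,
                          master_seed = 1, record_state = FALSE) {
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  if (n_trials < 1) stopf("'n_trials' must be >= 1")
  structure(list(duration = duration, dt = dt,
                 n_trials = as.integer(n_trials),
                 master_seed = as.integer(master_seed),
                 record_state = isTRUE(record_state)),
            class = "engine_config")
}

#' Build the fast-chopper pacemaker microcircuit
#'
#' Two or three mutually excitatory fast chopper neurons (membrane time
#' constant 0.8 ms) wired in a ring with chopper-chopper synaptic delay
#' `delay`; the ring's delay sets the population clock (0.4 ms at the
#' default).  An onset (trigger) neuron is wired to exactly one chopper.
#' Auditory-nerve input depolarizes every chopper with a summed weight one
#' eighth of the chopper-chopper weight: it enables chopping but cannot
#' initiate it.
#'
#' @param n_fast 2 or 3 fast choppers.
#' @param delay chopper-chopper synaptic delay (ms).
#' @param jitter_sd synaptic delay jitter SD (ms); 0 for deterministic runs,
#'   0.26 for the stochastic sustained-chopper protocol.
#' @param drive a [waveform()] driving the auditory-nerve input and the
#'   onset neuron, or `NULL` to attach inputs later.  Default: a step of
#'   amplitude `an_level` from 2 ms to 50 ms.
#' @param an_mode `"current"` injects the drive directly (signal-step mode);
#'   `"an"` converts it to stochastic auditory-nerve fiber trains.
#' @param fiber_params an [an_fiber_params()] for `an_mode = "an"`.
#' @param an_level default step amplitude (calibrated so the steady
#'   auditory-nerve depolarization sits just below threshold).
#' @param onset_latency onset-neuron spike latency (ms).  The circuit
#'   default gives the auditory-nerve depolarization a few membrane time
#'   constants to charge the choppers before the trigger spike arrives.
#' @return a [network_spec()].
#' @export
#' @examples
#' spec <- build_pacemaker(n_fast = 2, drive = step_drive(0.95 / 3, 2, 50))
#' res <- simulate_network(spec, engine_config(duration = 50))
#' diff(res$spikes$fast1$trials[[1]])  # 0.8 ms interspike intervals
build_pacemaker <- function(n_fast = 2, delay = 0.4, jitter_sd = 0,
                            drive = NULL, an_mode = c("current", "an"),
                            fiber_params = NULL,
                            an_level = .cal$an_step_level,
                            onset_latency = 2.5) {
  if (!n_fast %in% c(2, 3)) stopf("'n_fast' must be 2 or 3")
  an_mode <- match.arg(an_mode)
  ids <- paste0("fast", seq_len(n_fast))
  neurons <- c(stats::setNames(rep(list(fast_chopper_params()), n_fast), ids),
               list(onset = onset_params(spike_latency = onset_latency)))
  # two quanta put the ring synapses high on the tanh saturation, so one
  # spike reliably crosses within a step once the nerve has depolarized the
  # membrane, while the total charge stays below threshold from rest
  ring <- synapse_params(weight = .cal$w_chopper, delay_mean = delay,
                         delay_jitter_sd = jitter_sd, quanta_per_spike = 2)
  synapses <- list()
  for (i in seq_len(n_fast)) {
    j <- if (i == n_fast) 1L else i + 1L
    synapses[[length(synapses) + 1L]] <-
      list(pre = ids[i], post = ids[j], params = ring)
  }
  # the trigger pathway is a single reliable event: same weight and delay as
  # the ring, but no jitter and a fully saturating quantal content, so
  # chopping starts at a sharp time across trials
  trigger <- synapse_params(weight = .cal$w_chopper, delay_mean = delay,
                            quanta_per_spike = 10)
  synapses[[length(synapses) + 1L]] <-
    list(pre = "onset", post = ids[1], params = trigger)

  inputs <- list()
  if (!is.null(drive)) {
    w_an_total <- .cal$w_chopper / .cal$an_weight_div
    if (an_mode == "current") {
      for (id in ids)
        inputs[[length(inputs) + 1L]] <- input_current(id, drive, w_an_total)
    } else {
      fp <- if (is.null(fiber_params)) an_fiber_params() else fiber_params
      # auditory-nerve synapses: slower transmitter kinetics pool the five
      # fibers into a smooth subthreshold depolarization
      syn_an <- synapse_params(weight = w_an_total / fp$n_fibers,
                               delay_mean = 0.4, delay_jitter_sd = 0,
                               transmitter_decay_tau = 2.5,
                               saturation_scale = 7, quanta_per_spike = 1)
      for (id in ids)
        inputs[[length(inputs) + 1L]] <- input_an(id, drive, fp, syn_an)
    }
    inputs[[length(inputs) + 1L]] <- input_onset("onset", drive)
  }
  network_spec(neurons, synapses, inputs,
               topology_label = sprintf("pacemaker%d", n_fast))
}

#' Attach a slow-chopper interval bank to a pacemaker
#'
#' Adds one slow chopper per refractory value, each receiving the pooled
#' suprathreshold output of every fast chopper.  Because the membrane is
#' clamped during the absolute refractory period, a slow chopper skips the
#' pacemaker inputs that fall inside it and fires at the first input after,
#' so its interspike intervals are integer multiples of the pacemaker clock
#' even when the refractory period itself is not.
#'
#' @param refractory_list numeric vector of absolute refractory periods (ms).
#' @param pacemaker a [network_spec()] from [build_pacemaker()].
#' @param weight pacemaker-to-slow synaptic weight (suprathreshold alone).
#' @param jitter_sd delay jitter SD for the projection synapses; defaults to
#'   the pacemaker ring's jitter.
#' @return the extended [network_spec()].
#' @export
build_interval_bank <- function(refractory_list, pacemaker,
                                weight = .cal$w_slow, jitter_sd = NULL) {
  if (length(refractory_list) == 0) stopf("'refractory_list' must be non-empty")
  if (any(refractory_list <= 0)) stopf("refractory periods must be > 0")
  if (is.null(jitter_sd))
    jitter_sd <- pacemaker$synapses[[1]]$params$delay_jitter_sd
  fast_ids <- grep("^fast", names(pacemaker$neurons), value = TRUE)
  neurons <- pacemaker$neurons
  synapses <- pacemaker$synapses
  syn <- synapse_params(weight = weight, delay_mean = 0.4,
                        delay_jitter_sd = jitter_sd)
  for (i in seq_along(refractory_list)) {
    id <- sprintf("slow%d", i)
    neurons[[id]] <- slow_chopper_params(refractory_list[i])
    for (f in fast_ids)
      synapses[[length(synapses) + 1L]] <- list(pre = f, post = id, params = syn)
  }
  network_spec(neurons, synapses, pacemaker$inputs,
               topology_label = paste0(pacemaker$topology_label, "+bank"))
}

# resample a waveform onto the engine's left-endpoint grid; zero outside its
# support
resample_drive <- function(w, n_steps, dt) {
  tw <- waveform_times(w)
  te <- (seq_len(n_steps) - 1) * dt
  if (length(w$samples) == 1) {
    out <- ifelse(te <= tw, w$samples, 0)
  } else {
    out <- stats::approx(tw, w$samples, xout = te, rule = 1)$y
    out[is.na(out)] <- 0
  }
  out
}

#' Simulate a network
#'
#' Clock-driven loop at `dt`: delayed synaptic deposits are delivered into
#' each synapse's transmitter pool, every neuron takes one Euler step, spikes
#' are recorded at the crossing step, and outgoing deposits are scheduled
#' with per-spike delays.  Simultaneous deliveries within one step are summed
#' before the neuron step.  All randomness is drawn from per-trial seeds
#' derived from `master_seed`, so identical `(spec, config)` give
#' bit-identical results and trials do not depend on execution order.
#'
#' @param spec a [network_spec()].
#' @param config an [engine_config()].
#' @return an object of class `sim_result`: `spikes` (named list of
#'   [spike_train()]), `traces` (matrix of membrane potentials of the first
#'   trial when `record_state`), `times` (trace time axis), `config_echo`.
#' @export
simulate_network <- function(spec, config) {
  if (!inherits(spec, "network_spec")) stopf("'spec' must be a network_spec")
  if (!inherits(config, "engine_config")) stopf("'config' must be an engine_config")
  dt <- config$dt
  n_steps <- round(config$duration / dt)
  ids <- names(spec$neurons)
  is_lif <- vapply(spec$neurons, inherits, logical(1), "lif_params")
  lif_ids <- ids[is_lif]
  onset_ids <- ids[!is_lif]
  n_lif <- length(lif_ids)

  # static LIF parameter vectors
  p <- spec$neurons[lif_ids]
  tau <- vapply(p, `[[`, 0, "membrane_time_constant")
  thr <- vapply(p, `[[`, 0, "threshold")
  vreset <- vapply(p, `[[`, 0, "reset")
  eleak <- vapply(p, `[[`, 0, "leak_reversal")
  absr_steps <- round(vapply(p, `[[`, 0, "absolute_refractory") / dt)
  rel_amp <- vapply(p, `[[`, 0, "relative_refractory_amplitude")
  rel_tau <- vapply(p, `[[`, 0, "relative_refractory_tau")
  dtau <- dt / tau

  trial_seeds <- derive_seeds(config$master_seed, config$n_trials)
  spikes_acc <- lapply(ids, function(i) vector("list", config$n_trials))
  names(spikes_acc) <- ids
  traces <- NULL
  trace_times <- NULL

  for (trial in seq_len(config$n_trials)) {
    res <- with_local_seed(trial_seeds[trial],
                           run_trial(spec, config, n_steps, lif_ids, onset_ids,
                                     tau, thr, vreset, eleak, absr_steps,
                                     rel_amp, rel_tau, dtau))
    for (id in ids) spikes_acc[[id]][[trial]] <- res$spikes[[id]]
    if (trial == 1 && config$record_state) {
      traces <- res$trace
      trace_times <- seq_len(n_steps) * dt
    }
  }

  out_trains <- lapply(ids, function(id) {
    refr <- if (id %in% lif_ids)
      spec$neurons[[id]]$absolute_refractory else NULL
    spike_train(spikes_acc[[id]], t_stop = config$duration, unit_id = id,
                refractory = refr)
  })
  names(out_trains) <- ids
  structure(list(spikes = out_trains, traces = traces, times = trace_times,
                 config_echo = list(config = config,
                                    topology = spec$topology_label,
                                    n_neurons = length(ids),
                                    n_synapses = length(spec$synapses))),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s: %d units, %d trial(s), %.1f ms\n",
              x$config_echo$topology, length(x$spikes),
              x$config_echo$config$n_trials, x$config_echo$config$duration))
  for (id in names(x$spikes))
    cat(sprintf("  %-8s %d spikes\n", id, n_spikes(x$spikes[[id]])))
  invisible(x)
}

# One trial of the clock-driven loop.  Runs inside the trial's RNG stream.
run_trial <- function(spec, config, n_steps, lif_ids, onset_ids,
                      tau, thr, vreset, eleak, absr_steps, rel_amp, rel_tau,
                      dtau) {
  dt <- config$dt
  n_lif <- length(lif_ids)

  # resolve onset units and per-trial auditory-nerve trains
  source_spikes <- list()   # unit id -> spike time vector (ms)
  for (oid in onset_ids) {
    dr <- NULL
    for (inp in spec$inputs)
      if (inp$type == "onset_drive" && inp$target == oid) dr <- inp$waveform
    source_spikes[[oid]] <-
      if (is.null(dr)) numeric(0)
      else onset_response(dr, spec$neurons[[oid]])$trials[[1]]
  }

  # synapse table: network synapses plus one synapse per AN fiber / fixed
  # train.  Columns are parallel vectors.
  s_pre <- character(0); s_post <- character(0); s_par <- list()
  s_source <- list()  # per synapse: NULL (dynamic) or spike-time vector
  add_syn <- function(pre, post, par, source) {
    s_pre[[length(s_pre) + 1L]] <<- pre
    s_post[[length(s_post) + 1L]] <<- post
    s_par[[length(s_par) + 1L]] <<- par
    s_source[length(s_source) + 1L] <<- list(source)  # may be NULL
  }
  for (s in spec$synapses) {
    src <- if (s$pre %in% onset_ids) source_spikes[[s$pre]] else NULL
    add_syn(s$pre, s$post, s$params, src)
  }
  i_ext <- matrix(0, n_steps, n_lif, dimnames = list(NULL, lif_ids))
  for (inp in spec$inputs) {
    if (inp$type == "current") {
      i_ext[, inp$target] <- i_ext[, inp$target] +
        inp$weight * resample_drive(inp$waveform, n_steps, dt)
    } else if (inp$type == "an") {
      fp <- inp$fiber_params
      fp$seed <- sample.int(.Machine$integer.max - 1L, 1L)
      trains <- an_spikes(inp$waveform, fp, n_trials = 1)
      for (tr in trains)
        add_syn(tr$unit_id, inp$target, inp$synapse, tr$trials[[1]])
    } else if (inp$type == "spikes") {
      for (tr in inp$trains)
        add_syn(tr$unit_id, inp$target, inp$synapse, tr$trials[[1]])
    }
  }

  n_syn <- length(s_par)
  w <- vapply(s_par, `[[`, 0, "weight")
  sat <- vapply(s_par, `[[`, 0, "saturation_scale")
  q <- vapply(s_par, `[[`, 0, "quanta_per_spike")
  decay <- exp(-dt / vapply(s_par, `[[`, 0, "transmitter_decay_tau"))
  dmean <- vapply(s_par, `[[`, 0, "delay_mean")
  djit <- vapply(s_par, `[[`, 0, "delay_jitter_sd")

  # deposit schedule; source-driven synapses are prefilled
  D <- matrix(0, n_steps, max(n_syn, 1L))
  for (s in seq_len(n_syn)) {
    st <- s_source[[s]]
    if (is.null(st) || !length(st)) next
    delays <- draw_delays(length(st), dmean[s], djit[s], dt)
    arr <- pmax(1L, round((st + delays) / dt))
    for (a in arr[arr <= n_steps]) D[a, s] <- D[a, s] + q[s]
  }
  dynamic <- which(vapply(s_source, is.null, logical(1)))
  dyn_by_pre <- split(dynamic, s_pre[dynamic])

  post_idx <- match(s_post, lif_ids)
  mmat <- matrix(0, n_lif, max(n_syn, 1L))
  for (s in seq_len(n_syn)) mmat[post_idx[s], s] <- 1

  v <- eleak
  last <- rep(-Inf, n_lif)
  clamp_left <- integer(n_lif)
  conc <- numeric(max(n_syn, 1L))
  spk_times <- lapply(seq_len(n_lif), function(i) numeric(0))
  trace <- if (config$record_state)
    matrix(NA_real_, n_steps, n_lif, dimnames = list(NULL, lif_ids)) else NULL

  for (k in seq_len(n_steps)) {
    t_now <- k * dt
    if (n_syn) conc <- conc + D[k, ]
    i_post <- if (n_syn) drop(mmat %*% (w * tanh(conc / sat))) else numeric(n_lif)
    i_post <- i_post + i_ext[k, ]
    clamped <- clamp_left > 0L
    v_new <- v + dtau * (eleak - v + i_post)
    v_new[clamped] <- vreset[clamped]
    thr_eff <- thr + rel_amp * exp(-(t_now - last) / rel_tau)
    spk <- !clamped & v_new >= thr_eff
    if (any(spk)) {
      v_new[spk] <- vreset[spk]
      last[spk] <- t_now
      clamp_left[spk] <- absr_steps[spk]
      for (i in which(spk)) {
        spk_times[[i]] <- c(spk_times[[i]], t_now)
        for (s in dyn_by_pre[[lif_ids[i]]]) {
          delay <- draw_delays(1L, dmean[s], djit[s], dt)
          a <- k + max(1L, round(delay / dt))
          if (a <= n_steps) D[a, s] <- D[a, s] + q[s]
        }
      }
    }
    clamp_left[clamped] <- clamp_left[clamped] - 1L
    if (n_syn) conc <- conc * decay
    v <- v_new
    if (!is.null(trace)) trace[k, ] <- v
  }

  spikes <- stats::setNames(spk_times, lif_ids)
  for (oid in onset_ids) spikes[[oid]] <- source_spikes[[oid]]
  list(spikes = spikes, trace = trace)
}

#' Does network self-excitation stop after the input ends?
#'
#' The mutual excitation of the pacemaker must not run away: the offset of
#' the auditory-nerve input is sufficient to stop the chopping.  The
#' condition is true iff no network spikes occur later than
#' `input offset + K * max membrane time constant`.  When the input lasts to
#' the end of the simulated window the question cannot be decided and the
#' condition is reported `FALSE`.
#'
#' @param spec the simulated [network_spec()].
#' @param result the matching `sim_result`.
#' @param K number of membrane time constants of grace after offset.
#' @return logical.
#' @export
stop_condition <- function(spec, result, K = 10) {
  offsets <- numeric(0)
  for (inp in spec$inputs) {
    if (inp$type %in% c("current", "an", "onset_drive")) {
      nz <- which(abs(inp$waveform$samples) > 0)
      if (length(nz))
        offsets <- c(offsets, waveform_times(inp$waveform)[nz[length(nz)]])
    } else if (inp$type == "spikes") {
      offsets <- c(offsets, unlist(lapply(inp$trains,
                                          function(tr) unlist(tr$trials))))
    }
  }
  if (!length(offsets)) return(TRUE)  # nothing drives the network
  offset <- max(offsets)
  is_lif <- vapply(spec$neurons, inherits, logical(1), "lif_params")
  tau_max <- max(vapply(spec$neurons[is_lif], `[[`, 0,
                        "membrane_time_constant"))
  horizon <- offset + K * tau_max
  if (horizon >= result$config_echo$config$duration) return(FALSE)
  for (id in names(spec$neurons)[is_lif]) {
    tt <- unlist(result$spikes[[id]]$trials)
    if (length(tt) && max(tt) > horizon) return(FALSE)
  }
  TRUE
}
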