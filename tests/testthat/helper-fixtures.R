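# Shared fixtures.  Simulations are memoised so that several test files can
# reuse the same run without paying for it twice.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# default step drive used by the deterministic circuit tests: auditory-nerve
# current on from 2 ms to past the end of the simulated window
fx_drive <- function(t_off = 60) step_drive(0.95 / 3, 2, t_off, duration = t_off + 5)

fx_pacemaker_sim <- function() {
  memo("pacemaker2", {
    spec <- build_pacemaker(2, drive = fx_drive())
    list(spec = spec,
         res = simulate_network(spec, engine_config(duration = 50)))
  })
}

fx_pacemaker3_sim <- function() {
  memo("pacemaker3", {
    spec <- build_pacemaker(3, drive = fx_drive())
    list(spec = spec,
         res = simulate_network(spec, engine_config(duration = 50)))
  })
}

fx_bank_sim <- function() {
  memo("bank", {
    spec <- build_interval_bank(c(0.5, 0.9, 1.3, 1.7, 2.1),
                                build_pacemaker(2, drive = fx_drive(110)))
    list(spec = spec,
         res = simulate_network(spec, engine_config(duration = 100)))
  })
}

# stochastic sustained-chopper protocol: tone burst at the unit's CF through
# the auditory-nerve front end, jittered ring delays
fx_protocol_sim <- function(n_trials = 100, seed = 7) {
  memo(sprintf("protocol_%d_%d", n_trials, seed), {
    w <- make_tone_burst(tone_burst_spec())
    fp <- an_fiber_params(release_rate_at_peak = level_to_rate(30))
    spec <- build_pacemaker(2, jitter_sd = 0.26, drive = w, an_mode = "an",
                            fiber_params = fp)
    list(spec = spec,
         res = simulate_network(spec, engine_config(duration = 40,
                                                    n_trials = n_trials,
                                                    master_seed = seed)))
  })
}

# independent event-trace oracle for the interval bank: pacemaker population
# events tick at exactly `clock` ms; a slow chopper fires at the first event
# strictly later than its refractory period after its last spike
oracle_slow_isis <- function(refractory, clock = 0.4, horizon = 100,
                             first_event = 0) {
  events <- seq(first_event, horizon, by = clock)
  spikes <- events[1]
  for (e in events[-1]) {
    if (e - spikes[length(spikes)] > refractory + 1e-9)
      spikes <- c(spikes, e)
  }
  diff(spikes)
}

# brute-force enumeration oracle for the coincidence equation
oracle_solve_coincidence <- function(tau_c, tau_k, max_int, tol) {
  out <- NULL
  for (m in 1:max_int) for (n in 1:max_int) for (k in 0:max_int) {
    tau_m <- (n * tau_c - k * tau_k) / m
    res <- abs(m * tau_m - (n * tau_c - k * tau_k))
    if (tau_m > tau_c && res <= tol)
      out <- rbind(out, data.frame(m = m, n = n, k = k, tau_m = tau_m,
                                   residual = res))
  }
  out <- out[order(out$m, out$residual, out$tau_m, out$n, out$k), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
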