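# Stimulus waveforms and the auditory-nerve front end.

test_that("tone bursts have the right support, envelope and level mapping", {
  w <- make_tone_burst(tone_burst_spec(frequency = 2890, duration = 25,
                                       rise_fall = 1.6, level = 30))
  t <- waveform_times(w)
  expect_equal(w$duration * 1e3, 25)
  expect_equal(length(w$samples) * w$sample_interval, 25e-3)
  # ramped envelope: amplitude inside the ramps is below the plateau
  plateau <- max(abs(w$samples[t > 5 & t < 20]))
  expect_lt(max(abs(w$samples[t < 0.8])), 0.6 * plateau)
  expect_lt(max(abs(w$samples[t > 24.4])), 0.6 * plateau)

  silent <- make_tone_burst(tone_burst_spec(level = -Inf))
  expect_true(all(silent$samples == 0))

  gated <- make_tone_burst(tone_burst_spec(frequency = 1000, duration = 10,
                                           rise_fall = 0, level = 0))
  # rectangular gate: every carrier cycle reaches the full peak
  tg <- waveform_times(gated)
  for (cyc in 0:8)
    expect_gt(max(abs(gated$samples[tg >= cyc & tg < cyc + 1])), 0.99)

  expect_error(tone_burst_spec(duration = 3, rise_fall = 1.6), "rise_fall")
  expect_error(tone_burst_spec(frequency = -1), "frequency")
})

test_that("AM tones have the specified envelope periodicity", {
  # depth 0: pure carrier, flat envelope
  flat <- make_am(am_spec(tau_c = 0.25, tau_m = 1.2, depth = 0, duration = 10))
  env <- abs(flat$samples)
  cyc_max <- tapply(env, floor(waveform_times(flat) / 0.25), max)
  expect_lt(diff(range(cyc_max[2:(length(cyc_max) - 1)])), 0.02)

  # oracle: autocorrelation of the analytic envelope peaks at tau_m
  spec <- am_spec(tau_c = 0.25, tau_m = 1.2, depth = 1, duration = 25)
  w <- make_am(spec)
  t <- waveform_times(w)
  env <- 1 + spec$depth * sin(2 * pi * t / spec$tau_m)
  ac <- stats::acf(env, lag.max = 80, plot = FALSE)$acf[-1]
  # first non-trivial peak: skip lags inside half a modulation period
  lo <- round(0.6 / (w$sample_interval * 1e3))
  lag_ms <- (lo - 1 + which.max(ac[lo:80])) * w$sample_interval * 1e3
  expect_equal(lag_ms, 1.2, tolerance = 0.05)

  # integer number of modulation cycles fits the duration
  spec5 <- am_spec(tau_c = 0.5, tau_m = 5, depth = 1, duration = 25)
  expect_equal(spec5$duration / spec5$tau_m, 5)

  expect_error(am_spec(tau_c = 1, tau_m = 0.5), "exceed")
})

test_that("step drives are piecewise constant with exact support", {
  w <- step_drive(1, 5, 30, duration = 40)
  t <- waveform_times(w)
  expect_true(all(w$samples[t >= 5 & t < 30] == 1))
  expect_true(all(w$samples[t < 5 | t >= 30] == 0))
  expect_true(all(step_drive(0, 5, 30)$samples == 0))
  # construction is linear: two steps superpose
  a <- step_drive(1, 5, 15, duration = 40)$samples
  b <- step_drive(0.5, 10, 30, duration = 40)$samples
  ab <- a + b
  expect_equal(max(ab), 1.5)
  expect_error(step_drive(1, 10, 5), "t_off")
})

test_that("spike train invariants are enforced", {
  expect_error(spike_train(list(c(2, 1)), 10), "strictly increasing")
  expect_error(spike_train(list(c(1, 12)), 10), "t_stop")
  expect_error(spike_train(list(c(1, 1.5)), 10, refractory = 1), "refractory")
  tr <- spike_train(c(1, 2, 4), 10)
  expect_equal(length(tr$trials), 1L)
  expect_equal(n_spikes(tr), 3L)
})

test_that("auditory-nerve spikes phase lock, adapt and respect the dead time", {
  w <- make_tone_burst(tone_burst_spec(frequency = 1000, duration = 50,
                                       rise_fall = 0, level = 30))
  fp <- an_fiber_params(n_fibers = 2, release_rate_at_peak = 8000, seed = 42)
  trains <- an_spikes(w, fp, n_trials = 20)
  expect_length(trains, 2)

  # refractory invariant on every trial
  for (tr in trains) for (tt in tr$trials)
    if (length(tt) > 1) expect_true(all(diff(tt) >= fp$refractory - 1e-9))

  # phase locking to the carrier
  expect_gt(vector_strength(trains[[1]], 1000), 0.5)

  # adaptation: early trial-averaged rate exceeds late rate
  fp200 <- an_fiber_params(n_fibers = 1, release_rate_at_peak = 8000, seed = 9)
  many <- an_spikes(w, fp200, n_trials = 200)[[1]]
  tt <- unlist(many$trials)
  expect_gt(sum(tt < 5), sum(tt >= 45))

  # determinism and seed decorrelation
  again <- an_spikes(w, fp, n_trials = 20)
  expect_identical(trains[[1]]$trials, again[[1]]$trials)
  other <- an_spikes(w, an_fiber_params(n_fibers = 2, seed = 43), n_trials = 20)
  expect_false(identical(trains[[1]]$trials, other[[1]]$trials))

  # zero waveform, zero spontaneous rate: silence
  silent <- an_spikes(step_drive(0, 1, 2, duration = 10), fp)
  expect_equal(sum(vapply(silent, n_spikes, 0L)), 0L)
})
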