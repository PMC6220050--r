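# Single-neuron dynamics.

test_that("a LIF neuron at rest stays silent and decays to the leak reversal", {
  p <- lif_params()
  s <- lif_state(membrane_potential = 0.9)
  for (k in 1:400) {
    r <- lif_step(s, 0, 0.025, p)
    s <- r$state
    expect_false(r$spiked)
  }
  expect_lt(abs(s$membrane_potential - p$leak_reversal), 1e-4)
})

test_that("constant suprathreshold drive reproduces the closed-form LIF period", {
  p <- lif_params(reset = 0, absolute_refractory = 0,
                  relative_refractory_amplitude = 0)
  for (current in c(1.5, 2, 4)) {
    expected <- lif_isi_closed_form(current, p)
    s <- lif_state()
    spikes <- numeric(0)
    dt <- 0.002
    for (k in seq_len(round(8 * expected / dt))) {
      r <- lif_step(s, current, dt, p)
      s <- r$state
      if (r$spiked) spikes <- c(spikes, s$time)
    }
    expect_equal(mean(diff(spikes)), expected, tolerance = 0.01)
  }
  expect_identical(lif_isi_closed_form(0.5, p), Inf)
})

test_that("inputs during the absolute refractory period are skipped", {
  p <- lif_params(absolute_refractory = 1)
  s <- lif_state(membrane_potential = 0.99)
  r <- lif_step(s, 100, 0.025, p)     # forced spike
  expect_true(r$spiked)
  s <- r$state
  # huge input right after the spike: clamped, no spike, no residual charge
  for (k in 1:30) {
    r <- lif_step(s, 1000, 0.025, p)
    s <- r$state
    expect_false(r$spiked)
    expect_equal(s$membrane_potential, p$reset)
  }
  expect_error(lif_step(s, 0, -1, p), "dt")
})

test_that("single-spike onset mode fires once at drive onset plus latency", {
  tr <- onset_response(step_drive(1, 5, 30, duration = 35),
                       onset_params(spike_latency = 0.1))
  expect_equal(tr$trials[[1]], 5.1)
  empty <- onset_response(step_drive(0, 5, 30, duration = 35), onset_params())
  expect_length(empty$trials[[1]], 0)
})

test_that("HH onset mode is phasic: a sustained step elicits at most two spikes", {
  tr <- onset_response(step_drive(1, 5, 30, duration = 35),
                       onset_params(mode = "hh"))
  n <- length(tr$trials[[1]])
  expect_gte(n, 1)
  expect_lte(n, 2)
  expect_gt(tr$trials[[1]][1], 5)      # causal
  expect_lt(tr$trials[[1]][1], 8)      # onset latency, not sustained firing
  silent <- onset_response(step_drive(0, 5, 30, duration = 35),
                           onset_params(mode = "hh"))
  expect_length(silent$trials[[1]], 0)
})

test_that("LIF steady firing rate is non-decreasing in drive amplitude", {
  p <- lif_params(reset = 0, absolute_refractory = 0.1,
                  relative_refractory_amplitude = 0)
  rate_at <- function(current) {
    s <- lif_state()
    n <- 0L
    for (k in 1:4000) {
      r <- lif_step(s, current, 0.025, p)
      s <- r$state
      if (r$spiked) n <- n + 1L
    }
    n
  }
  rates <- vapply(c(1.2, 1.5, 2, 3, 6), rate_at, 0L)
  expect_true(all(diff(rates) >= 0))
})
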