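# Spike-train statistics.

test_that("interspike intervals pair each gap with its onset spike", {
  df <- isis(spike_train(list(c(1, 2, 4)), 10))
  expect_equal(df$onset_time, c(1, 2))
  expect_equal(df$isi, c(1, 2))
  expect_equal(nrow(isis(spike_train(list(3), 10))), 0L)  # one spike, no ISI
  # pooled across trials
  df2 <- isis(spike_train(list(c(1, 2), c(5, 7)), 10))
  expect_equal(df2$isi, c(1, 2))
  expect_equal(df2$trial, c(1L, 2L))
})

test_that("the pacemaker benchmark yields only 0.8 ms intervals", {
  fx <- fx_pacemaker_sim()
  expect_equal(unique(round(isis(fx$res$spikes$fast1)$isi, 6)), 0.8)
})

test_that("the PSTH conserves spike counts and bins correctly", {
  tr <- spike_train(list(c(0.15, 2), c(0.1)), 10)
  p <- psth(tr, bin_width = 0.3)
  expect_equal(sum(p$counts), 3L)
  expect_equal(p$counts[1], 2L)  # both sub-0.3 spikes in the first bin
  fx <- fx_protocol_sim(n_trials = 100, seed = 7)
  p5 <- psth(fx$res$spikes$fast1, bin_width = 0.3)
  expect_equal(sum(p5$counts), n_spikes(fx$res$spikes$fast1))
})

test_that("the chopper protocol PSTH shows chopping peaks near 0.8 ms apart", {
  fx <- fx_protocol_sim(n_trials = 100, seed = 7)
  p <- psth(fx$res$spikes$fast1, bin_width = 0.3)
  peaks <- histogram_peaks(p, frac = 0.15, min_separation = 0.5)
  peaks <- peaks[peaks < 8]
  expect_gte(length(peaks), 3)
  spacing <- diff(peaks)
  expect_true(all(spacing >= 0.5 & spacing <= 1.25))
})

test_that("regularity flags sparse bins and is zero for periodic trains", {
  tr <- spike_train(list(seq(0.5, 29.5, by = 0.8)), 30)
  reg <- regularity(tr, bin_width = 2, min_count = 2)
  defined <- reg[reg$defined, ]
  expect_gt(nrow(defined), 5)
  expect_true(all(defined$cv < 1e-9))
  expect_true(all(abs(defined$mean_isi - 0.8) < 1e-9))
  # bins after the train end carry no statistics
  expect_true(all(is.na(reg$cv[!reg$defined])))
})

test_that("exponential interval trains approach the Poisson CV of one", {
  set.seed(31)
  gaps <- stats::rexp(1e4, rate = 1)
  tr <- spike_train(list(cumsum(gaps)), sum(gaps) + 1)
  reg <- regularity(tr, bin_width = sum(gaps) + 1, min_count = 10)
  cv <- reg$cv[reg$defined][1]
  expect_equal(cv, 1, tolerance = 0.1)
})

test_that("regularity is invariant to trial order and uniform time shifts", {
  fx <- fx_protocol_sim(n_trials = 100, seed = 7)
  tr <- fx$res$spikes$fast1
  swapped <- spike_train(rev(tr$trials), tr$t_stop)
  expect_equal(regularity(swapped, 1)$cv, regularity(tr, 1)$cv)
  shifted <- spike_train(lapply(tr$trials, `+`, 2), tr$t_stop + 2)
  a <- regularity(tr, 1)
  b <- regularity(shifted, 1)
  def_a <- which(a$defined)
  expect_equal(b$cv[def_a + 2], a$cv[def_a])  # 2 ms = 2 bins
})

test_that("base-interval estimation recovers common divisors with tie-breaks", {
  fit <- base_interval(c(0.8, 1.2, 2.0), c(0.1, 0.45, 0.01))
  expect_equal(fit$base, 0.4)
  expect_equal(fit$rms_deviation, 0, tolerance = 1e-9)
  expect_equal(sort(fit$multiples), c(2L, 3L, 5L))
  # largest exact divisor wins ties
  expect_equal(base_interval(1, c(0.3, 1.0, 0.1))$base, 1)
  # exact multiples of an on-grid base are recovered exactly
  for (b in c(0.2, 0.3, 0.4)) {
    vals <- b * c(2, 3, 5, 7)
    expect_equal(base_interval(vals, c(0.1, 0.45, 0.01))$base, b)
  }
  expect_error(base_interval(numeric(0)), "non-empty")
})

test_that("the interval bank's pooled intervals reveal the 0.4 ms base", {
  fx <- fx_bank_sim()
  pooled <- unlist(lapply(1:5, function(i)
    isis(fx$res$spikes[[sprintf("slow%d", i)]])$isi))
  fit <- base_interval(pooled, c(0.1, 0.45, 0.01))
  expect_equal(fit$base, 0.4, tolerance = 0.011)
  expect_lt(fit$rms_deviation, 0.01)
})
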