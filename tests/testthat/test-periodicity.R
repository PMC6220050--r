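# Coincidence equation and the periodicity network.

test_that("the coincidence solver matches a brute-force triple loop", {
  set.seed(55)
  for (rep in 1:25) {
    tau_c <- stats::runif(1, 0.1, 1)
    tau_k <- stats::runif(1, 0.1, 1)
    got <- solve_coincidence(tau_c, tau_k, max_int = 6, tol = 0.05)
    want <- oracle_solve_coincidence(tau_c, tau_k, max_int = 6, tol = 0.05)
    expect_equal(as.data.frame(got)[c("m", "n", "k")],
                 want[c("m", "n", "k")])
    expect_equal(got$tau_m, want$tau_m)
    # every emitted solution satisfies the equation by substitution
    expect_true(all(abs(got$m * got$tau_m -
                          (got$n * tau_c - got$k * tau_k)) <= 0.05))
    expect_true(all(got$tau_m > tau_c))
  }
})

test_that("k = 0 solutions are the integrator harmonics of the carrier", {
  s <- solve_coincidence(0.5, 0.3, max_int = 5, tol = 1e-9)
  k0 <- s[s$k == 0 & s$m == 1, ]
  expect_equal(sort(k0$tau_m), 0.5 * 2:5)   # n*tau_c for n = 2..5 (n=1 excluded)
  # tau_m for m = 2 is half that for m = 1 at equal (n, k)
  m1 <- s[s$m == 1 & s$n == 4 & s$k == 1, "tau_m"]
  m2 <- s[s$m == 2 & s$n == 4 & s$k == 1, "tau_m"]
  expect_equal(m2, m1 / 2)
})

test_that("best modulation frequency follows the oscillator arithmetic", {
  u <- periodicity_unit(cf = 4000, tau_k = 0.4, integrator_n = 8)
  b <- bmf_of_unit(u)
  expect_true(b$tuned)
  expect_equal(b$tau_m, 1.2)        # 8 * 0.25 - 2 * 0.4
  expect_equal(b$k, 2)
  expect_equal(b$bmf, 1000 / 1.2, tolerance = 1e-9)
  # vanishing oscillator contribution: BMF = cf / n
  u0 <- periodicity_unit(cf = 1000, tau_k = 1e-6, integrator_n = 4,
                         n_osc_spikes = 0)
  expect_equal(bmf_of_unit(u0)$bmf, 250, tolerance = 1e-3)
  # tuned units hit the requested CF/BMF ratio exactly
  tu <- tuned_unit(cf = 3000, ratio = 6)
  expect_equal(bmf_of_unit(tu)$bmf, 500, tolerance = 1e-9)
})

test_that("a unit responds maximally at its best modulation frequency", {
  u <- tuned_unit(cf = 2400, ratio = 6, inhibition_enabled = TRUE)
  bmf <- bmf_of_unit(u)$bmf
  resp_bmf <- unit_response(am_spec(u$tau_c, 1000 / bmf, 1, 150), u)
  for (fm in bmf * c(0.7, 0.85, 1.2, 1.5)) {
    r <- unit_response(am_spec(u$tau_c, 1000 / fm, 1, 150), u)
    expect_lte(r, resp_bmf)
  }
  expect_gt(resp_bmf, 0)
  # flat envelope: no trigger events, no response
  expect_equal(unit_response(am_spec(u$tau_c, 1000 / bmf, 0, 150), u), 0L)
  expect_error(unit_response(am_spec(0.25, 10, 1, 5), u), "modulation period")
})

test_that("inhibition suppresses the harmonic response", {
  u_on <- tuned_unit(cf = 2400, ratio = 6, inhibition_enabled = TRUE)
  u_off <- tuned_unit(cf = 2400, ratio = 6, inhibition_enabled = FALSE)
  bmf <- bmf_of_unit(u_on)$bmf
  st <- am_spec(u_on$tau_c, 1000 / (2 * bmf), 1, 150)  # second harmonic
  expect_lt(unit_response(st, u_on), unit_response(st, u_off))
  expect_gt(unit_response(st, u_off), 0)
})

test_that("the response matrix has the tuned diagonal and harmonic sidebands", {
  rm_on <- response_matrix(inhibition = TRUE)
  rm_off <- response_matrix(inhibition = FALSE)
  expect_equal(dim(rm_on$response), c(16L, 16L))
  # with inhibition each row peaks at the column nearest CF/6
  for (i in 1:16) {
    target <- which.min(abs(rm_on$mod_freqs - rm_on$carrier_freqs[i] / 6))
    expect_equal(unname(which.max(rm_on$response[i, ])), target)
  }
  # inhibition never increases any cell
  expect_true(all(rm_on$response <= rm_off$response))
  # without inhibition at least one row has a strong response at the
  # second harmonic of its best modulation frequency
  harmonic_frac <- vapply(1:11, function(i)
    rm_off$response[i, i + 5] / max(rm_off$response[i, ]), 0)
  expect_true(any(harmonic_frac > 0.25))
})
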