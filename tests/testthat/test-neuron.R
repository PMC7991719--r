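test_that("membrane derivative matches hand-evaluated values", {
  expect_equal(membrane_derivative(-70, -14), 0)
  expect_equal(membrane_derivative(0, 0), 140)
  expect_equal(membrane_derivative(-65, -13), -3)
})

test_that("the RS resting point is stationary to machine precision", {
  p <- izh_params("RS")
  st <- neuron_state(p)
  expect_equal(st$v, -70)
  expect_equal(st$u, -14)
  for (i in 1:10000) {
    out <- step_neuron(st, p, input_current = 0, dt = 0.5)
    st <- out$state
  }
  expect_equal(st$v, -70, tolerance = 1e-12)
  expect_equal(st$u, -14, tolerance = 1e-12)
  expect_length(st$spike_times, 0)
})

test_that("parameter presets carry the published RS and FS values", {
  rs <- izh_params("RS")
  expect_equal(unlist(rs[c("a", "b", "c", "d")]),
               c(a = 0.01, b = 0.2, c = -65, d = 8))
  fs <- izh_params("FS")
  expect_equal(unlist(fs[c("a", "b", "c", "d")]),
               c(a = 0.1, b = 0.2, c = -65, d = 2))
  expect_equal(rs$v_peak, 30)
})

test_that("a spike is registered, clamped at 30 mV, and reset", {
  p <- izh_params("RS")
  st <- neuron_state(p, v = 35, u = -14)  # already past threshold
  out <- step_neuron(st, p, input_current = 0, dt = 0.5, t = 0.5)
  expect_true(out$spiked)
  expect_equal(out$v_trace, 30)
  expect_equal(out$state$v, p$c)          # v <- c
  expect_equal(out$state$spike_times, 0.5)
  # u is incremented by d on top of its Euler step
  expect_gt(out$state$u, -14 + p$d - 1)
})

test_that("recorded voltage traces never exceed the peak and spikes increase", {
  r <- simulate_window(c(n = 10), izh_params("RS"), 1000, record_v = TRUE)
  expect_true(all(r$v <= 30))
  expect_true(all(diff(r$times[[1]]) > 0))
  # every spike sample is followed by a trace value restarting from reset
  spike_steps <- round(r$times[[1]] / r$dt)
  after <- r$v[pmin(spike_steps + 1, nrow(r$v)), 1]
  expect_true(all(after < 0))
})

test_that("diverging integration is reported as an error", {
  st <- neuron_state()
  expect_error(
    {
      out <- st
      for (i in 1:50) out <- step_neuron(out, izh_params("RS"), 1e6, dt = 50)$state
    },
    "non-finite"
  )
})

test_that("firing rate is non-decreasing in constant current", {
  counts <- package_counts(seq(0, 20, length.out = 20))
  expect_true(all(diff(counts) >= 0))
})

test_that("coarse integration tracks the fine-step reference within one spike", {
  currents <- 0:20
  coarse <- package_counts(currents, dt = 0.5)
  fine <- euler_reference_counts(currents, dt = 0.05)
  expect_true(all(abs(coarse - fine) <= 1))
})

test_that("simulate_window handles empty drive and validates inputs", {
  r <- simulate_window(c(a = 0, b = 0, c = 0), izh_params("RS"), 1000)
  expect_equal(sum(lengths(r$times)), 0)
  expect_error(
    simulate_window(c(1, 2), list(izh_params("RS")), 100),
    "does not match")
})

test_that("calibrated band currents reproduce their target rates", {
  rs <- izh_params("RS")
  i_theta <- calibrate_band_current(rs, 6)
  n_theta <- package_counts(i_theta)
  expect_gte(n_theta, 5)
  expect_lte(n_theta, 7)
  i_gamma <- calibrate_band_current(rs, 50)
  n_gamma <- package_counts(i_gamma)
  expect_gte(n_gamma, 45)
  expect_lte(n_gamma, 55)
  expect_gt(i_gamma, i_theta)  # stronger drive for the faster band
  fs <- izh_params("FS")
  i_gamma_fs <- calibrate_band_current(fs, 50)
  n_fs <- package_counts(i_gamma_fs, fs)
  expect_gte(n_fs, 30)
  expect_lte(n_fs, 80)
  expect_error(calibrate_band_current(rs, 6, max_current = 1), "unreachable")
})

test_that("the band normalizer is bounded, monotone and zero-preserving", {
  nrm <- band_normalizer("theta", i_cal = 4.5)
  x <- c(-3, 0, 0.5, 2, 4, 8, 100)
  out <- normalize_drive(x, nrm, x_ref = 8)
  expect_true(all(out >= 0 & out <= 4.5))
  expect_equal(out[2], 0)
  expect_true(all(diff(out) >= 0))
  # drives below the relative threshold are silenced
  expect_equal(out[3], 0)
  # the reference drive maps exactly onto the calibrated current
  expect_equal(unname(out[6]), 4.5)
})
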