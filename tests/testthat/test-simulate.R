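test_that("null model produces identically zero traces", {
  m <- response_model(amax_uV = 0, slope_uV = 0, carrier_amp_uV = 0,
                      noise_sd_uV = 0)
  ep <- simulate_epochs(fast_grating(), m, seed = 1)
  expect_true(all(ep$traces == 0))
  expect_equal(dim(ep$traces), c(8L, 500L))
})

test_that("same seed reproduces traces bit-identically, different seeds differ", {
  p <- fast_grating()
  m <- response_model()
  a <- simulate_epochs(p, m, seed = 7)
  b <- simulate_epochs(p, m, seed = 7)
  d <- simulate_epochs(p, m, seed = 8)
  expect_identical(a$traces, b$traces)
  expect_false(isTRUE(all.equal(a$traces, d$traces)))
  # the caller's RNG stream is not disturbed
  set.seed(99); x1 <- rnorm(3)
  set.seed(99); invisible(simulate_epochs(p, m, seed = 7)); x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("trial averaging obeys the 1/sqrt(n) noise law", {
  m <- response_model(amax_uV = 0, slope_uV = 0, carrier_amp_uV = 0,
                      noise_sd_uV = 10)
  for (n in c(25L, 100L, 500L)) {
    p <- stimulus_protocol("full_field", pulse_duration_ms = 10,
                           rep_rate_hz = 1, irradiance_mw_mm2 = 1,
                           n_trials = n, sampling_rate_hz = 2000)
    avg <- average_epochs(simulate_epochs(p, m, seed = 100 + n))
    expect_equal(sd(avg$voltage), 10 / sqrt(n), tolerance = 0.1)
  }
})

test_that("direct average simulation matches the averaged-epochs noise scale", {
  m <- response_model(amax_uV = 0, slope_uV = 0, carrier_amp_uV = 0,
                      noise_sd_uV = 10)
  p <- stimulus_protocol("full_field", pulse_duration_ms = 10,
                         rep_rate_hz = 1, irradiance_mw_mm2 = 1,
                         n_trials = 500L, sampling_rate_hz = 2000)
  avg <- simulate_average(p, m, seed = 11)
  expect_equal(sd(avg$voltage), 10 / sqrt(500), tolerance = 0.1)
  expect_identical(avg$n_trials_averaged, 500L)
})

test_that("ladder seeding is reproducible and matches single-condition calls", {
  m <- response_model()
  ps <- list(fast_grating(40), fast_grating(80))
  lad <- simulate_ladder(ps, m, seed = 5)
  seeds <- ladder_seeds(5, 2)
  expect_identical(lad[[1]]$traces,
                   simulate_epochs(ps[[1]], m, seeds[1])$traces)
  expect_identical(lad[[2]]$traces,
                   simulate_epochs(ps[[2]], m, seeds[2])$traces)
  one <- simulate_ladder(ps[1], m, seed = 5)
  expect_length(one, 1)
  expect_identical(one[[1]]$traces,
                   simulate_epochs(ps[[1]], m, ladder_seeds(5, 1))$traces)
})

test_that("sigmoid law gives non-decreasing amplitudes along an irradiance ladder", {
  m <- response_model()
  irr <- exp(seq(log(0.002), log(4.7), length.out = 8))
  amps <- vapply(irr, function(E)
    evoked_amplitude(fast_fullfield(E), m), numeric(1))
  expect_true(all(diff(amps) >= 0))
})

test_that("grating law is zero at the acuity limit and logarithmic above it", {
  m <- response_model(slope_uV = 40, w_true_um = 28)
  expect_equal(evoked_amplitude(fast_grating(28), m), 0)
  expect_equal(evoked_amplitude(fast_grating(117), m), 40 * log(117 / 28))
  expect_equal(evoked_amplitude(fast_grating(13), m), 0)  # clipped below limit
  # static baseline never evokes a response
  bl <- baseline_protocol(n_trials = 4L, sampling_rate_hz = 500)
  expect_equal(evoked_amplitude(bl, m), 0)
})

test_that("invalid protocols are rejected", {
  expect_error(stimulus_protocol("grating", pulse_duration_ms = 4,
                                 rep_rate_hz = 1, carrier_freq_hz = 64,
                                 irradiance_mw_mm2 = 2.4, bar_width_um = 60,
                                 sampling_rate_hz = 100),
               "carrier")
  expect_error(stimulus_protocol("full_field", pulse_duration_ms = 10,
                                 rep_rate_hz = 2, irradiance_mw_mm2 = -1),
               "irradiance")
  expect_error(stimulus_protocol("grating", pulse_duration_ms = 4,
                                 rep_rate_hz = 1, carrier_freq_hz = 64,
                                 irradiance_mw_mm2 = 2.4),
               "bar_width")
  expect_error(stimulus_protocol("full_field", pulse_duration_ms = 10,
                                 rep_rate_hz = 2, irradiance_mw_mm2 = 1,
                                 epoch_duration_s = 2),
               "tile")
  expect_error(simulate_ladder(list(), response_model(), 1), "empty")
})

test_that("template is biphasic, unit peak-to-peak, and dies out within the epoch", {
  m <- response_model()
  t_s <- seq(0, 0.5, by = 5e-4)
  w <- vep_template(t_s, m)
  expect_equal(max(w) - min(w), 1, tolerance = 1e-3)
  expect_lt(max(abs(w[t_s > 0.4])), 1e-3)     # finite duration
  expect_lt(which.min(w), which.max(w))       # negative lobe leads
})
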