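# independent oracle: explicit transform, zero the notched bins, invert
zero_notch_oracle <- function(v, fs, fc = 64, hw = 1) {
  n <- length(v)
  X <- fft(v)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency
  kill <- vapply(f, function(fi)
    any(abs(fi - fc * seq_len(floor(fs / 2 / fc))) <= hw), logical(1))
  X[kill] <- 0
  Re(fft(X, inverse = TRUE) / n)
}

notch_mask <- function(n, fs, fc = 64, hw = 1) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  vapply(f, function(fi)
    any(abs(fi - fc * seq_len(floor(fs / 2 / fc))) <= hw), logical(1))
}

test_that("traces with no power in the notched bins pass through unchanged", {
  fs <- 500
  t_s <- (0:499) / fs
  v <- 3 + 2 * sin(2 * pi * 5 * t_s) - cos(2 * pi * 20 * t_s)
  avg <- flat_avg(v, fs)
  out <- reconstruct_spectrum(avg, filter_spec(64))
  expect_lt(sqrt(mean((out$voltage - v)^2)), 1e-9)
  expect_true(out$filtered)
})

test_that("a pure 64 Hz carrier is suppressed by at least 20 dB", {
  fs <- 2000
  t_s <- (0:1999) / fs
  v <- sin(2 * pi * 64 * t_s)                 # RMS 0.707 uV
  out <- reconstruct_spectrum(flat_avg(v, fs), filter_spec(64))
  expect_lte(sqrt(mean(out$voltage^2)), 0.07)
  # matches the zero-the-bins oracle closely (interpolation from clean
  # bins of an otherwise silent spectrum reconstructs ~nothing)
  oracle <- zero_notch_oracle(v, fs)
  expect_lt(sqrt(mean((out$voltage - oracle)^2)), 0.01)
})

test_that("removing a gated carrier leaves the evoked template nearly intact", {
  p <- fast_grating(117, n_trials = 1L, sampling_rate_hz = 2000)
  clean <- quiet_model(slope_uV = 40)
  dirty <- response_model(slope_uV = 40, carrier_amp_uV = 20, noise_sd_uV = 0)
  ref <- average_epochs(simulate_epochs(p, clean, 1))
  contaminated <- average_epochs(simulate_epochs(p, dirty, 1))
  out <- reconstruct_spectrum(contaminated, filter_spec(64))
  expect_equal(peak_to_peak(out), peak_to_peak(ref), tolerance = 0.05)
})

test_that("spectra of input and output agree exactly outside the notches", {
  fs <- 500
  set.seed(42)
  v <- rnorm(500)
  out <- reconstruct_spectrum(flat_avg(v, fs), filter_spec(64))
  keep <- !notch_mask(500, fs)
  expect_equal(fft(out$voltage)[keep], fft(v)[keep], tolerance = 1e-12)
})

test_that("the filter is linear and idempotent", {
  fs <- 500
  set.seed(7)
  x <- rnorm(500); y <- rnorm(500)
  fspec <- filter_spec(64)
  filt <- function(v) reconstruct_spectrum(flat_avg(v, fs), fspec)$voltage
  expect_equal(filt(2 * x - 3 * y), 2 * filt(x) - 3 * filt(y),
               tolerance = 1e-12)
  once <- filt(x)
  twice <- filt(once)
  expect_lt(sqrt(mean((twice - once)^2)), 1e-6)
})

test_that("degenerate filter requests are rejected", {
  fs <- 500
  v <- rnorm(100)
  # 1 Hz carrier with 1 Hz half-width notches every positive bin
  expect_error(reconstruct_spectrum(flat_avg(v, fs), filter_spec(1)),
               "entire spectrum")
  avg <- reconstruct_spectrum(flat_avg(v, fs), filter_spec(64))
  expect_error(reconstruct_spectrum(avg, filter_spec(64)), "already")
  expect_error(reconstruct_spectrum(flat_avg(v, fs), filter_spec(300)),
               "Nyquist")
})

test_that("averaging is the pointwise mean and rejects ragged input", {
  p <- fast_grating(n_trials = 3L)
  m <- quiet_model()
  ep <- simulate_epochs(p, m, 1)
  x <- sin(2 * pi * 3 * ep$times)
  ep$traces <- rbind(x, x, x)
  expect_equal(average_epochs(ep)$voltage, x)
  ep$traces <- rbind(x, -x)
  expect_equal(average_epochs(ep)$voltage, rep(0, length(x)))
  # brute-force elementwise oracle on random traces
  set.seed(3)
  ep$traces <- matrix(rnorm(50 * length(ep$times)), nrow = 50)
  manual <- apply(ep$traces, 2, mean)
  expect_equal(average_epochs(ep)$voltage, manual, tolerance = 1e-15)
  ep$traces <- ep$traces[, -1]
  expect_error(average_epochs(ep), "ragged")
})
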