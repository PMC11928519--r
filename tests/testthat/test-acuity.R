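zero_noise <- function() estimate_noise(c(0, 0, 0))

test_that("an exact log-line is recovered with zero residual", {
  w <- c(10, 100, 1000)
  gr <- grating_response(w, 3 * log(w) + 2, zero_noise())
  fit <- fit_log_linear(gr)
  expect_equal(fit$a, 3, tolerance = 1e-10)
  expect_equal(fit$b, 2, tolerance = 1e-10)
  expect_equal(max(abs(fit$cov)), 0, tolerance = 1e-12)
  expect_identical(fit$n_points, 3L)
})

test_that("OLS matches pencil-and-paper normal equations on 3 noisy points", {
  w <- c(20, 50, 110)
  y <- c(9.1, 21.4, 30.2)
  x <- log(w)
  # hand solution: a = Sxy/Sxx, b = ybar - a xbar; cov = s2 * (X'X)^-1
  Sxx <- sum((x - mean(x))^2)
  Sxy <- sum((x - mean(x)) * (y - mean(y)))
  a_hand <- Sxy / Sxx
  b_hand <- mean(y) - a_hand * mean(x)
  res <- y - (a_hand * x + b_hand)
  s2 <- sum(res^2) / (3 - 2)
  var_a <- s2 / Sxx
  var_b <- s2 * (1 / 3 + mean(x)^2 / Sxx)
  cov_ab <- -s2 * mean(x) / Sxx

  fit <- fit_log_linear(grating_response(w, y, zero_noise()))
  expect_equal(fit$a, a_hand, tolerance = 1e-12)
  expect_equal(fit$b, b_hand, tolerance = 1e-12)
  expect_equal(fit$cov[1, 1], var_a, tolerance = 1e-10)
  expect_equal(fit$cov[2, 2], var_b, tolerance = 1e-10)
  expect_equal(fit$cov[1, 2], cov_ab, tolerance = 1e-10)
})

test_that("degenerate grating tables are not estimable", {
  nm <- estimate_noise(c(5, 5, 5))
  expect_error(fit_log_linear(grating_response(c(10, 20, 30), c(1, 2, 9), nm)),
               "not estimable")
  gr <- grating_response(c(10, 20, 30), c(6, 7, 9), nm)
  expect_error(fit_log_linear(gr, min_points = 4), "not estimable")
})

test_that("the acuity limit solves exp((N - b)/a) and matches a grid scan", {
  expect_equal(acuity_limit(loglinear_fit(1, 0, diag(2) * 0), noise = 0), 1)
  N28 <- 2 + 3 * log(28)
  expect_equal(acuity_limit(loglinear_fit(3, 2, diag(2) * 0), noise = N28), 28)

  # grid-scan oracle: sign change of a*ln(w) + b - N over w in [1, 200]
  set.seed(61)
  for (i in 1:5) {
    a <- runif(1, 1, 10); b <- runif(1, -5, 5)
    N <- b + a * log(runif(1, 2, 150))
    grid <- seq(1, 200, by = 0.001)
    sgn <- sign(a * log(grid) + b - N)
    cross <- grid[which(diff(sgn) != 0)[1]]
    expect_lt(abs(acuity_limit(loglinear_fit(a, b, diag(2) * 0), N) - cross),
              0.001 + 1e-9)
  }

  expect_error(acuity_limit(loglinear_fit(-1, 0, diag(2) * 0), 0),
               "not estimable")
})

test_that("delta method reproduces the hand-computed case exactly", {
  fit <- loglinear_fit(a = 1, b = 0, cov = diag(c(0.01, 0.01)))
  est <- acuity_ci(fit, noise = 0)
  expect_equal(est$w_star_um, 1)
  expect_equal(unname(est$gradient), c(0, -1, 1))
  expect_equal(est$sd_um, 0.1)
  expect_equal(est$ci_low_um, 1 - 1.92 * 0.1)
  expect_equal(est$ci_high_um, 1 + 1.92 * 0.1)

  # all variances zero -> the interval collapses onto the point estimate
  est0 <- acuity_ci(loglinear_fit(2, 1, matrix(0, 2, 2)), noise = 5)
  expect_equal(est0$sd_um, 0)
  expect_equal(est0$ci_low_um, est0$w_star_um)
  expect_equal(est0$ci_high_um, est0$w_star_um)
})

test_that("the interval is symmetric with half-width z * sd", {
  fit <- loglinear_fit(3, 2, matrix(c(0.04, -0.01, -0.01, 0.09), 2, 2))
  est <- acuity_ci(fit, noise = 12, z = 1.92)
  expect_equal(est$ci_high_um - est$w_star_um, 1.92 * est$sd_um)
  expect_equal(est$w_star_um - est$ci_low_um, 1.92 * est$sd_um)
  wide <- acuity_ci(fit, noise = 12, z = 2.5)
  expect_equal(wide$ci_high_um - wide$w_star_um, 2.5 * wide$sd_um)
})

test_that("acuity is scale-equivariant in the width units", {
  set.seed(9)
  w <- c(15, 25, 40, 70, 115)
  y <- 8 + 30 * log(w / 20) + rnorm(5, sd = 0.5)
  nm <- estimate_noise(c(6, 7, 6.5, 7.2))
  w1 <- acuity_limit(fit_log_linear(grating_response(w, y, nm)), nm)
  w2 <- acuity_limit(fit_log_linear(grating_response(3 * w, y, nm)), nm)
  expect_equal(w2, 3 * w1, tolerance = 1e-9)
})

test_that("a steeper fit crosses the noise level at a smaller width", {
  prev <- Inf
  for (a in c(1, 2, 4, 8)) {
    w <- acuity_limit(loglinear_fit(a, 1, diag(2) * 0), noise = 6)
    expect_lt(w, prev)
    prev <- w
  }
})

test_that("delta-method sd agrees with a parametric bootstrap at high SNR", {
  skip_if_not_installed("MASS")
  # a well-determined fit (SNR >= 5): simulated cohort grating study
  scn <- study_scenario(include_fullfield = FALSE)
  r <- run_pipeline(scn, analysis_config(simulate_averages = TRUE), seed = 77)
  fit <- r$fit; nm <- r$noise
  est <- acuity_ci(fit, nm)
  set.seed(123)
  ab <- MASS::mvrnorm(1e4, mu = c(fit$a, fit$b), Sigma = fit$cov)
  Nd <- rnorm(1e4, mean = nm$mean_amp, sd = sqrt(nm$var_N))
  boot <- exp((Nd - ab[, 2]) / ab[, 1])
  expect_equal(est$sd_um, sd(boot), tolerance = 0.15)
})

test_that("the fitted slope recovers the generative slope across replicates", {
  scn <- study_scenario(include_fullfield = FALSE)
  cfg <- analysis_config(simulate_averages = TRUE)
  slopes <- vapply(1:100, function(i)
    run_pipeline(scn, cfg, seed = 40000 + i)$fit$a, numeric(1))
  expect_equal(mean(slopes), scn$model$slope_uV, tolerance = 0.1)
})

test_that("extrapolation beyond the tested widths is flagged", {
  nm <- estimate_noise(c(2, 2.5, 2.2))
  w <- c(30, 50, 80, 120)
  y <- 40 + 25 * log(w / 30)
  fit <- fit_log_linear(grating_response(w, y, nm))
  est <- acuity_ci(fit, nm)             # crossing far below 30 um
  expect_true(est$extrapolated)
  expect_lt(est$w_star_um, 30)
})
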