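#' Grating response table
#'
#' @param bar_widths_um Strictly increasing grating bar widths, um.
#' @param amplitudes_uV Peak-to-peak VEP amplitudes, uV, same length.
#' @param noise A [estimate_noise()] result.
#' @return An object of class `"grating_response"`.
#' @export
grating_response <- function(bar_widths_um, amplitudes_uV, noise) {
  stopifnot(inherits(noise, "noise_model"),
            length(bar_widths_um) == length(amplitudes_uV))
  if (any(bar_widths_um <= 0)) stop("bar widths must be positive")
  if (is.unsorted(bar_widths_um, strictly = TRUE)) {
    stop("bar widths must be strictly increasing")
  }
  structure(list(bar_widths_um = as.numeric(bar_widths_um),
                 amplitudes_uV = as.numeric(amplitudes_uV), noise = noise),
            class = "grating_response")
}

#' Construct a log-linear fit object
#'
#' Container for a fit of VEP amplitude against the natural logarithm of the
#' grating bar width: `amplitude = a * ln(width) + b`. Normally produced by
#' [fit_log_linear()]; the constructor is exported so fits with known
#' parameters can be built directly.
#'
#' @param a Slope, uV per ln-um.
#' @param b Intercept, uV.
#' @param cov 2x2 symmetric covariance matrix of `(a, b)`.
#' @param n_points Number of points entering the fit.
#' @param included_mask Logical mask of included points (optional).
#' @param width_range_um Range of tested bar widths, um (optional; used to
#'   flag extrapolated acuity estimates).
#' @param lm_fit The underlying [stats::lm] object (optional).
#' @return An object of class `"loglinear_fit"`.
#' @export
loglinear_fit <- function(a, b, cov, n_points = NA_integer_,
                          included_mask = NULL, width_range_um = NULL,
                          lm_fit = NULL) {
  stopifnot(is.finite(a), is.finite(b), is.matrix(cov),
            all(dim(cov) == c(2, 2)))
  if (max(abs(cov - t(cov))) > 1e-8 * (1 + max(abs(cov)))) {
    stop("covariance matrix must be symmetric")
  }
  dimnames(cov) <- list(c("a", "b"), c("a", "b"))
  structure(list(a = a, b = b, cov = cov,
                 n_points = as.integer(n_points),
                 included_mask = included_mask,
                 width_range_um = width_range_um, lm_fit = lm_fit),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat("<loglinear_fit> amplitude =", signif(x$a, 4), "* ln(width) +",
      signif(x$b, 4), " (", x$n_points, "points )\n")
  invisible(x)
}

#' Fit VEP amplitude against log bar width
#'
#' Ordinary least squares of peak-to-peak amplitude on the natural logarithm
#' of the bar width, restricted to data points above the noise level (points
#' whose amplitude exceeds `noise$upper95`). At least three supra-noise
#' points are required for a non-singular parameter covariance. The
#' covariance matrix is the usual residual-variance-scaled inverse
#' normal-equations matrix reported by [stats::vcov].
#'
#' By default (`include = "contiguous"`) only the contiguous supra-noise run
#' ending at the widest grating is fitted: a response that is genuinely
#' resolvable at some bar width is resolvable at every larger one, so an
#' isolated supra-noise point surrounded by sub-noise widths is a noise
#' excursion, not a response — the same persistence reasoning
#' [estimate_threshold()] applies to the irradiance ladder.
#' `include = "all_supra"` fits every supra-noise point.
#'
#' @param gr A [grating_response()].
#' @param min_points Minimum number of supra-noise points (default 3).
#' @param include Point-inclusion rule, `"contiguous"` (default) or
#'   `"all_supra"`.
#' @return A [loglinear_fit()] with slope `a` (uV per ln-um), intercept `b`
#'   (uV) and covariance ordered `(a, b)`.
#' @export
fit_log_linear <- function(gr, min_points = 3L,
                           include = c("contiguous", "all_supra")) {
  stopifnot(inherits(gr, "grating_response"))
  include <- match.arg(include)
  inc <- gr$amplitudes_uV > gr$noise$upper95
  if (include == "contiguous") inc <- rev(cumprod(rev(inc))) == 1
  if (sum(inc) < min_points) {
    stop("not estimable: only ", sum(inc), " data points above the noise ",
         "level (need at least ", min_points, ")")
  }
  w <- gr$bar_widths_um[inc]
  if (length(unique(w)) < 2L) {
    stop("not estimable: included bar widths are all equal, ",
         "normal equations are singular")
  }
  df <- data.frame(lw = log(w), amp = gr$amplitudes_uV[inc])
  fit <- stats::lm(amp ~ lw, data = df)
  co <- stats::coef(fit)
  # an exactly collinear table (zero residual) is legitimate input; the
  # zero covariance it yields is the right answer, not a defect
  V <- withCallingHandlers(
    stats::vcov(fit)[c("lw", "(Intercept)"), c("lw", "(Intercept)")],
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  loglinear_fit(a = unname(co["lw"]), b = unname(co["(Intercept)"]),
                cov = unname(V), n_points = sum(inc), included_mask = inc,
                width_range_um = range(gr$bar_widths_um), lm_fit = fit)
}

# Resolve the noise level N and its variance for the intersection.
# `noise` may be a noise_model or a bare numeric level (variance 0).
.noise_level <- function(noise, level = c("mean", "upper95")) {
  level <- match.arg(level)
  if (inherits(noise, "noise_model")) {
    list(N = switch(level, mean = noise$mean_amp, upper95 = noise$upper95),
         var_N = noise$var_N)
  } else if (is.numeric(noise) && length(noise) == 1L) {
    list(N = noise, var_N = 0)
  } else {
    stop("noise must be a noise_model or a single numeric level")
  }
}

#' Grating acuity limit: intersection of the fit with the noise level
#'
#' The acuity limit is the bar width at which the log-linear amplitude fit
#' crosses the baseline noise level:
#' `w* = exp((N - b) / a)`.
#' The level `N` defaults to the *mean* baseline amplitude (the noise level
#' drawn as the dashed line in grating dose-response plots);
#' `level = "upper95"` intersects with the significance bound instead.
#'
#' @param fit A [loglinear_fit()] with positive slope.
#' @param noise A [estimate_noise()] result, or a bare numeric noise level.
#' @param level Which baseline level to intersect, `"mean"` (default) or
#'   `"upper95"`.
#' @return Acuity limit `w*`, um.
#' @export
acuity_limit <- function(fit, noise, level = c("mean", "upper95")) {
  stopifnot(inherits(fit, "loglinear_fit"))
  if (fit$a <= 0) {
    stop("not estimable: fitted slope is not positive, no ascending fit ",
         "to intersect with the noise level")
  }
  nl <- .noise_level(noise, level)
  exp((nl$N - fit$b) / fit$a)
}

#' Acuity limit with a delta-method confidence interval
#'
#' Propagates the fit-parameter covariance and the noise-level variance
#' through `w* = exp((N - b)/a)` to first order. With gradient
#' `g = w* * (-(N - b)/a^2, -1/a, 1/a)` with respect to `(a, b, N)`,
#' `Var(w*) = g_a^2 Var(a) + g_b^2 Var(b) + 2 g_a g_b Cov(a,b)
#'            + g_N^2 var_N`,
#' and the confidence interval is `w* -/+ z * sd`. The multiplier defaults
#' to `z = 1.92` for a normal-approximation 95% interval.
#'
#' @inheritParams acuity_limit
#' @param z Confidence-interval multiplier (default 1.92).
#' @return An object of class `"acuity_estimate"` with fields `w_star_um`,
#'   `sd_um`, `ci_low_um`, `ci_high_um`, `z`, `level` and `extrapolated`
#'   (`TRUE` when `w*` falls outside the tested width range).
#' @examples
#' f <- loglinear_fit(a = 1, b = 0, cov = diag(c(0.01, 0.01)))
#' acuity_ci(f, noise = 0)  # w* = 1, sd = 0.1, CI [0.808, 1.192]
#' @export
acuity_ci <- function(fit, noise, z = 1.92, level = c("mean", "upper95")) {
  stopifnot(z > 0)
  level <- match.arg(level)
  w_star <- acuity_limit(fit, noise, level)
  nl <- .noise_level(noise, level)
  a <- fit$a; b <- fit$b; N <- nl$N
  g_a <- w_star * (-(N - b) / a^2)
  g_b <- w_star * (-1 / a)
  g_N <- w_star * (1 / a)
  var_w <- g_a^2 * fit$cov[1, 1] + g_b^2 * fit$cov[2, 2] +
    2 * g_a * g_b * fit$cov[1, 2] + g_N^2 * nl$var_N
  sd_w <- sqrt(max(0, var_w))
  extrap <- if (is.null(fit$width_range_um)) NA else {
    w_star < min(fit$width_range_um) || w_star > max(fit$width_range_um)
  }
  structure(list(w_star_um = w_star, sd_um = sd_w,
                 ci_low_um = w_star - z * sd_w,
                 ci_high_um = w_star + z * sd_w,
                 z = z, level = level, extrapolated = extrap,
                 gradient = c(a = g_a, b = g_b, N = g_N)),
            class = "acuity_estimate")
}

#' @export
print.acuity_estimate <- function(x, ...) {
  cat("<acuity_estimate> w* =", signif(x$w_star_um, 4), "um, sd",
      signif(x$sd_um, 3), "um, ", sprintf("%.2f", x$z), "*sd CI [",
      signif(x$ci_low_um, 4), ",", signif(x$ci_high_um, 4), "] um",
      if (isTRUE(x$extrapolated)) "(extrapolated)", "\n")
  invisible(x)
}
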