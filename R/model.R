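#' Generative response model for synthetic VEP recordings
#'
#' Parametrises the deterministic and stochastic structure of a simulated
#' recording:
#'
#' * a fixed biphasic cortical template (difference of two gamma-density
#'   lobes: a negative lobe peaking at `t1_ms` and a broader positive lobe at
#'   `t2_ms`, normalised to unit peak-to-peak amplitude);
#' * a full-field amplitude law, the sigmoid
#'   `A(E) = amax * E^h / (e50^h + E^h)` in uV as a function of retinal
#'   irradiance `E` (mW/mm^2);
#' * a grating amplitude law,
#'   `A(w) = max(0, grating_offset + slope * ln(w / w_true))`,
#'   zero at and below the true acuity limit `w_true_um` when
#'   `grating_offset_uV = 0` (the default);
#' * a carrier stimulus artifact: a sinusoid at the protocol's carrier
#'   frequency plus second and third harmonics at -12 dB, present throughout
#'   the pulse train;
#' * independent white Gaussian noise per trial with SD `noise_sd_uV`.
#'
#' `grating_offset_uV` anchors the evoked amplitude at `w_true_um`. Leaving
#' it at 0 reproduces the plain logarithmic law; setting it to the expected
#' peak-to-peak noise floor (see [noise_floor_p2p()]) makes the analysis-side
#' log-linear model cross the noise level exactly at `w_true_um`, which is
#' how [study_scenario()] configures it.
#'
#' @param t1_ms,t2_ms Latencies of the negative and positive template lobes,
#'   ms.
#' @param lobe_shape Gamma shape parameter of both lobes (>1).
#' @param amax_uV,e50_mw_mm2,hill Sigmoid full-field law: saturation
#'   amplitude (uV), half-saturation irradiance (mW/mm^2) and Hill slope.
#' @param slope_uV Grating-law slope, uV per natural-log-um.
#' @param w_true_um True acuity limit of the generative model, um.
#' @param grating_offset_uV Evoked amplitude at `w_true_um`, uV.
#' @param carrier_amp_uV Carrier artifact amplitude, uV (deterministic, so it
#'   survives trial averaging at full amplitude).
#' @param noise_sd_uV Per-trial white Gaussian noise SD, uV.
#' @return An object of class `"response_model"`.
#' @export
response_model <- function(t1_ms = 40, t2_ms = 80, lobe_shape = 4,
                           amax_uV = 120, e50_mw_mm2 = 0.3, hill = 1.5,
                           slope_uV = 40, w_true_um = 28,
                           grating_offset_uV = 0,
                           carrier_amp_uV = 20, noise_sd_uV = 25) {
  stopifnot(t1_ms > 0, t2_ms > t1_ms, lobe_shape > 1,
            amax_uV >= 0, e50_mw_mm2 > 0, hill > 0,
            slope_uV >= 0, w_true_um > 0, grating_offset_uV >= 0,
            carrier_amp_uV >= 0, noise_sd_uV >= 0)
  structure(list(t1_ms = t1_ms, t2_ms = t2_ms, lobe_shape = lobe_shape,
                 amax_uV = amax_uV, e50_mw_mm2 = e50_mw_mm2, hill = hill,
                 slope_uV = slope_uV, w_true_um = w_true_um,
                 grating_offset_uV = grating_offset_uV,
                 carrier_amp_uV = carrier_amp_uV, noise_sd_uV = noise_sd_uV),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat("<response_model>\n")
  cat("  template: lobes at", x$t1_ms, "/", x$t2_ms, "ms (gamma shape",
      x$lobe_shape, ")\n")
  cat("  full-field: Amax", x$amax_uV, "uV, E50", x$e50_mw_mm2,
      "mW/mm^2, Hill", x$hill, "\n")
  cat("  grating: slope", x$slope_uV, "uV/ln-um, w_true", x$w_true_um,
      "um, offset", x$grating_offset_uV, "uV\n")
  cat("  carrier artifact", x$carrier_amp_uV, "uV; per-trial noise SD",
      x$noise_sd_uV, "uV\n")
  invisible(x)
}

# Unnormalised biphasic waveform. Each lobe is a gamma density whose mode is
# placed at the requested latency (scale = mode / (shape - 1)).
.template_raw <- function(t_s, model) {
  k <- model$lobe_shape
  s1 <- (model$t1_ms / 1000) / (k - 1)
  s2 <- (model$t2_ms / 1000) / (k - 1)
  g1 <- stats::dgamma(t_s, shape = k, scale = s1)
  g2 <- stats::dgamma(t_s, shape = k, scale = s2)
  # unit-peak lobes, negative N1 followed by positive P2
  p1 <- stats::dgamma((k - 1) * s1, shape = k, scale = s1)
  p2 <- stats::dgamma((k - 1) * s2, shape = k, scale = s2)
  -g1 / p1 + g2 / p2
}

#' Evaluate the biphasic VEP template
#'
#' The template is normalised so its continuous peak-to-peak amplitude is 1
#' (normalisation computed on a fine internal grid, independent of the
#' requested sample times). Scaling it by an amplitude in uV therefore yields
#' a waveform whose noise-free peak-to-peak amplitude equals that amplitude.
#'
#' @param t_s Times in seconds (epoch onset at 0).
#' @param model A [response_model()].
#' @return Numeric vector of template values (unitless, unit peak-to-peak).
#' @export
vep_template <- function(t_s, model) {
  fine <- seq(0, max(0.4, model$t2_ms / 1000 * 4), length.out = 8192)
  ref <- .template_raw(fine, model)
  p2p <- max(ref) - min(ref)
  if (p2p == 0) return(rep(0, length(t_s)))
  .template_raw(t_s, model) / p2p
}

#' Deterministic evoked amplitude implied by a protocol
#'
#' Evaluates the model's amplitude law for a stimulus condition: the sigmoid
#' irradiance law for full-field protocols, the logarithmic bar-width law for
#' gratings, and 0 for the static-grating baseline.
#'
#' @param protocol A [stimulus_protocol()].
#' @param model A [response_model()].
#' @return Peak-to-peak evoked amplitude, uV.
#' @export
evoked_amplitude <- function(protocol, model) {
  switch(protocol$mode,
    full_field = {
      E <- protocol$irradiance_mw_mm2
      model$amax_uV * E^model$hill /
        (model$e50_mw_mm2^model$hill + E^model$hill)
    },
    grating = {
      if (!is.null(model$grating_cal)) {
        cal <- model$grating_cal
        pmax(0, stats::approx(x = log(cal$bar_width_um), y = cal$evoked_uV,
                              xout = log(protocol$bar_width_um),
                              rule = 2)$y)
      } else {
        max(0, model$grating_offset_uV +
               model$slope_uV * log(protocol$bar_width_um / model$w_true_um))
      }
    },
    static_grating_baseline = 0)
}

#' Expected peak-to-peak amplitude of the averaged noise floor
#'
#' Closed-form extreme-value approximation to the expected peak-to-peak
#' amplitude of white Gaussian noise after trial averaging, over a response
#' window of `m` samples: `2 * sigma_avg * E[max of m standard normals]`,
#' with `sigma_avg = noise_sd_uV / sqrt(n_trials)` and the classical
#' Cramer expansion `E[max_m] ~ b - (ln ln m + ln 4*pi)/(2b) + gamma/b`,
#' `b = sqrt(2 ln m)`.
#'
#' This is the level a peak-to-peak measurement of a response-free recording
#' converges to; [study_scenario()] uses it to anchor the generative grating
#' law at the noise floor.
#'
#' @param noise_sd_uV Per-trial noise SD, uV.
#' @param n_trials Number of averaged trials.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param window Response window `c(start, end)` in seconds.
#' @return Expected peak-to-peak noise amplitude, uV.
#' @export
noise_floor_p2p <- function(noise_sd_uV, n_trials, sampling_rate_hz = 2000,
                            window = c(0.01, 0.3)) {
  stopifnot(noise_sd_uV >= 0, n_trials >= 1, diff(window) > 0)
  m <- max(2, floor(diff(window) * sampling_rate_hz) + 1)
  sigma <- noise_sd_uV / sqrt(n_trials)
  b <- sqrt(2 * log(m))
  emax <- b - (log(log(m)) + log(4 * pi)) / (2 * b) + 0.5772156649 / b
  2 * sigma * emax
}
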