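#' Peak-to-peak amplitude over a response window
#'
#' `max(voltage) - min(voltage)` over all samples with
#' `window[1] <= t <= window[2]`. The default window, 10-300 ms after
#' stimulus onset, brackets both lobes of the cortical response while
#' excluding the onset sample.
#'
#' @param avg An `"averaged_vep"`.
#' @param window Response window `c(start, end)`, seconds.
#' @return Peak-to-peak amplitude, uV (non-negative scalar).
#' @export
peak_to_peak <- function(avg, window = c(0.01, 0.3)) {
  stopifnot(inherits(avg, "averaged_vep"), length(window) == 2)
  if (window[2] <= window[1]) stop("empty response window")
  sel <- avg$times >= window[1] & avg$times <= window[2]
  if (!any(sel)) stop("empty response window: no samples between ",
                      window[1], " and ", window[2], " s")
  v <- avg$voltage[sel]
  max(v) - min(v)
}

#' Characterise the noise baseline
#'
#' Summarises peak-to-peak amplitudes measured under the response-free
#' baseline condition (a static grating). The "noise level" used downstream
#' is `mean_amp`; the significance bound `upper95` is, by default, the upper
#' 95% bound of the amplitude *distribution*, `mean + 1.96 * sd` — a single
#' averaged response must exceed plausible noise excursions, not merely the
#' mean's uncertainty. `mode = "sem"` gives the alternative bound on the
#' mean, `mean + 1.96 * sd / sqrt(n)`.
#'
#' `var_N = sd^2 / n` is the variance of the estimated noise level (the
#' mean), which is what the delta method for the acuity limit consumes.
#'
#' @param baseline_amps At least two baseline peak-to-peak amplitudes, uV.
#' @param mode Significance-bound convention, `"distribution"` (default) or
#'   `"sem"`.
#' @param source Free-text description of the baseline condition.
#' @return An object of class `"noise_model"` with fields `mean_amp`,
#'   `sd_amp`, `upper95`, `var_N`, `n_baseline`, `mode`, `source`.
#' @examples
#' estimate_noise(c(1, 3))  # mean 2, sd sqrt(2), upper95 4.772
#' @export
estimate_noise <- function(baseline_amps, mode = c("distribution", "sem"),
                           source = "static grating baseline") {
  mode <- match.arg(mode)
  baseline_amps <- as.numeric(baseline_amps)
  n <- length(baseline_amps)
  if (n < 2) stop("need at least 2 baseline amplitudes to estimate noise")
  m <- mean(baseline_amps)
  s <- stats::sd(baseline_amps)
  upper <- switch(mode,
                  distribution = m + 1.96 * s,
                  sem = m + 1.96 * s / sqrt(n))
  structure(list(mean_amp = m, sd_amp = s, upper95 = upper,
                 var_N = s^2 / n, n_baseline = n, mode = mode,
                 source = source),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model> mean", signif(x$mean_amp, 4), "uV, sd",
      signif(x$sd_amp, 4), "uV, upper95", signif(x$upper95, 4),
      "uV (", x$mode, ", n =", x$n_baseline, ")\n")
  invisible(x)
}

#' Dose-response table for full-field stimulation
#'
#' @param irradiances_mw_mm2 Strictly increasing retinal irradiances,
#'   mW/mm^2.
#' @param amplitudes_uV Peak-to-peak VEP amplitudes, uV, same length.
#' @param noise A [estimate_noise()] result.
#' @return An object of class `"dose_response"`.
#' @export
dose_response <- function(irradiances_mw_mm2, amplitudes_uV, noise) {
  stopifnot(inherits(noise, "noise_model"),
            length(irradiances_mw_mm2) == length(amplitudes_uV))
  if (any(irradiances_mw_mm2 <= 0)) stop("irradiances must be positive")
  if (is.unsorted(irradiances_mw_mm2, strictly = TRUE)) {
    stop("irradiances must be strictly increasing")
  }
  structure(list(irradiances_mw_mm2 = as.numeric(irradiances_mw_mm2),
                 amplitudes_uV = as.numeric(amplitudes_uV), noise = noise),
            class = "dose_response")
}

#' Detect the stimulation threshold on an irradiance ladder
#'
#' The stimulation threshold is the lowest irradiance whose VEP amplitude
#' exceeds the noise significance bound (`noise$upper95`) *and* from which
#' every higher irradiance also exceeds it — the persistence requirement
#' guards against single-step flukes. The threshold is always a ladder
#' member; no interpolation is performed. `NA` when no irradiance qualifies.
#'
#' @param dr A [dose_response()].
#' @return An object of class `"threshold_estimate"` with fields
#'   `threshold_mw_mm2` (`NA` if absent), `supra_noise_mask`, `rule`,
#'   `irradiances_mw_mm2`.
#' @export
estimate_threshold <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  mask <- dr$amplitudes_uV > dr$noise$upper95
  persistent <- rev(cumprod(rev(mask))) == 1
  thr <- if (any(persistent)) {
    dr$irradiances_mw_mm2[which(persistent)[1]]
  } else {
    NA_real_
  }
  structure(list(threshold_mw_mm2 = thr, supra_noise_mask = mask,
                 rule = paste("lowest irradiance exceeding the noise upper",
                              "95% bound, with all higher irradiances also",
                              "exceeding it"),
                 irradiances_mw_mm2 = dr$irradiances_mw_mm2),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (is.na(x$threshold_mw_mm2)) {
    cat("<threshold_estimate> absent: no irradiance exceeds the noise bound\n")
  } else {
    cat("<threshold_estimate>", signif(x$threshold_mw_mm2, 3), "mW/mm^2\n")
  }
  invisible(x)
}
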