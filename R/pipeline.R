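#' Assemble a simulation scenario
#'
#' A scenario is a cohort experiment: every stimulation condition (each
#' irradiance step, each bar width, and the baseline) is recorded once per
#' subject, amplitudes are averaged across subjects per condition (the
#' group-mean curves with SEM error bars typical of cohort VEP studies), and
#' the noise model is estimated from the per-subject baseline amplitudes.
#'
#' @param model A [response_model()].
#' @param fullfield Optional list of full-field [stimulus_protocol()]s
#'   (increasing irradiance).
#' @param gratings Optional list of grating protocols (increasing bar
#'   width).
#' @param baseline A single baseline [stimulus_protocol()] (response-free
#'   condition used to characterise the noise).
#' @param n_subjects Number of subjects in the cohort (at least 2, so the
#'   baseline amplitude spread is estimable).
#' @return A `"vep_scenario"`.
#' @export
scenario <- function(model, fullfield = NULL, gratings = NULL,
                     baseline = baseline_protocol(), n_subjects = 7L) {
  stopifnot(inherits(model, "response_model"),
            inherits(baseline, "stim_protocol"))
  if (is.null(fullfield) && is.null(gratings)) {
    stop("scenario needs at least one of: fullfield ladder, grating ladder")
  }
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) {
    stop("scenario needs at least 2 subjects to estimate the noise spread")
  }
  structure(list(model = model, fullfield = fullfield, gratings = gratings,
                 baseline = baseline, n_subjects = n_subjects),
            class = "vep_scenario")
}

#' The default in-vivo study scenario
#'
#' Reproduces the stimulation conditions of the in-vivo measurements this
#' package analyses: a full-field irradiance ladder (10 ms pulses at 2 Hz,
#' 0.002-4.7 mW/mm^2), an alternating-grating bar-width ladder (4 ms pulses
#' on a 64 Hz carrier, 1 Hz alternation, 2.4 mW/mm^2, 13-117 um), a static
#' 120 um grating as noise baseline, all sampled at 2 kHz and averaged over
#' 500 trials.
#'
#' The generative grating law is calibrated so that the analysis-side model
#' is exactly true: per ladder width, the evoked amplitude is solved such
#' that the *expected measured* peak-to-peak amplitude (after trial
#' averaging, carrier filtering and windowed peak-to-peak extraction, whose
#' noise excursions inflate any measured amplitude) equals
#' `noise floor + slope * ln(w / w_true)`. The fitted log-linear amplitude
#' line then crosses the estimated noise level at `w_true_um`, making the
#' acuity estimator consistent for the generative acuity limit. The
#' calibration is a Monte-Carlo solve under a fixed internal seed, so it is
#' deterministic and cached.
#'
#' @param model Base [response_model()].
#' @param include_fullfield,include_gratings Which arms to include.
#' @param n_subjects Cohort size (default 7 biologically independent
#'   subjects per group).
#' @param n_trials Trials per recording (default 500).
#' @param response_window Response window used by the calibration, seconds.
#' @param anchor_grating_law Calibrate the grating law against the measured
#'   noise floor (default `TRUE`); if `FALSE` the model's plain logarithmic
#'   law is used unchanged.
#' @return A `"vep_scenario"`.
#' @export
study_scenario <- function(model = response_model(),
                           include_fullfield = TRUE,
                           include_gratings = TRUE,
                           n_subjects = 7L,
                           n_trials = 500L,
                           response_window = c(0.01, 0.3),
                           anchor_grating_law = TRUE) {
  gratings <- if (include_gratings) grating_ladder(n_trials = n_trials)
  if (anchor_grating_law && !is.null(gratings)) {
    model <- .calibrate_grating_model(model, gratings,
                                      window = response_window)
  }
  scenario(model = model,
           fullfield = if (include_fullfield)
             fullfield_ladder(n_trials = n_trials),
           gratings = gratings,
           baseline = baseline_protocol(n_trials = n_trials),
           n_subjects = n_subjects)
}

#' Analysis configuration
#'
#' Collects the analysis conventions in one place: the carrier filter, the
#' peak-to-peak response window, the noise significance-bound convention,
#' the acuity intersection level and CI multiplier, and whether simulated
#' recordings are drawn as full multi-trial epoch sets or directly as trial
#' averages.
#'
#' @param filter A [filter_spec()] for carrier-bearing recordings.
#' @param response_window Peak-to-peak window `c(start, end)`, seconds.
#' @param noise_bound Convention for the significance bound, see
#'   [estimate_noise()].
#' @param z Acuity CI multiplier (default 1.92).
#' @param intersection_level Noise level the acuity fit is intersected with,
#'   see [acuity_limit()].
#' @param simulate_averages If `TRUE`, simulated recordings are drawn with
#'   [simulate_average()] (distributionally identical to full multi-trial
#'   simulation, much faster); default `FALSE` uses [simulate_epochs()].
#' @return An `"analysis_config"`.
#' @export
analysis_config <- function(filter = filter_spec(),
                            response_window = c(0.01, 0.3),
                            noise_bound = c("distribution", "sem"),
                            z = 1.92,
                            intersection_level = c("mean", "upper95"),
                            simulate_averages = FALSE) {
  noise_bound <- match.arg(noise_bound)
  intersection_level <- match.arg(intersection_level)
  stopifnot(inherits(filter, "filter_spec"),
            length(response_window) == 2,
            response_window[2] > response_window[1], z > 0)
  structure(list(filter = filter, response_window = response_window,
                 noise_bound = noise_bound, z = z,
                 intersection_level = intersection_level,
                 simulate_averages = isTRUE(simulate_averages)),
            class = "analysis_config")
}

#' Simulate and measure one stimulation condition
#'
#' The elementary measurement of the pipeline: simulate one recording
#' (full epoch set or direct trial average, per
#' `config$simulate_averages`), average, remove the carrier artifact when
#' the protocol has a carrier, and extract the windowed peak-to-peak
#' amplitude. Averaging many such measurements over seeds yields the
#' *measured* amplitude law of the generative model (the evoked law plus
#' the noise-floor inflation of peak-to-peak extraction), which is the
#' estimand the threshold and acuity estimators recover.
#'
#' @param protocol A [stimulus_protocol()].
#' @param model A [response_model()].
#' @param seed Integer seed.
#' @param config An [analysis_config()].
#' @return Peak-to-peak amplitude, uV.
#' @export
condition_amplitude <- function(protocol, model, seed,
                                config = analysis_config()) {
  avg <- if (config$simulate_averages) {
    simulate_average(protocol, model, seed)
  } else {
    average_epochs(simulate_epochs(protocol, model, seed))
  }
  if (!is.null(protocol$carrier_freq_hz)) {
    fspec <- config$filter
    fspec$carrier_freq_hz <- protocol$carrier_freq_hz
    avg <- reconstruct_spectrum(avg, fspec)
  }
  peak_to_peak(avg, config$response_window)
}

#' Run the full analysis pipeline on a scenario
#'
#' Executes simulate -> average -> carrier filter -> peak-to-peak (once per
#' subject and condition) -> group-mean amplitudes -> noise baseline ->
#' stimulation threshold and/or grating acuity, and returns a structured
#' report. Deterministic given `seed` (the timestamp aside).
#'
#' @param scn A `"vep_scenario"` (e.g. [study_scenario()] or
#'   [read_scenario()]).
#' @param config An [analysis_config()].
#' @param seed Master integer seed.
#' @return A `"run_report"`: list with `config`, `noise`, `dose_response`
#'   and `threshold` (when the scenario has a full-field arm),
#'   `grating_table`, `fit` and `acuity` (when it has a grating arm;
#'   `acuity_error` carries the reason when the acuity is not estimable),
#'   `software`, `timestamp`. Amplitude tables carry the group mean and the
#'   SEM across subjects.
#' @export
run_pipeline <- function(scn, config = analysis_config(), seed = 1L) {
  stopifnot(inherits(scn, "vep_scenario"), inherits(config, "analysis_config"))
  n_ff <- length(scn$fullfield)
  n_gr <- length(scn$gratings)
  n_sub <- scn$n_subjects
  n_cond <- n_ff + n_gr + 1L           # + baseline
  seeds <- matrix(ladder_seeds(seed, n_cond * n_sub), nrow = n_sub)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # amplitude matrix: subjects x conditions
  conditions <- c(scn$fullfield, scn$gratings, list(scn$baseline))
  amp <- stage("amplitude extraction", {
    vapply(seq_len(n_cond), function(j) {
      vapply(seq_len(n_sub), function(s) {
        condition_amplitude(conditions[[j]], scn$model, seeds[s, j], config)
      }, numeric(1))
    }, numeric(n_sub))
  })
  if (n_sub == 1L) amp <- matrix(amp, nrow = 1L)

  baseline_amps <- amp[, n_cond]
  noise <- stage("noise model",
                 estimate_noise(baseline_amps, mode = config$noise_bound))

  report <- list(config = config, n_subjects = n_sub, noise = noise,
                 baseline_amplitudes_uV = baseline_amps)
  sem <- function(x) stats::sd(x) / sqrt(length(x))

  if (n_ff > 0) {
    irr <- vapply(scn$fullfield, function(p) p$irradiance_mw_mm2, numeric(1))
    cols <- seq_len(n_ff)
    amps <- colMeans(amp[, cols, drop = FALSE])
    dr <- dose_response(irr, amps, noise)
    thr <- estimate_threshold(dr)
    report$dose_response <- data.frame(irradiance_mw_mm2 = irr,
                                       amplitude_uV = amps,
                                       sem_uV = apply(amp[, cols, drop = FALSE],
                                                      2, sem),
                                       supra_noise = thr$supra_noise_mask)
    report$threshold <- thr
  }

  if (n_gr > 0) {
    widths <- vapply(scn$gratings, function(p) p$bar_width_um, numeric(1))
    cols <- n_ff + seq_len(n_gr)
    amps <- colMeans(amp[, cols, drop = FALSE])
    sems <- apply(amp[, cols, drop = FALSE], 2, sem)
    gr <- grating_response(widths, amps, noise)
    fit <- tryCatch(fit_log_linear(gr), error = function(e) e)
    if (inherits(fit, "error")) {
      report$grating_table <- data.frame(bar_width_um = widths,
                                         amplitude_uV = amps,
                                         sem_uV = sems)
      report$acuity_error <- conditionMessage(fit)
    } else {
      acu <- tryCatch(acuity_ci(fit, noise, z = config$z,
                                level = config$intersection_level),
                      error = function(e) e)
      report$grating_table <- data.frame(bar_width_um = widths,
                                         amplitude_uV = amps,
                                         sem_uV = sems,
                                         included = fit$included_mask)
      fit$lm_fit <- NULL              # keep the report serialisable
      report$fit <- fit
      if (inherits(acu, "error")) {
        report$acuity_error <- conditionMessage(acu)
      } else {
        report$acuity <- acu
      }
    }
  }

  report$software <- paste0("vepacuity ",
                            as.character(utils::packageVersion("vepacuity")))
  report$timestamp <- format(Sys.time(), tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%SZ")
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$noise)
  if (!is.null(x[["threshold"]])) print(x[["threshold"]])
  if (!is.null(x[["acuity"]])) print(x[["acuity"]])
  if (!is.null(x[["acuity_error"]])) cat("acuity:", x[["acuity_error"]], "\n")
  invisible(x)
}
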