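#' Describe one stimulation condition
#'
#' A stimulus protocol captures everything the simulator and the analysis need
#' to know about a single recording condition: either a full-field
#' near-infrared pulse at a given retinal irradiance, an alternating grating
#' of a given bar width delivered on a pulsed carrier, or a static (non
#' alternating) grating used to measure the noise baseline.
#'
#' Epochs are stimulus-locked: one epoch spans exactly one stimulus cycle, so
#' `epoch_duration_s * rep_rate_hz` must equal 1.
#'
#' @param mode Stimulation mode: `"full_field"` (single pulse per cycle, no
#'   carrier), `"grating"` (alternating grating on a pulsed carrier) or
#'   `"static_grating_baseline"` (same carrier, no alternation, hence no
#'   evoked response).
#' @param pulse_duration_ms Duration of each light pulse, in milliseconds.
#' @param rep_rate_hz Epoch repetition rate in Hz: the full-field pulse rate,
#'   or the grating alternation rate.
#' @param carrier_freq_hz Pulse-train carrier frequency in Hz, or `NULL` when
#'   the stimulus has no carrier (full-field single pulses).
#' @param irradiance_mw_mm2 Retinal irradiance in mW/mm^2.
#' @param bar_width_um Grating bar width in micrometres (grating modes only).
#' @param n_trials Number of stimulus-locked trials recorded.
#' @param sampling_rate_hz Acquisition sampling rate in Hz.
#' @param epoch_duration_s Epoch length in seconds; defaults to one stimulus
#'   cycle, `1 / rep_rate_hz`.
#'
#' @return An object of class `"stim_protocol"`.
#' @examples
#' stimulus_protocol("full_field", pulse_duration_ms = 10, rep_rate_hz = 2,
#'                   irradiance_mw_mm2 = 0.5)
#' @export
stimulus_protocol <- function(mode = c("full_field", "grating",
                                       "static_grating_baseline"),
                              pulse_duration_ms,
                              rep_rate_hz,
                              carrier_freq_hz = NULL,
                              irradiance_mw_mm2,
                              bar_width_um = NULL,
                              n_trials = 500L,
                              sampling_rate_hz = 2000,
                              epoch_duration_s = 1 / rep_rate_hz) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(pulse_duration_ms), length(pulse_duration_ms) == 1L,
            pulse_duration_ms > 0,
            is.numeric(rep_rate_hz), length(rep_rate_hz) == 1L,
            rep_rate_hz > 0,
            is.numeric(sampling_rate_hz), sampling_rate_hz > 0,
            is.numeric(epoch_duration_s), epoch_duration_s > 0)
  if (!is.numeric(irradiance_mw_mm2) || irradiance_mw_mm2 <= 0) {
    stop("irradiance_mw_mm2 must be a positive irradiance in mW/mm^2")
  }
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("n_trials must be >= 1")
  if (!is.null(carrier_freq_hz)) {
    if (!is.numeric(carrier_freq_hz) || carrier_freq_hz <= 0) {
      stop("carrier_freq_hz must be positive when present")
    }
    if (sampling_rate_hz <= 2 * carrier_freq_hz) {
      stop("invalid protocol: sampling_rate_hz must exceed twice the ",
           "carrier frequency (", carrier_freq_hz, " Hz)")
    }
  }
  if (mode %in% c("grating", "static_grating_baseline")) {
    if (is.null(bar_width_um) || !is.numeric(bar_width_um) ||
        bar_width_um <= 0) {
      stop("bar_width_um must be a positive width (um) in grating modes")
    }
  }
  if (abs(epoch_duration_s * rep_rate_hz - 1) > 1e-9) {
    stop("epochs must tile the stimulus cycle: ",
         "epoch_duration_s * rep_rate_hz must equal 1")
  }
  structure(list(mode = mode,
                 pulse_duration_ms = pulse_duration_ms,
                 rep_rate_hz = rep_rate_hz,
                 carrier_freq_hz = carrier_freq_hz,
                 irradiance_mw_mm2 = irradiance_mw_mm2,
                 bar_width_um = bar_width_um,
                 n_trials = n_trials,
                 sampling_rate_hz = sampling_rate_hz,
                 epoch_duration_s = epoch_duration_s),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>", x$mode, "\n")
  cat("  pulse", x$pulse_duration_ms, "ms @", x$rep_rate_hz, "Hz",
      if (!is.null(x$carrier_freq_hz)) paste0("(carrier ", x$carrier_freq_hz,
                                              " Hz)"), "\n")
  cat("  irradiance", x$irradiance_mw_mm2, "mW/mm^2",
      if (!is.null(x$bar_width_um)) paste0("| bar width ", x$bar_width_um,
                                           " um"), "\n")
  cat("  ", x$n_trials, " trials, ", x$sampling_rate_hz, " Hz, epoch ",
      x$epoch_duration_s, " s\n", sep = "")
  invisible(x)
}

#' Build a full-field irradiance ladder
#'
#' One protocol per irradiance step, sharing all other stimulus parameters.
#' The defaults are the full-field protocol used for stimulation-threshold
#' measurements: 10 ms pulses at 2 Hz, 2 kHz sampling, 500 trials.
#'
#' @param irradiances_mw_mm2 Increasing vector of retinal irradiances,
#'   mW/mm^2. Default: 12 log-spaced steps spanning 0.002-4.7 mW/mm^2.
#' @param pulse_duration_ms,rep_rate_hz,n_trials,sampling_rate_hz Shared
#'   stimulus parameters, see [stimulus_protocol()].
#' @return A list of `"stim_protocol"` objects.
#' @export
fullfield_ladder <- function(irradiances_mw_mm2 =
                               exp(seq(log(0.002), log(4.7), length.out = 12)),
                             pulse_duration_ms = 10,
                             rep_rate_hz = 2,
                             n_trials = 500L,
                             sampling_rate_hz = 2000) {
  if (length(irradiances_mw_mm2) == 0) stop("empty irradiance ladder")
  if (is.unsorted(irradiances_mw_mm2, strictly = TRUE)) {
    stop("irradiances must be strictly increasing")
  }
  lapply(irradiances_mw_mm2, function(E) {
    stimulus_protocol("full_field",
                      pulse_duration_ms = pulse_duration_ms,
                      rep_rate_hz = rep_rate_hz,
                      irradiance_mw_mm2 = E,
                      n_trials = n_trials,
                      sampling_rate_hz = sampling_rate_hz)
  })
}

#' Build a grating bar-width ladder
#'
#' One protocol per bar width. Defaults follow the grating-acuity protocol:
#' 4 ms pulses on a 64 Hz carrier, 1 Hz grating alternation, irradiance
#' 2.4 mW/mm^2, bar widths spanning 13-117 um.
#'
#' @param bar_widths_um Increasing vector of bar widths, um. Default: 9
#'   log-spaced steps from 13 to 117 um.
#' @param irradiance_mw_mm2,pulse_duration_ms,rep_rate_hz,carrier_freq_hz
#'   Shared stimulus parameters.
#' @param n_trials,sampling_rate_hz Acquisition parameters.
#' @return A list of `"stim_protocol"` objects.
#' @export
grating_ladder <- function(bar_widths_um =
                             exp(seq(log(13), log(117), length.out = 9)),
                           irradiance_mw_mm2 = 2.4,
                           pulse_duration_ms = 4,
                           rep_rate_hz = 1,
                           carrier_freq_hz = 64,
                           n_trials = 500L,
                           sampling_rate_hz = 2000) {
  if (length(bar_widths_um) == 0) stop("empty bar-width ladder")
  if (is.unsorted(bar_widths_um, strictly = TRUE)) {
    stop("bar widths must be strictly increasing")
  }
  lapply(bar_widths_um, function(w) {
    stimulus_protocol("grating",
                      pulse_duration_ms = pulse_duration_ms,
                      rep_rate_hz = rep_rate_hz,
                      carrier_freq_hz = carrier_freq_hz,
                      irradiance_mw_mm2 = irradiance_mw_mm2,
                      bar_width_um = w,
                      n_trials = n_trials,
                      sampling_rate_hz = sampling_rate_hz)
  })
}

#' Static-grating baseline protocol
#'
#' The noise baseline is recorded by projecting a static (non-alternating)
#' grating with the other stimulus parameters unchanged, so the recording
#' contains the carrier artifact and noise but no evoked response.
#'
#' @param bar_width_um Static grating bar width, um (default 120).
#' @inheritParams grating_ladder
#' @return A `"stim_protocol"` of mode `"static_grating_baseline"`.
#' @export
baseline_protocol <- function(bar_width_um = 120,
                              irradiance_mw_mm2 = 2.4,
                              pulse_duration_ms = 4,
                              rep_rate_hz = 1,
                              carrier_freq_hz = 64,
                              n_trials = 500L,
                              sampling_rate_hz = 2000) {
  stimulus_protocol("static_grating_baseline",
                    pulse_duration_ms = pulse_duration_ms,
                    rep_rate_hz = rep_rate_hz,
                    carrier_freq_hz = carrier_freq_hz,
                    irradiance_mw_mm2 = irradiance_mw_mm2,
                    bar_width_um = bar_width_um,
                    n_trials = n_trials,
                    sampling_rate_hz = sampling_rate_hz)
}
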