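#' Construct an averaged VEP trace
#'
#' Container for a trial-averaged, stimulus-locked voltage trace. Normally
#' produced by [average_epochs()] or [simulate_average()]; the constructor
#' is exported so recordings averaged elsewhere can enter the pipeline.
#'
#' @param times Uniformly spaced times, seconds, stimulus onset at 0.
#' @param voltage Voltage trace, uV, same length as `times`.
#' @param n_trials_averaged Number of trials entering the average.
#' @param protocol The [stimulus_protocol()] of the recording.
#' @param filtered Whether the carrier artifact has been removed.
#' @param filter The [filter_spec()] applied, if any.
#' @return An object of class `"averaged_vep"`.
#' @export
averaged_vep <- function(times, voltage, n_trials_averaged, protocol,
                         filtered = FALSE, filter = NULL) {
  stopifnot(length(times) == length(voltage), n_trials_averaged >= 1,
            inherits(protocol, "stim_protocol"))
  structure(list(times = times, voltage = voltage,
                 n_trials_averaged = as.integer(n_trials_averaged),
                 protocol = protocol, filtered = isTRUE(filtered),
                 filter = filter),
            class = "averaged_vep")
}

new_averaged_vep <- function(...) averaged_vep(...)

#' @export
print.averaged_vep <- function(x, ...) {
  cat("<averaged_vep>", length(x$voltage), "samples, mean of",
      x$n_trials_averaged, "trials",
      if (x$filtered) "(carrier-filtered)" else "(unfiltered)", "\n")
  invisible(x)
}

#' Average an epoch set into a single VEP trace
#'
#' Pointwise arithmetic mean across trials.
#'
#' @param epochs An `"epoch_set"` from [simulate_epochs()] or
#'   [read_epochs()].
#' @return An `"averaged_vep"`: list with `times` (s), `voltage` (uV),
#'   `n_trials_averaged`, `protocol` and `filtered = FALSE`.
#' @export
average_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  tr <- epochs$traces
  if (!is.matrix(tr) || nrow(tr) < 1L) {
    stop("epoch set must contain at least one rectangular trial")
  }
  if (ncol(tr) != length(epochs$times)) {
    stop("ragged traces: trial length does not match the time grid")
  }
  new_averaged_vep(times = epochs$times, voltage = colMeans(tr),
                   n_trials_averaged = nrow(tr),
                   protocol = epochs$protocol, filtered = FALSE)
}

#' Carrier-notch filter specification
#'
#' Defines which spectral bins the spectrum-reconstruction filter treats as
#' carrier contamination: all bins within `notch_halfwidth_hz` of
#' `k * carrier_freq_hz`, for harmonics `k = 1..n_harmonics`. Notched bins
#' are re-estimated ("reconstructed") by linear interpolation of the complex
#' spectrum from the `interp_neighbors` nearest clean bins on each side.
#'
#' @param carrier_freq_hz Carrier fundamental, Hz (default 64).
#' @param n_harmonics Number of harmonics to notch; `NULL` (default) notches
#'   every harmonic below the Nyquist frequency.
#' @param notch_halfwidth_hz Half-width of each notch, Hz.
#' @param interp_neighbors Clean bins per side used for reconstruction.
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(carrier_freq_hz = 64, n_harmonics = NULL,
                        notch_halfwidth_hz = 1, interp_neighbors = 2L) {
  stopifnot(carrier_freq_hz > 0, notch_halfwidth_hz > 0,
            interp_neighbors >= 1)
  if (!is.null(n_harmonics)) stopifnot(n_harmonics >= 1)
  structure(list(carrier_freq_hz = carrier_freq_hz,
                 n_harmonics = n_harmonics,
                 notch_halfwidth_hz = notch_halfwidth_hz,
                 interp_neighbors = as.integer(interp_neighbors)),
            class = "filter_spec")
}

#' Remove the pulsed-stimulus carrier by spectrum reconstruction
#'
#' Computes the discrete Fourier spectrum of the averaged trace, replaces
#' every bin lying within `notch_halfwidth_hz` of a carrier harmonic by a
#' linear interpolation of the complex spectrum anchored on the nearest
#' clean bins on each side, enforces conjugate symmetry, and inverse
#' transforms. Bins outside the notches are untouched, so the filter is
#' linear, exactly idempotent, and leaves the VEP band intact.
#'
#' @param avg An unfiltered `"averaged_vep"`.
#' @param spec A [filter_spec()]; defaults to the protocol's carrier
#'   frequency when available.
#' @return The filtered `"averaged_vep"` (`filtered = TRUE`), same length,
#'   real-valued.
#' @export
reconstruct_spectrum <- function(avg, spec = NULL) {
  stopifnot(inherits(avg, "averaged_vep"))
  if (avg$filtered) stop("trace is already carrier-filtered")
  if (is.null(spec)) {
    fc <- avg$protocol$carrier_freq_hz
    if (is.null(fc)) stop("no carrier frequency available: supply a filter_spec")
    spec <- filter_spec(carrier_freq_hz = fc)
  }
  stopifnot(inherits(spec, "filter_spec"))

  v <- avg$voltage
  n <- length(v)
  fs <- avg$protocol$sampling_rate_hz
  nyq <- fs / 2
  if (spec$carrier_freq_hz >= nyq) {
    stop("carrier frequency is at or above the Nyquist frequency")
  }
  nh <- spec$n_harmonics
  if (is.null(nh)) nh <- max(1L, floor((nyq - 1e-9) / spec$carrier_freq_hz))
  if (nh * spec$carrier_freq_hz >= fs) {
    stop("notched harmonics must lie below the sampling rate")
  }

  X <- stats::fft(v)
  half <- floor(n / 2) + 1L          # DC .. Nyquist (positive frequencies)
  f_pos <- (seq_len(half) - 1) * fs / n
  notched <- rep(FALSE, half)
  for (k in seq_len(nh)) {
    fk <- k * spec$carrier_freq_hz
    if (fk >= nyq + spec$notch_halfwidth_hz) break
    notched <- notched | (abs(f_pos - fk) <= spec$notch_halfwidth_hz)
  }
  notched[1] <- FALSE                 # never touch DC
  if (!any(notched)) {
    out <- avg
    out$filtered <- TRUE
    out$filter <- spec
    return(out)
  }
  if (all(notched[-1])) {
    stop("notches cover the entire spectrum: nothing left to reconstruct from")
  }

  idx <- which(notched)
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  nb <- spec$interp_neighbors
  clean <- which(!notched)
  for (run in runs) {
    lo <- run[1]; hi <- run[length(run)]
    left <- utils::tail(clean[clean < lo], nb)
    right <- utils::head(clean[clean > hi], nb)
    if (length(left) == 0 && length(right) == 0) {
      stop("no clean bins adjacent to a notch: widen interp_neighbors")
    }
    if (length(left) == 0) {
      X[run] <- mean(X[right])
    } else if (length(right) == 0) {
      X[run] <- mean(X[left])
    } else {
      xl <- mean(left);  vl <- mean(X[left])
      xr <- mean(right); vr <- mean(X[right])
      X[run] <- vl + (vr - vl) * (run - xl) / (xr - xl)
    }
  }
  # conjugate symmetry so the reconstruction stays real
  for (j in idx) {
    if (j == 1L) next
    mirror <- n + 2L - j
    if (mirror == j) {                # Nyquist bin (even n) is its own mirror
      X[j] <- Re(X[j])
    } else {
      X[mirror] <- Conj(X[j])
    }
  }
  out_v <- Re(stats::fft(X, inverse = TRUE) / n)
  new_averaged_vep(times = avg$times, voltage = out_v,
                   n_trials_averaged = avg$n_trials_averaged,
                   protocol = avg$protocol, filtered = TRUE, filter = spec)
}
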