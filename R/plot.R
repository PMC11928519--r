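#' @export
plot.averaged_vep <- function(x, ...) {
  graphics::plot(x$times * 1000, x$voltage, type = "l",
                 xlab = "time (ms)", ylab = "voltage (uV)",
                 main = sprintf("Averaged VEP (%d trials%s)",
                                x$n_trials_averaged,
                                if (x$filtered) ", filtered" else ""), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Plot the grating-acuity fit of a pipeline report
#'
#' Amplitude versus bar width on a log width axis, with the log-linear fit,
#' the mean noise level, the significance bound, and the acuity estimate
#' with its confidence interval.
#'
#' @param report A `"run_report"` with a grating arm.
#' @param ... Passed to [graphics::plot].
#' @return Invisibly, `report`.
#' @export
plot_grating_fit <- function(report, ...) {
  stopifnot(inherits(report, "run_report"))
  tab <- report$grating_table
  if (is.null(tab)) stop("report has no grating arm")
  graphics::plot(tab$bar_width_um, tab$amplitude_uV, log = "x",
                 xlab = "bar width (um)", ylab = "VEP amplitude (uV)",
                 pch = 19, ...)
  graphics::abline(h = report$noise$mean_amp, lty = 2)
  graphics::abline(h = report$noise$upper95, lty = 3)
  if (!is.null(report$fit)) {
    w <- exp(seq(log(min(tab$bar_width_um)), log(max(tab$bar_width_um)),
                 length.out = 200))
    graphics::lines(w, report$fit$a * log(w) + report$fit$b, col = "red")
  }
  if (!is.null(report$acuity)) {
    graphics::points(report$acuity$w_star_um, report$noise$mean_amp,
                     col = "red", pch = 4, cex = 1.5)
    graphics::segments(report$acuity$ci_low_um, report$noise$mean_amp,
                       report$acuity$ci_high_um, report$noise$mean_amp,
                       col = "red")
  }
  invisible(report)
}
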