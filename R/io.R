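#' Write an epoch set to disk
#'
#' Traces go to a long-format CSV with columns `trial`, `time_s`,
#' `voltage_uV` (one row per trial and sample, units fixed in the header);
#' the protocol, seed and (optionally) the generative model go to a JSON
#' sidecar next to it. [read_epochs()] round-trips both.
#'
#' @param epochs An `"epoch_set"`.
#' @param csv_path Output CSV path; the sidecar is written to the same path
#'   with extension `.json`.
#' @param model Optional [response_model()] recorded in the sidecar.
#' @return Invisibly, the CSV path.
#' @export
write_epochs <- function(epochs, csv_path, model = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_tr <- nrow(epochs$traces)
  n_t <- ncol(epochs$traces)
  df <- data.frame(trial = rep(seq_len(n_tr), each = n_t),
                   time_s = rep(epochs$times, times = n_tr),
                   voltage_uV = as.vector(t(epochs$traces)))
  utils::write.csv(df, csv_path, row.names = FALSE)
  sidecar <- list(protocol = unclass(epochs$protocol),
                  seed = epochs$seed,
                  model = if (!is.null(model)) unclass(model))
  jsonlite::write_json(sidecar, .sidecar_path(csv_path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(csv_path)
}

.sidecar_path <- function(csv_path) sub("\\.csv$", ".json", csv_path)

.protocol_from_list <- function(p) {
  stimulus_protocol(mode = p$mode,
                    pulse_duration_ms = p$pulse_duration_ms,
                    rep_rate_hz = p$rep_rate_hz,
                    carrier_freq_hz = p$carrier_freq_hz,
                    irradiance_mw_mm2 = p$irradiance_mw_mm2,
                    bar_width_um = p$bar_width_um,
                    n_trials = p$n_trials,
                    sampling_rate_hz = p$sampling_rate_hz,
                    epoch_duration_s = p$epoch_duration_s)
}

.model_from_list <- function(m) {
  cal <- m$grating_cal
  m$grating_cal <- NULL
  model <- do.call(response_model, m)
  if (!is.null(cal)) model$grating_cal <- lapply(cal, unlist)
  model
}

#' Read an epoch set written by [write_epochs()]
#'
#' Validates the long CSV format (exact column names, units in the header),
#' rejects ragged trials and non-uniform time grids, and rebuilds the
#' protocol from the JSON sidecar.
#'
#' @param csv_path Path to the CSV written by [write_epochs()].
#' @param json_path Sidecar path (defaults to `csv_path` with `.json`).
#' @return An `"epoch_set"`.
#' @export
read_epochs <- function(csv_path, json_path = .sidecar_path(csv_path)) {
  df <- utils::read.csv(csv_path)
  need <- c("trial", "time_s", "voltage_uV")
  if (!identical(names(df), need)) {
    stop("parse error: expected columns ", paste(need, collapse = ", "),
         " (units are part of the header), got ",
         paste(names(df), collapse = ", "))
  }
  if (!file.exists(json_path)) {
    stop("parse error: JSON sidecar not found at ", json_path)
  }
  side <- jsonlite::fromJSON(json_path)
  protocol <- .protocol_from_list(side$protocol)

  trials <- unique(df$trial)
  lens <- tapply(df$voltage_uV, df$trial, length)
  if (length(unique(lens)) != 1L) {
    stop("parse error: ragged trials (trial lengths differ: ",
         paste(range(lens), collapse = "-"), ")")
  }
  n_t <- unname(lens[1])
  times <- df$time_s[df$trial == trials[1]]
  dt <- diff(times)
  if (length(dt) > 0 &&
      (max(dt) - min(dt)) > 1e-9 * max(abs(times[-1]))) {
    stop("parse error: non-uniform time grid")
  }
  for (tr in trials) {
    if (max(abs(df$time_s[df$trial == tr] - times)) > 1e-12) {
      stop("parse error: trials do not share a common time grid")
    }
  }
  traces <- matrix(df$voltage_uV, nrow = length(trials), ncol = n_t,
                   byrow = TRUE)
  structure(list(protocol = protocol, times = times, traces = traces,
                 seed = if (!is.null(side$seed)) as.integer(side$seed)
                        else NA_integer_),
            class = "epoch_set")
}

#' Write an analysis report as JSON
#'
#' Serialises a [run_pipeline()] report (config echo, per-condition
#' amplitude tables, noise model, threshold and acuity estimates, package
#' version, timestamp) to pretty-printed JSON with full numeric precision.
#'
#' @param report A `"run_report"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(.unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

.unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), .unclass_deep)
  } else if (is.data.frame(x)) {
    x
  } else {
    if (is.object(x)) unclass(x) else x
  }
}

#' Read a simulation scenario from JSON
#'
#' A scenario file describes a complete simulated experiment: a response
#' model, optional full-field irradiance ladder, optional grating bar-width
#' ladder, and the baseline condition. See [study_scenario()] for the
#' in-memory equivalent and [write_scenario()] for the inverse.
#'
#' @param path Path to a scenario JSON file.
#' @return A `"vep_scenario"` object.
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  model <- .model_from_list(raw$model)
  as_protocols <- function(x) lapply(x, .protocol_from_list)
  scenario(model = model,
           fullfield = if (!is.null(raw$fullfield)) as_protocols(raw$fullfield),
           gratings = if (!is.null(raw$gratings)) as_protocols(raw$gratings),
           baseline = .protocol_from_list(raw$baseline),
           n_subjects = raw$n_subjects)
}

#' Write a scenario to JSON
#'
#' @param scn A `"vep_scenario"`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "vep_scenario"))
  jsonlite::write_json(.unclass_deep(scn), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
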