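# RNG hygiene: simulation entry points take an explicit seed, and the
# caller's RNG state is restored afterwards.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic part of one trial: scaled template plus gated carrier
# artifact (fundamental + 2f and 3f harmonics at -12 dB). Cached: Monte-Carlo
# studies re-simulate the same condition thousands of times.
.deterministic_trace <- function(protocol, model, t_s) {
  key <- paste(c("det", format(c(unlist(protocol[c("mode", "pulse_duration_ms",
                   "rep_rate_hz", "irradiance_mw_mm2", "sampling_rate_hz",
                   "epoch_duration_s")]),
                 protocol$bar_width_um, protocol$carrier_freq_hz,
                 unlist(model[vapply(model, is.numeric, logical(1))]),
                 unlist(model$grating_cal), length(t_s)), digits = 15)),
               collapse = "|")
  cached <- .vep_cache[[key]]
  if (!is.null(cached)) return(cached)
  amp <- evoked_amplitude(protocol, model)
  v <- amp * vep_template(t_s, model)
  fc <- protocol$carrier_freq_hz
  if (!is.null(fc) && model$carrier_amp_uV > 0) {
    v <- v + model$carrier_amp_uV *
      (sin(2 * pi * fc * t_s) +
       0.25 * sin(2 * pi * 2 * fc * t_s) +
       0.25 * sin(2 * pi * 3 * fc * t_s))
  }
  .vep_cache[[key]] <- v
  v
}

.epoch_times <- function(protocol) {
  n <- round(protocol$epoch_duration_s * protocol$sampling_rate_hz)
  (seq_len(n) - 1) / protocol$sampling_rate_hz
}

#' Simulate a multi-trial stimulus-locked recording
#'
#' Every trial is the same deterministic component (evoked template scaled by
#' the model's amplitude law, plus the carrier artifact when the protocol has
#' a carrier) plus independent white Gaussian noise of SD
#' `model$noise_sd_uV`. Identical `(protocol, model, seed)` reproduce
#' bit-identical output; the caller's RNG state is left untouched.
#'
#' @param protocol A [stimulus_protocol()].
#' @param model A [response_model()].
#' @param seed Integer seed.
#' @return An object of class `"epoch_set"`: list with `protocol`, `times`
#'   (seconds, onset at 0), `traces` (`n_trials` x `n_samples` matrix, uV)
#'   and `seed`.
#' @export
simulate_epochs <- function(protocol, model, seed) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(model, "response_model"))
  t_s <- .epoch_times(protocol)
  det <- .deterministic_trace(protocol, model, t_s)
  n <- length(t_s)
  traces <- .with_seed(seed, {
    noise <- if (model$noise_sd_uV > 0) {
      matrix(stats::rnorm(protocol$n_trials * n, sd = model$noise_sd_uV),
             nrow = protocol$n_trials)
    } else {
      matrix(0, nrow = protocol$n_trials, ncol = n)
    }
    sweep(noise, 2, det, `+`)
  })
  structure(list(protocol = protocol, times = t_s, traces = traces,
                 seed = as.integer(seed)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", nrow(x$traces), "trials x", ncol(x$traces),
      "samples (", x$protocol$mode, ", seed", x$seed, ")\n")
  invisible(x)
}

#' Simulate the trial average directly
#'
#' Draws the `n_trials`-trial average in one step: deterministic component
#' plus white Gaussian noise of SD `noise_sd_uV / sqrt(n_trials)`. For white
#' Gaussian per-trial noise this is distributionally identical to averaging
#' the output of [simulate_epochs()], at 1/n_trials of the cost, which makes
#' replicated Monte-Carlo studies of the full analysis chain cheap.
#'
#' @inheritParams simulate_epochs
#' @return An `"averaged_vep"` object (see [average_epochs()]).
#' @export
simulate_average <- function(protocol, model, seed) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(model, "response_model"))
  t_s <- .epoch_times(protocol)
  det <- .deterministic_trace(protocol, model, t_s)
  sd_avg <- model$noise_sd_uV / sqrt(protocol$n_trials)
  v <- .with_seed(seed, det + if (sd_avg > 0)
    stats::rnorm(length(det), sd = sd_avg) else 0)
  new_averaged_vep(times = t_s, voltage = v,
                   n_trials_averaged = protocol$n_trials,
                   protocol = protocol, filtered = FALSE)
}

#' Reproducible per-condition seeds for a ladder
#'
#' Derives one independent seed per ladder index from a single master seed,
#' so that `simulate_ladder(ps, m, seed)[[i]]` equals
#' `simulate_epochs(ps[[i]], m, ladder_seeds(seed, length(ps))[i])`.
#'
#' @param seed Master integer seed.
#' @param n Number of conditions.
#' @return Integer vector of `n` seeds.
#' @export
ladder_seeds <- function(seed, n) {
  stopifnot(n >= 1)
  .with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Simulate a ladder of stimulation conditions
#'
#' One [simulate_epochs()] call per protocol, each with its own seed derived
#' reproducibly from the master seed via [ladder_seeds()].
#'
#' @param protocols Non-empty list of [stimulus_protocol()] objects sharing
#'   the same sampling rate.
#' @param model A [response_model()].
#' @param seed Master integer seed.
#' @param average If `TRUE`, return [simulate_average()] results instead of
#'   full epoch sets.
#' @return List of `"epoch_set"` (or `"averaged_vep"`) objects, one per
#'   protocol.
#' @export
simulate_ladder <- function(protocols, model, seed, average = FALSE) {
  if (length(protocols) == 0) stop("empty ladder: no protocols supplied")
  fs <- vapply(protocols, function(p) p$sampling_rate_hz, numeric(1))
  if (length(unique(fs)) != 1L) {
    stop("all ladder protocols must share the same sampling rate")
  }
  seeds <- ladder_seeds(seed, length(protocols))
  fun <- if (average) simulate_average else simulate_epochs
  Map(function(p, s) fun(p, model, s), protocols, seeds)
}
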