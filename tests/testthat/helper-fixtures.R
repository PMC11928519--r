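# Small, fast fixtures: 500 Hz sampling keeps the 64 Hz carrier and its
# first harmonics below Nyquist while epochs stay short.

fast_grating <- function(bar_width_um = 60, n_trials = 8L,
                         sampling_rate_hz = 500) {
  stimulus_protocol("grating", pulse_duration_ms = 4, rep_rate_hz = 1,
                    carrier_freq_hz = 64, irradiance_mw_mm2 = 2.4,
                    bar_width_um = bar_width_um, n_trials = n_trials,
                    sampling_rate_hz = sampling_rate_hz)
}

fast_fullfield <- function(irradiance = 0.5, n_trials = 8L,
                           sampling_rate_hz = 500) {
  stimulus_protocol("full_field", pulse_duration_ms = 10, rep_rate_hz = 2,
                    irradiance_mw_mm2 = irradiance, n_trials = n_trials,
                    sampling_rate_hz = sampling_rate_hz)
}

quiet_model <- function(...) {
  response_model(noise_sd_uV = 0, carrier_amp_uV = 0, ...)
}

# bare averaged trace on a uniform grid, for direct metric tests
flat_avg <- function(voltage, sampling_rate_hz = 500, rep_rate_hz = 1) {
  p <- stimulus_protocol("full_field", pulse_duration_ms = 10,
                         rep_rate_hz = rep_rate_hz, irradiance_mw_mm2 = 1,
                         sampling_rate_hz = sampling_rate_hz)
  averaged_vep(times = (seq_along(voltage) - 1) / sampling_rate_hz,
               voltage = voltage, n_trials_averaged = 1L, protocol = p)
}
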