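---
title: "Quantifying prosthetic vision from VEPs: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prosthetic vision from VEPs: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(vepacuity)
```

## The measurement problem

A photovoltaic subretinal implant converts pulsed near-infrared light into
electrical stimulation of the surviving inner retina. Two numbers summarise
how well an implanted eye sees:

* the **stimulation threshold** — the lowest retinal irradiance
  (mW/mm&sup2;) at which a full-field flash evokes a cortical response
  distinguishable from noise;
* the **grating acuity** — the narrowest alternating-grating bar width
  (µm) that still evokes a response, i.e. the spatial resolution limit.

Both are read out from visually evoked potentials (VEPs): voltages recorded
through transcranial electrodes over the visual cortex, time-locked to the
stimulus and averaged over hundreds of trials. This package implements the
full analysis chain from raw multi-trial recordings to those two numbers,
together with a synthetic-recording generator that lets every stage be
validated by simulation.

## The analysis chain

1. **Epoch averaging.** Trials are stimulus-locked; the average of
   `n` trials reduces white noise by `1/sqrt(n)` (`average_epochs()`).
2. **Carrier removal.** Grating stimuli are delivered as a 64 Hz pulse
   train. The pulses leave a narrowband artifact at the carrier frequency
   and its harmonics, removed by *spectrum reconstruction*
   (`reconstruct_spectrum()`): the discrete spectrum is computed, every bin
   within 1 Hz of a carrier harmonic is replaced by linear interpolation of
   the complex spectrum from the two nearest clean bins on each side,
   conjugate symmetry is enforced, and the trace is inverse-transformed.
   Only notched bins change, so the filter is linear, exactly idempotent,
   and leaves the low-frequency VEP band untouched. "Spectrum
   reconstruction" has no canonical published definition; this
   notch-and-interpolate reading is the package's convention, chosen
   because it is deterministic and minimal.
3. **Response quantification.** Peak-to-peak voltage over a response window
   of 10–300 ms after stimulus onset (`peak_to_peak()`). The window is a
   convention — it brackets the rat cortical response (negative lobe near
   40 ms, positive lobe near 80 ms) while excluding the onset sample — and
   is configurable.
4. **Noise baseline.** A static (non-alternating) 120 µm grating delivers
   the same carrier and light dose but evokes no response; its
   peak-to-peak amplitudes define the noise distribution
   (`estimate_noise()`).
5. **Threshold.** The lowest irradiance whose amplitude exceeds the noise
   significance bound, with all higher irradiances also exceeding it
   (`estimate_threshold()`).
6. **Acuity.** Amplitude is regressed on `ln(bar width)` over the
   supra-noise points; the acuity limit is where the fitted line crosses
   the noise level, with a delta-method confidence interval
   (`fit_log_linear()`, `acuity_ci()`).

## Noise bound: two conventions, one default

"Exceeding the noise above the 95 % confidence interval" can mean a bound
on the noise *distribution* or on its *mean*. The default is the
distribution bound, `mean + 1.96 * sd`: a single averaged response must
exceed plausible noise excursions, not merely the uncertainty of the mean.
The SEM variant (`mean + 1.96 * sd / sqrt(n)`) is available through
`estimate_noise(mode = "sem")`.

## Acuity: intersection level, inclusion rule, and the 1.92 multiplier

The acuity limit is `w* = exp((N - b) / a)` for the fitted line
`amplitude = a ln(w) + b`. Two distinct noise quantities play different
roles, and the defaults keep them apart deliberately:

* **Point inclusion** uses the significance bound `upper95`: only widths
  whose amplitude exceeds it count as "data points above the noise level".
  By default the included set is additionally required to be the contiguous
  supra-noise run ending at the widest grating: a response genuinely
  resolvable at some width is resolvable at every larger one, so an
  isolated supra-noise point surrounded by sub-noise widths is a noise
  excursion, not a response. This mirrors the persistence requirement of
  the threshold rule; the plain rule is available via
  `fit_log_linear(include = "all_supra")`.
* **Intersection** uses the *mean* baseline amplitude (the noise level
  drawn as a dashed line in grating dose–response figures):
  `acuity_limit(level = "mean")`. Intersecting at `upper95` instead is
  supported (`level = "upper95"`) but shifts the estimate upward by
  `1.96 sd_N / a` on the log-width scale and makes it a biased estimator of
  the width at which the response sinks into the noise; the mean level is
  the default for that reason. Consistently, the noise-level variance that
  enters the delta method is the SEM-based `var_N = sd^2 / n` — the
  variance of the estimated *mean* level.

The delta method propagates the fit covariance and `var_N` through the
nonlinear map: with gradient
`g = w* (-(N - b)/a^2, -1/a, 1/a)` with respect to `(a, b, N)`,

```
Var(w*) = g_a^2 Var(a) + g_b^2 Var(b) + 2 g_a g_b Cov(a, b) + g_N^2 var_N
```

and the 95 % interval is `w* ± 1.92 sd`. The multiplier is kept at 1.92
exactly as used in the field for this readout (a normal-approximation 95 %
interval); it is configurable but deliberately not "corrected" to 1.96.
The natural logarithm is used throughout; any other base rescales `a` and
`b` but leaves `w*` unchanged.

Degenerate inputs fail loudly rather than silently: fewer than three
supra-noise points, all-equal included widths (singular normal equations),
or a non-positive slope each raise a *not estimable* error — never a
pseudo-inverse, never an extrapolated guess.

## The synthetic cohort

`study_scenario()` emulates a cohort experiment: 7 subjects, each
contributing one 500-trial recording per condition at 2 kHz sampling —

* full-field: 10 ms pulses at 2 Hz, twelve log-spaced irradiances from
  0.002 to 4.7 mW/mm²;
* gratings: 4 ms pulses on a 64 Hz carrier, 1 Hz alternation,
  2.4 mW/mm², nine log-spaced bar widths from 13 to 117 µm;
* baseline: a static 120 µm grating, identical otherwise.

Amplitudes are averaged across subjects per condition (the group-mean
curves with SEM error bars of a typical cohort study) and the noise model
comes from the 7 per-subject baseline amplitudes. The generative response
model (`response_model()`) uses:

* a biphasic template — difference of two gamma-density lobes, negative
  peak at 40 ms, positive at 80 ms, unit peak-to-peak; only the
  peak-to-peak amplitude matters downstream, so any fixed biphasic shape
  would do;
* a sigmoid irradiance law `A(E) = A_max E^h / (E50^h + E^h)` with
  `A_max = 120` µV, `E50 = 0.3` mW/mm², `h = 1.5`;
* a logarithmic grating law with slope 40 µV per ln-µm and true acuity
  limit `w_true = 28` µm;
* a deterministic carrier artifact of 20 µV with 2nd and 3rd harmonics at
  −12 dB (deterministic, so it survives averaging at full amplitude and
  gives the filter something realistic to remove);
* white Gaussian per-trial noise of SD 25 µV, typical of raw transcranial
  rodent recordings.

None of the amplitude or noise figures are measured constants; they are
conventions chosen once to be realistic for rodent prosthetic VEPs, and
they are printed in `response_model()`'s defaults rather than hidden.

### Why the grating law is calibrated

Peak-to-peak extraction is biased upward on noisy traces: over an `m`-sample
window, response-free noise measures at a floor of roughly
`2 sigma sqrt(2 ln m)` (Gaussian extreme-value statistics,
`noise_floor_p2p()`), and noise excursions at the template extrema inflate
any measured response by a few `sigma`. A generative law with
`A(w_true) = 0` therefore *measures* above zero everywhere, and the fitted
line would cross the noise level away from `w_true`. Because the
generator's purpose is to make the analysis model true — amplitude linear
in `ln w`, crossing the noise level exactly at the generative acuity
limit — `study_scenario()` calibrates the evoked amplitude per ladder
width so that the *expected measured* amplitude equals
`floor + slope * ln(w / w_true)` under the exact measurement chain (trial
averaging, carrier filter, windowed peak-to-peak). The calibration is a
fixed-seed Monte-Carlo solve, deterministic and cached; the uncalibrated
law (`A(w) = max(0, slope * ln(w / w_true))`) remains the
`response_model()` default and is what `anchor_grating_law = FALSE`
selects.

### Monte-Carlo representation

For replicated simulation studies, `simulate_average()` draws the
500-trial average directly with noise SD `25 / sqrt(500)` µV — for white
Gaussian per-trial noise this is *distributionally identical* to averaging
500 simulated trials, at a five-hundredth of the cost. The full
multi-trial path (`simulate_epochs()` then `average_epochs()`) is the
pipeline default and is exercised end to end in the test suite; the two
paths agree exactly in their deterministic component and in the noise law.

### What the generator does and does not emulate

It reproduces the stimulus structure, trial averaging, carrier
contamination, and amplitude laws the analysis assumes. It does **not**
model pink/structured EEG noise, per-subject response heterogeneity
(subjects differ only through noise), eye movements or artifact trials,
latency jitter, or any biophysics of the electrode–retina interface.
Passing recovery tests therefore shows the *estimators* are correct and
calibrated under their stated assumptions — not that those assumptions
hold in any particular animal.

## Validation summary

The test suite and `scripts/acceptance.R` recompute, from scratch:

* exact worked examples for the geometry utilities (hexagonal pitch
  `100 µm × cos 30° → 87 µm`; Snellen `100 µm → 20/420`,
  `hex pitch of 22 µm → 20/80` at 4.8 µm/arcmin);
* the filter contract (≥ 20 dB carrier suppression, ≤ 5 % template
  distortion, spectra untouched outside the notches, linearity,
  idempotence);
* the `1/sqrt(n)` averaging law;
* threshold recovery within one ladder step of the generative crossing,
  and acuity recovery with median error well under 10 % of `w_true` and
  1.92-sd CI coverage inside 90–98 %, over hundreds of seeded cohort
  replicates (500 in the test suite's acuity block; 300 and 150 in the
  acceptance script — sizes chosen so each block completes in tens of
  seconds on one core);
* agreement of the delta-method sd with a 10⁴-draw parametric bootstrap,
  and of every closed-form step with brute-force oracles (hand normal
  equations, 1 nm grid scan of the intersection, exhaustive peak-to-peak
  scan).

The observed CI coverage (~92 %) sits slightly below the nominal 95 %
because the method fixes `z = 1.92` while both the fit covariance and
`var_N` are estimated from few degrees of freedom (6 fitted points, 7
baseline subjects) — the familiar normal-versus-t gap, inherent to the
published procedure rather than to this implementation.

## Worked example

```{r example, eval = FALSE}
scn <- study_scenario()                    # 7 subjects, all three arms
cfg <- analysis_config()
report <- run_pipeline(scn, cfg, seed = 1)
report
plot_grating_fit(report)
write_report(report, "report.json")
```

## Known limitations

* The carrier filter assumes the carrier frequency sits close to a DFT bin
  (true for 1 s epochs and integer-Hz carriers); a strongly off-bin
  carrier would leak outside the 1 Hz notches.
* `estimate_threshold()` never interpolates between ladder steps, so the
  threshold resolution is the ladder spacing.
* The acuity CI is symmetric in width; for very uncertain fits a
  log-width interval would respect positivity better.
* Filtering is applied to the trial average, not per trial — identical for
  a linear filter, but per-trial artifact rejection is out of scope.
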