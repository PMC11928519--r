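# vepacuity

Analysis of visually evoked potentials (VEP) for photovoltaic subretinal
prostheses: from raw multi-trial cortical recordings to the two numbers
that summarise prosthetic vision in an implanted eye — the **stimulation
threshold** (lowest retinal irradiance that evokes a significant cortical
response) and the **grating acuity limit** (narrowest alternating-grating
bar width that still evokes one), the latter with a delta-method 95%
confidence interval.

Intended for electrophysiologists and implant engineers analysing
stimulus-locked VEP recordings (e.g. rodent studies of subretinal implant
resolution), and for anyone who wants a fully simulated, seeded test bed
for this class of analysis.

## The method

For each stimulation condition, stimulus-locked trials are averaged
(noise shrinks as 1/√n), the 64 Hz pulse-train carrier artifact is removed
by *spectrum reconstruction* (bins within 1 Hz of each carrier harmonic
are replaced by linear interpolation of the complex spectrum from
neighbouring clean bins), and the response is quantified as the
peak-to-peak amplitude V over a 10–300 ms window.

A response-free baseline (static grating) gives a noise model with mean
amplitude N and significance bound `N + 1.96·SD`. Then:

* **Threshold**: the lowest irradiance E on the ladder with `V(E)` above
  the significance bound, persistently so at all higher irradiances.
* **Acuity**: over supra-noise bar widths w, fit `V = a·ln w + b` by
  ordinary least squares (parameter covariance Σ); the acuity limit is the
  intersection with the noise level,

      w* = exp((N − b)/a),

  and with gradient `g = w*·(−(N−b)/a², −1/a, 1/a)` with respect to
  (a, b, N), the delta method gives
  `Var(w*) = gₐ²Var(a) + g_b²Var(b) + 2gₐg_b Cov(a,b) + g_N²·Var(N)`,
  reported as the 95% interval `w* ± 1.92·SD(w*)`.

Small dosimetry/geometry utilities round the toolkit out: corneal→retinal
irradiance via pattern-area power conservation, hexagonal pixel pitch
(`width·cos 30°`), and Snellen conversion (20/20 = 1 arcmin = 4.8 µm on
the human retina).

A synthetic cohort generator (`study_scenario()`) reproduces the study
conditions — 500-trial recordings at 2 kHz from 7 subjects; full-field
10 ms pulses at 2 Hz over 0.002–4.7 mW/mm²; gratings of 13–117 µm on a
64 Hz carrier at 2.4 mW/mm²; static 120 µm grating baseline — with a known
generative acuity limit of 28 µm, so every estimator can be validated by
seeded Monte-Carlo. See the methods vignette
(`vignettes/vep-acuity-methods.Rmd`) for the conventions and their
rationale.

## Worked example

```r
library(vepacuity)

scn    <- study_scenario()              # simulated 7-subject cohort
report <- run_pipeline(scn, analysis_config(), seed = 1)
report
#> <run_report>
#> <noise_model> mean 6.858 uV, sd 0.5263 uV, upper95 7.89 uV ( distribution , n = 7 )
#> <threshold_estimate> 0.0336 mW/mm^2
#> <acuity_estimate> w* = 28.07 um, sd 0.208 um,  1.92 *sd CI [ 27.67 , 28.47 ] um
```

Reading the output: the seven baseline recordings put the noise level at
6.86 µV (significance bound 7.89 µV); the full-field ladder first exceeds
the bound — persistently — at 0.0336 mW/mm², the stimulation threshold;
and the log-linear fit through the supra-noise grating amplitudes crosses
the noise level at 28.07 µm, recovering the generator's 28 µm acuity limit
well within the 1.92·SD interval. Per-condition amplitude tables with SEMs
are in `report$dose_response` and `report$grating_table`:

```r
head(report$grating_table)
#>   bar_width_um amplitude_uV    sem_uV included
#> 1     13.00000     6.898331 0.2128734    FALSE
#> 2     17.10896     6.694653 0.1918810    FALSE
#> 3     22.51666     6.883541 0.2693747    FALSE
#> 4     29.63359     9.117358 0.2932727     TRUE
#> 5     39.00000    20.215880 0.2727482     TRUE
#> 6     51.32689    30.500228 0.3214803     TRUE
```

Geometry one-liners:

```r
hex_pitch(100, rounded = TRUE)        # 87   (µm pitch of 100 µm hex pixels)
snellen_denominator(100)              # 420  (100 µm feature -> 20/420)
snellen_denominator(hex_pitch(22))    # 80   (22 µm hex pitch -> 20/80)
```

A thin command-line front end over the same functions lives at
`inst/cli/vep.R` (subcommands `simulate`, `filter`, `threshold`, `acuity`,
`convert`, `run`), reading/writing long-format CSV recordings with JSON
sidecars.

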