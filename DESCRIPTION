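Package: vepacuity
Title: Visually Evoked Potential Analysis for Photovoltaic Retinal Prostheses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for visually evoked potentials (VEP) recorded
    during stimulation of photovoltaic subretinal implants. Provides a
    synthetic multi-trial VEP generator, removal of the pulsed-stimulus
    carrier artifact by spectrum reconstruction, peak-to-peak response
    quantification, stimulation-threshold detection against a noise baseline,
    and grating-acuity estimation by intersecting a log-linear amplitude fit
    with the noise level, with a delta-method confidence interval. Includes
    small dosimetry and geometry utilities (retinal irradiance adjustment,
    hexagonal pixel pitch, Snellen conversion) and reproducible file formats
    for recordings and reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
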