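Package: nirsocial
Title: Simulation and Analysis of Infant Social-Brain fNIRS Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for event-related functional near-infrared spectroscopy
    (fNIRS) studies of the infant social brain. Converts dual-wavelength light
    intensity to oxy- and deoxy-haemoglobin concentration changes via the
    modified Beer-Lambert law, applies looking-time and motion-artifact trial
    rejection, computes channel-wise windowed peak statistics with
    Benjamini-Hochberg false-discovery-rate correction, builds baseline
    corrected region-of-interest epoch responses, and fits linear mixed models
    of group differences in visual-social and vocal versus non-vocal auditory
    responses. A companion synthetic-data generator emulates the stimulus
    design, hemodynamics, physiological noise, motion artifacts and
    looking-time attrition of such studies so that every pipeline stage can be
    verified end-to-end by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    lmerTest,
    emmeans,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
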