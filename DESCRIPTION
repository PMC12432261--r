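Package: eareog
Title: Periauricular Electrooculography Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing electrooculography (EOG) recorded from
    electrodes positioned around the ears in a headphone form factor.
    Implements lag-constrained correlation ranking of differential electrode
    montages against gold-standard periorbital EOG and camera-based gaze,
    saccade voltage-deflection analysis, and linear prediction of horizontal
    gaze-angle changes with mean-absolute-error and Bland-Altman reporting.
    Includes a corneo-retinal dipole forward simulator of periauricular and
    periorbital potentials, a smooth-pursuit and saccade stimulus generator,
    and a deterministic end-to-end pipeline, so the full analysis runs
    without access to laboratory recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
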