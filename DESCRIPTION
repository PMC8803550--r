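Package: opmclean
Title: Interference Suppression and Source Analysis for Wearable OPM-MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for suppressing environmental and movement-related magnetic
    interference in recordings from wearable arrays of optically pumped
    magnetometers (OPM-MEG). Implements homogeneous field correction (first
    order spherical harmonic projection), synthetic gradiometry by windowed
    reference-channel regression, motion-capture artifact regression,
    zero-phase Butterworth filtering, spectral interpolation of narrow-band
    interference, robust windowed detrending, signal space projection,
    fastICA-based physiological artifact removal, Welch amplitude spectral
    density and shielding-factor metrics, epoching and evoked t-statistics,
    Hanning-taper time-frequency analysis, and a regularised LCMV beamformer
    with a dual correlated-source constraint. Ships a synthetic OPM session
    simulator (spherical-conductor dipole forward model, remnant-field drift,
    field-gradient motion artifacts, line interference, physiological
    artifacts) with exact per-component ground truth, plus config-driven
    pipeline presets for a mobile auditory-evoked-field experiment and a
    stationary finger-tapping beta-band experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
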