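Package: bcindex
Title: Individual Alpha Frequency and Neurophysiological BCI Aptitude Index from Resting EEG
Version: 0.1.0
Authors@R: person("bcindex", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the individual alpha frequency (IAF) from paired
    eyes-closed/eyes-open resting EEG using the occipital reactivity
    spectrum, fits a constant + power-law + Gaussian-peak model to
    central-channel power spectra to compute a neurophysiological
    predictor of motor-imagery BCI aptitude, and validates the IAF
    against a theoretical value derived from cardiac frequency through
    the harmonic brain-body frequency structure, with Pan-Tompkins QRS
    detection on a single-lead ECG. Includes seeded synthetic EEG/ECG
    generators so the full pipeline is testable without external data,
    and a command-line entry point producing figures and a JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
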