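# bcindex pipeline configuration - reference copy with all defaults.
# Flat key = value; pass via `bcindex run --config FILE` or as a named
# list to run_pipeline(config = ...).

# Welch PSD: 4-s epochs give 0.25 Hz resolution
welch.epoch_seconds = 4
welch.overlap = 0.5
welch.window = "hann"

# IAF from the eyes-closed minus eyes-open reactivity spectrum
iaf.search_low_hz = 7
iaf.search_high_hz = 14
iaf.smooth = false

# Aptitude predictor: spectral model fit on the eyes-open recording
predictor.fit_low_hz = 2
predictor.fit_high_hz = 35
predictor.two_peaks = true
predictor.degenerate_tol = 0.01
# predictor.truncate_eo_s = 120   # uncomment to use only the first 2 min

# ECG validation chain: NN-interval plausibility window (seconds)
ecg.nn_min_s = 0.3
ecg.nn_max_s = 2.0
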