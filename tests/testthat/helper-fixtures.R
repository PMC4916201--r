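# shared fixture builders (everything generated in code, no binary files)

# single-channel recording holding a pure sinusoid
sine_recording <- function(freq_hz, fs = 128, duration_s = 60, amp = 1,
                           label = "Cz", phase = 0) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  recording(matrix(amp * sin(2 * pi * freq_hz * t + phase), 1), fs, label)
}

# PSD pair where EC = EO + a Gaussian bump on the given channels
bump_psd_pair <- function(center_hz, labels = c("O1", "O2"),
                          bump_area = 5, bump_sd = 0.5,
                          fs = 128, epoch_seconds = 4) {
  freqs <- seq(0, fs / 2, by = 1 / epoch_seconds)
  base <- outer(rep(1, length(labels)),
                50 / pmax(freqs, 0.25))  # shared 1/f-ish background
  bump <- bump_area / (bump_sd * sqrt(2 * pi)) *
    exp(-(freqs - center_hz)^2 / (2 * bump_sd^2))
  mk <- function(power) structure(
    list(freqs_hz = freqs, power = power, resolution_hz = 1 / epoch_seconds,
         epoch_seconds = epoch_seconds, labels = labels,
         sample_rate_hz = fs),
    class = "bci_psd")
  list(ec = mk(base + outer(rep(1, length(labels)), bump)),
       eo = mk(base), bump = bump, freqs = freqs)
}

# detection scoring against generator ground truth
score_detection <- function(detected, truth, fs, window_s = 0.05) {
  w <- window_s * fs
  sens <- mean(vapply(truth, function(p) any(abs(detected - p) <= w), TRUE))
  prec <- mean(vapply(detected, function(p) any(abs(truth - p) <= w), TRUE))
  c(sensitivity = sens, precision = prec)
}
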