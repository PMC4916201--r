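test_that("high-pass preprocessing removes DC and spares cardiac frequencies", {
  fs <- 256
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  # constant offset vanishes
  out <- preprocess_ecg(rep(3.7, length(t)), fs)
  expect_lt(max(abs(out)), 1e-6)
  # 1 Hz component passes within 1%
  x <- sin(2 * pi * 1 * t)
  out2 <- preprocess_ecg(x, fs)
  mid <- seq(fs, length(t) - fs)  # ignore wrap-around edges
  expect_equal(stats::sd(out2[mid]), stats::sd(x[mid]), tolerance = 0.01)
  # slow drift is strongly attenuated while the QRS band is untouched
  drift <- sin(2 * pi * 0.01 * t)
  ecg <- generate_ecg(30, fs, 60)$signal
  filt <- preprocess_ecg(drift + ecg, fs)
  # drift band = the bins at/below 0.07 Hz, well under the 0.1 Hz cutoff
  drift_power <- function(z) sum(Mod(stats::fft(z))[2:3]^2)
  expect_lt(drift_power(filt) / drift_power(drift + ecg), 0.01)  # >= 20 dB
  # QRS-band energy is preserved
  qrs_power <- function(z) {
    sp <- Mod(stats::fft(z))^2
    k <- round(c(5, 15) * 30) + 1  # 30 s record -> 1/30 Hz bins
    sum(sp[k[1]:k[2]])
  }
  expect_equal(qrs_power(filt), qrs_power(drift + ecg), tolerance = 0.01)
  expect_error(preprocess_ecg(ecg[1:100], fs), "10 s")
})

test_that("Pan-Tompkins finds every beat of a regular rhythm", {
  e <- generate_ecg(120, 256, 60)
  peaks <- detect_r_peaks(preprocess_ecg(e$signal, 256), 256)
  expect_true(abs(length(peaks) - 120) <= 1)
  expect_true(all(abs(diff(peaks) / 256 - 1.0) < 0.02))
  sc <- score_detection(peaks, e$peak_indices, 256)
  expect_equal(unname(sc), c(1, 1))
})

test_that("jittered beats are still detected perfectly and amplitude-invariantly", {
  e <- generate_ecg(120, 256, 72, jitter_sd_s = 0.02, seed = 7)
  filt <- preprocess_ecg(e$signal, 256)
  peaks <- detect_r_peaks(filt, 256)
  sc <- score_detection(peaks, e$peak_indices, 256)
  expect_equal(unname(sc), c(1, 1))
  # scaling the trace must not move a single peak
  peaks2 <- detect_r_peaks(filt * 0.013, 256)
  expect_identical(peaks, peaks2)
  peaks3 <- detect_r_peaks(filt * 250, 256)
  expect_identical(peaks, peaks3)
})

test_that("flat input is a detection error", {
  expect_error(detect_r_peaks(rep(0, 256 * 30), 256), "flat")
})

test_that("NN intervals: arithmetic, plausibility cleaning, failure modes", {
  expect_equal(nn_intervals(c(0, 128, 256) + 1L, 128),
               c(1, 1), ignore_attr = TRUE)
  p <- as.integer(round(seq(0, by = 0.8 * 128, length.out = 99))) + 1L
  nn <- nn_intervals(p, 128)
  expect_length(nn, 98)
  expect_true(all(abs(nn - 0.8) < 0.01))
  # a spurious extra peak creating a 0.1 s interval is dropped
  expect_message(
    nn2 <- nn_intervals(c(1L, 129L, 142L, 257L), 128),
    "discarded 1")
  expect_equal(attr(nn2, "discarded"), 1)
  expect_length(nn2, 2)
  expect_error(nn_intervals(c(1L), 128), "at least 2")
  expect_error(nn_intervals(c(1L, 5L), 128), "plausibility")
})

test_that("cardiac frequency is the inverted mean NN", {
  expect_equal(cardiac_frequency(c(0.8, 0.8, 0.8)), 1.25)
  expect_equal(cardiac_frequency(1.0), 1.0)
  expect_equal(cardiac_frequency(c(0.75, 0.85)), 1.25)
  expect_error(cardiac_frequency(numeric(0)), "no NN")
})

test_that("harmonic structure doubles exactly and anchors at i = 0", {
  s <- 1.17
  f <- harmonic_frequency(s, 0:6)
  expect_equal(f[1], s)
  expect_equal(f[-1] / f[-7], rep(2, 6))
  expect_equal(theoretical_iaf(s), 8 * s)
  expect_equal(theoretical_iaf(1.348), 10.784)
  expect_error(harmonic_frequency(1.25, -1), "non-negative")
  expect_error(harmonic_frequency(0, 1), "> 0")
})

test_that("end-to-end chain recovers the heart rate across 50-90 bpm", {
  for (bpm in c(50, 60, 72, 75, 90)) {
    e <- generate_ecg(60, 256, bpm)
    res <- analyze_ecg(e$signal, 256)
    expect_equal(res$s_hz, bpm / 60, tolerance = 0.01)
    expect_equal(res$theoretical_iaf_hz, 8 * bpm / 60, tolerance = 0.01)
    expect_equal(length(res$nn_intervals_s), length(res$r_peak_indices) - 1L)
  }
})
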