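test_that("generators are bit-reproducible pure functions of config + seed", {
  cfg <- synth_eeg_config(duration_s = 20, seed = 9)
  a <- generate_eeg_pair(cfg)
  b <- generate_eeg_pair(cfg)
  expect_identical(a$ec$data, b$ec$data)
  expect_identical(a$eo$data, b$eo$data)
  expect_false(identical(a$ec$data, a$eo$data))  # independent streams

  e1 <- generate_ecg(20, 256, 70, jitter_sd_s = 0.02, seed = 4)
  e2 <- generate_ecg(20, 256, 70, jitter_sd_s = 0.02, seed = 4)
  expect_identical(e1$signal, e2$signal)

  p1 <- sample_model_psd(model_params(1, 50, -1.2, 8, 10, 1),
                         seq(2, 35, 0.25), 0.05, seed = 2)
  p2 <- sample_model_psd(model_params(1, 50, -1.2, 8, 10, 1),
                         seq(2, 35, 0.25), 0.05, seed = 2)
  expect_identical(p1$power, p2$power)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_eeg_pair(synth_eeg_config(duration_s = 16, seed = 1)))
  invisible(generate_ecg(20, 128, 60, jitter_sd_s = 0.01, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("config invariants are checked", {
  expect_error(synth_eeg_config(duration_s = 10), ">= 16")
  expect_error(synth_eeg_config(alpha_amp_ec = 1, alpha_amp_eo = 2),
               "alpha_amp_ec")
  expect_error(generate_eeg_pair(list()), "synth_eeg_config")
  expect_error(generate_ecg(0, 128, 60), "> 0")
  expect_error(generate_ecg(20, 128, 300), "bpm")
})

test_that("noiseless model PSD sampler returns the model exactly", {
  params <- model_params(1, 50, -1.2, 8, 10, 1)
  freqs <- seq(2, 35, by = 0.25)
  psd <- sample_model_psd(params, freqs, 0)
  expect_equal(psd$power[1, ], model_psd(freqs, params))
})

test_that("synthetic EEG is stationary across thirds of the recording", {
  pair <- generate_eeg_pair(synth_eeg_config(duration_s = 90, seed = 14))
  x <- pair$ec$data[1, ]
  n <- length(x)
  v <- sapply(split(x, rep(1:3, each = n / 3)), stats::var)
  expect_true(max(v) / min(v) < 1.2 / 0.8)
})

test_that("strong reactivity is recovered; no reactivity is mostly invalid", {
  pair <- generate_eeg_pair(synth_eeg_config(seed = 5))
  res <- estimate_iaf(welch_psd(pair$ec), welch_psd(pair$eo))
  expect_true(res$valid)
  expect_lt(abs(res$iaf_hz - 10.25), 0.2501)  # within one bin

  invalid <- sum(sapply(1:20, function(s) {
    pair <- generate_eeg_pair(synth_eeg_config(
      duration_s = 60, seed = s, alpha_amp_ec = 1, alpha_amp_eo = 1))
    !estimate_iaf(welch_psd(pair$ec), welch_psd(pair$eo))$valid
  }))
  expect_gt(invalid, 10)
})

test_that("regular synthetic ECG carries its stated rhythm", {
  e <- generate_ecg(120, 256, 75)
  expect_length(e$peak_times_s, 150)
  expect_true(all(abs(diff(e$peak_times_s) - 0.8) < 1e-9))
  expect_equal(cardiac_frequency(diff(e$peak_times_s)), 1.25)
})
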