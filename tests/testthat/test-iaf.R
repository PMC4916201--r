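test_that("reactivity spectrum is the raw EC-EO difference, sign preserved", {
  pair <- bump_psd_pair(10.25)
  d <- reactivity_spectrum(pair$ec, pair$eo, "O1")
  expect_equal(d, pair$bump, tolerance = 1e-12)
  # identical inputs -> all zero
  expect_true(all(reactivity_spectrum(pair$eo, pair$eo, "O2") == 0))
  # EO above EC -> negative entries survive (no clipping)
  d2 <- reactivity_spectrum(pair$eo, pair$ec, "O1")
  expect_true(any(d2 < 0))
  expect_equal(d2, -d)
})

test_that("mismatched grids and missing channels are refused", {
  pair <- bump_psd_pair(10)
  other <- bump_psd_pair(10, epoch_seconds = 2)
  expect_error(reactivity_spectrum(pair$ec, other$eo, "O1"), "grid")
  expect_error(reactivity_spectrum(pair$ec, pair$eo, "Cz"), "not found")
})

test_that("estimate_iaf finds constructed bumps and builds the 2 Hz bands", {
  pair <- bump_psd_pair(10.25)
  res <- estimate_iaf(pair$ec, pair$eo)
  expect_true(res$valid)
  expect_equal(res$iaf_hz, 10.25)
  expect_equal(unname(res$peak_hz_per_channel), c(10.25, 10.25))
  expect_equal(res$lower_band_hz, c(8.25, 10.25))
  expect_equal(res$upper_band_hz, c(10.25, 12.25))
})

test_that("IAF is the mean of per-channel peak frequencies", {
  pair <- bump_psd_pair(9.75)   # O1 bump at 9.75
  pair2 <- bump_psd_pair(10.25) # O2 bump at 10.25
  ec <- pair$ec
  i2 <- which(toupper(ec$labels) == "O2")
  ec$power[i2, ] <- pair2$ec$power[i2, ]
  res <- estimate_iaf(ec, pair$eo)
  expect_equal(unname(res$peak_hz_per_channel), c(9.75, 10.25))
  expect_equal(res$iaf_hz, 10.0)
})

test_that("zero difference yields an invalid result with diagnostics, never 0", {
  pair <- bump_psd_pair(10)
  res <- estimate_iaf(pair$eo, pair$eo)
  expect_false(res$valid)
  expect_true(is.na(res$iaf_hz))
  expect_match(res$diagnostic[1], "O1")
  expect_null(res$lower_band_hz)
})

test_that("shifting the bump by k bins shifts the IAF by exactly k bins", {
  for (k in c(-4, 1, 6)) {
    f0 <- 10 + k * 0.25
    res <- estimate_iaf(bump_psd_pair(f0)$ec, bump_psd_pair(f0)$eo)
    expect_equal(res$iaf_hz, f0)
  }
})

test_that("IAF is invariant to a common positive gain", {
  cfg <- synth_eeg_config(duration_s = 60, seed = 21)
  pair <- generate_eeg_pair(cfg)
  r1 <- estimate_iaf(welch_psd(pair$ec), welch_psd(pair$eo))
  gain <- 7.3
  scaled <- lapply(pair, function(r)
    recording(r$data * gain, r$sample_rate_hz, r$labels, r$condition))
  r2 <- estimate_iaf(welch_psd(scaled$ec), welch_psd(scaled$eo))
  expect_equal(r1$iaf_hz, r2$iaf_hz)
  expect_equal(r1$peak_hz_per_channel, r2$peak_hz_per_channel)
})

test_that("individual_bands arithmetic and domain", {
  expect_equal(individual_bands(10), list(lower = c(8, 10), upper = c(10, 12)))
  expect_equal(individual_bands(7)$lower, c(5, 7))
  expect_error(individual_bands(2), "> 2")
})
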