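test_that("model_psd evaluates the closed form", {
  # degenerate constant model
  p0 <- model_params(3, 0, 0, 0, 10, 1)
  expect_equal(model_psd(c(1, 5, 30), p0), rep(3, 3))
  # hand arithmetic: 1 + 50*10^-1.2 at x = 10, no peak
  p1 <- model_params(1, 50, -1.2, 0, 10, 1)
  expect_equal(model_psd(10, p1), 1 + 50 * 10^-1.2, tolerance = 1e-12)
  # Gaussian maximum adds A3/(sigma*sqrt(2*pi)) at x = mu
  p2 <- model_params(1, 50, -1.2, 8, 10, 1)
  expect_equal(model_psd(10, p2) - model_psd(10, p1), 8 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_error(model_psd(c(0, 10), p2), "<= 0")
})

test_that("model_params validates its invariants", {
  expect_error(model_params(-1, 1, -1, 1, 10, 1), ">= 0")
  expect_error(model_params(1, 1, 0.5, 1, 10, 1), "k2")
  expect_error(model_params(1, 1, -1, 1, 10, 0), "sigma")
  expect_error(model_params(1, 1, -1, 1, 10, 1, A3b = 1, mub = 9, sigmab = 1),
               "mub > mu")
})

test_that("noiseless single-peak parameters are recovered to 1e-3 relative", {
  truth <- c(k1 = 1, A2 = 50, k2 = -1.2, A3 = 8, mu = 10, sigma = 1)
  psd <- sample_model_psd(model_params(1, 50, -1.2, 8, 10, 1),
                          seq(2, 35, by = 0.25), 0)
  fit <- fit_psd_model(psd, "C3", two_peaks = FALSE)
  expect_true(fit$converged)
  got <- unlist(fit$params[names(truth)])
  expect_true(all(abs(got / truth - 1) < 1e-3))
})

test_that("two bumps are located within a bin each", {
  params <- model_params(1, 50, -1.2, 8, 10, 1, A3b = 4, mub = 20, sigmab = 1.5)
  psd <- sample_model_psd(params, seq(2, 35, by = 0.25), 0)
  fit <- fit_psd_model(psd, "C3", two_peaks = TRUE)
  expect_true(fit$converged)
  expect_equal(fit$params$mu, 10, tolerance = 0.025)
  expect_equal(fit$params$mub, 20, tolerance = 0.0125)
})

test_that("peakless power-law input fits with a vanishing peak", {
  psd <- sample_model_psd(model_params(0.5, 40, -1.3, 0, 10, 1),
                          seq(2, 35, by = 0.25), 0)
  fit <- fit_psd_model(psd, "C3", two_peaks = FALSE)
  expect_lt(fit$params$A3 / (fit$params$sigma * sqrt(2 * pi)),
            1e-6 * max(psd$power))
  pr <- compute_predictor(fit, psd)
  expect_equal(pr$index, 0, tolerance = 1e-6)
  expect_equal(pr$method, "psd_minus_powerlaw")  # degenerate -> fallback
})

test_that("primary index equals the Gaussian closed form and is monotone in A3", {
  idx <- vapply(c(4, 8, 16), function(a3) {
    psd <- sample_model_psd(model_params(1, 50, -1.2, a3, 10, 1),
                            seq(2, 35, by = 0.25), 0)
    fit <- fit_psd_model(psd, "C3", two_peaks = FALSE)
    pr <- compute_predictor(fit, psd)
    expect_equal(pr$method, "model_minus_powerlaw")
    expect_equal(signif(pr$index, 4), signif(a3 / sqrt(2 * pi), 4))
    pr$index
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("predictor scales linearly with a uniform PSD gain", {
  psd <- sample_model_psd(model_params(1, 50, -1.2, 8, 10, 1),
                          seq(2, 35, by = 0.25), 0.05, seed = 3)
  c_gain <- 4.2
  psd2 <- psd
  psd2$power <- psd$power * c_gain
  p1 <- compute_predictor(fit_psd_model(psd, "C3", two_peaks = FALSE), psd)
  p2 <- compute_predictor(fit_psd_model(psd2, "C3", two_peaks = FALSE), psd2)
  expect_equal(p2$index / p1$index, c_gain, tolerance = 1e-2)
})

test_that("non-converged fit on a peaked PSD falls back to PSD - power law", {
  psd <- sample_model_psd(model_params(1, 50, -1.2, 8, 10, 1),
                          seq(2, 35, by = 0.25), 0)
  fit <- fit_psd_model(psd, "C3", two_peaks = FALSE)
  fit$converged <- FALSE  # deliberately failed fit
  pr <- compute_predictor(fit, psd)
  expect_equal(pr$method, "psd_minus_powerlaw")
  expect_gt(pr$index, 0)
})

test_that("noisy replicates recover k2, mu, sigma with small median error", {
  errs <- sapply(1:30, function(s) {
    psd <- sample_model_psd(model_params(1, 50, -1.2, 8, 10, 1),
                            seq(2, 35, by = 0.25), 0.05, seed = s)
    fit <- fit_psd_model(psd, "C3", two_peaks = FALSE)
    abs(c(fit$params$k2 / -1.2, fit$params$mu / 10, fit$params$sigma / 1) - 1)
  })
  expect_true(all(apply(errs, 1, stats::median) <= 0.05))
})

test_that("degenerate inputs raise data errors, whole-channel wrapper combines", {
  psd <- sample_model_psd(model_params(1, 50, -1.2, 8, 10, 1),
                          seq(2, 35, by = 0.25), 0)
  psd0 <- psd; psd0$power[] <- 0
  expect_error(fit_psd_model(psd0, "C3"), "degenerate")
  expect_error(fit_psd_model(psd, "C3", fit_band_hz = c(2, 5)), "20")

  psd2 <- psd
  psd2$power <- rbind(psd$power, psd$power * 2)
  psd2$labels <- c("C3", "C4")
  res <- predictor_index(psd2, two_peaks = FALSE)
  expect_equal(res$combined, mean(res$index_per_channel))
  expect_named(res$method_per_channel, c("C3", "C4"))
})
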