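#' Spectral model parameters
#'
#' Parameters of the resting-EEG spectral model
#' \deqn{P(x) = k_1 + A_2 x^{k_2} + \frac{A_3}{\sigma\sqrt{2\pi}}
#'   e^{-(x-\mu)^2 / 2\sigma^2} (+ \text{optional beta peak})}
#' i.e. a constant floor, an aperiodic power law and one or two Gaussian
#' probability-density peaks (alpha, and optionally its beta harmonic).
#'
#' @param k1 Constant floor (>= 0).
#' @param A2 Power-law amplitude (>= 0).
#' @param k2 Power-law exponent (<= 0).
#' @param A3 Alpha-peak area (>= 0).
#' @param mu Alpha-peak center, Hz.
#' @param sigma Alpha-peak width, Hz (> 0).
#' @param A3b,mub,sigmab Optional beta-peak area/center/width; all three
#'   or none, and `mub > mu`.
#' @return A `bci_model_params` list.
#' @export
model_params <- function(k1, A2, k2, A3, mu, sigma,
                         A3b = NULL, mub = NULL, sigmab = NULL) {
  beta <- !is.null(A3b)
  if (beta && (is.null(mub) || is.null(sigmab)))
    stop("beta peak needs all of A3b, mub, sigmab", call. = FALSE)
  if (k1 < 0 || A2 < 0 || A3 < 0) stop("k1, A2, A3 must be >= 0", call. = FALSE)
  if (k2 > 0) stop("power-law exponent k2 must be <= 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (beta) {
    if (A3b < 0 || sigmab <= 0) stop("invalid beta-peak parameters", call. = FALSE)
    if (mub <= mu) stop("beta peak must lie above the alpha peak (mub > mu)",
                        call. = FALSE)
  }
  structure(list(k1 = k1, A2 = A2, k2 = k2, A3 = A3, mu = mu, sigma = sigma,
                 A3b = A3b, mub = mub, sigmab = sigmab),
            class = "bci_model_params")
}

gauss_peak <- function(x, area, mu, sigma) {
  area / (sigma * sqrt(2 * pi)) * exp(-(x - mu)^2 / (2 * sigma^2))
}

#' Evaluate the spectral model
#'
#' @param freqs Strictly positive frequency grid, Hz.
#' @param params A [model_params()] object.
#' @return Numeric vector of model power at `freqs`.
#' @examples
#' p <- model_params(1, 50, -1.2, 8, 10, 1)
#' model_psd(10, p)  # 1 + 50*10^-1.2 + 8/sqrt(2*pi)
#' @export
model_psd <- function(freqs, params) {
  if (any(freqs <= 0))
    stop("model undefined at frequencies <= 0 (power law)", call. = FALSE)
  out <- params$k1 + params$A2 * freqs^params$k2 +
    gauss_peak(freqs, params$A3, params$mu, params$sigma)
  if (!is.null(params$A3b))
    out <- out + gauss_peak(freqs, params$A3b, params$mub, params$sigmab)
  out
}

#' Power-law (aperiodic) component of the model
#' @inheritParams model_psd
#' @return `k1 + A2 * freqs^k2`.
#' @export
power_law <- function(freqs, params) {
  params$k1 + params$A2 * freqs^params$k2
}

#' Fit the spectral model to one channel of a PSD
#'
#' Bounded nonlinear least squares on linear power over `fit_band_hz`,
#' with multi-start (3 restarts, jittered alpha-center initialization).
#' The alpha-peak center is initialized at `iaf_hz` when supplied, else
#' at the tallest in-band local maximum; with `two_peaks = TRUE` a second
#' Gaussian (beta peak) is initialized at twice the alpha center and
#' bounded to 15-30 Hz. Optimizer failure on all restarts yields
#' `converged = FALSE`, never an error.
#'
#' @param psd A `bci_psd`.
#' @param channel Channel label to fit (e.g. `"C3"`).
#' @param iaf_hz Optional IAF used to initialize (and tighten the bounds
#'   of) the alpha-peak center.
#' @param fit_band_hz Frequency band fitted, default `c(2, 35)`.
#' @param two_peaks Fit the additional beta peak (default `TRUE`).
#' @param log_power Fit in dB (10*log10) instead of linear power.
#' @return A `bci_spectral_fit`: `params`, `fitted`, `power_law`,
#'   `freqs_hz`, `residual_rms`, `converged`, `fit_band_hz`, `channel`.
#' @export
fit_psd_model <- function(psd, channel, iaf_hz = NULL,
                          fit_band_hz = c(2, 35), two_peaks = TRUE,
                          log_power = FALSE) {
  ch <- resolve_channels(psd, channel)
  freqs <- psd$freqs_hz
  keep <- which(freqs >= fit_band_hz[1] & freqs <= fit_band_hz[2] & freqs > 0)
  if (length(keep) < 20L)
    stop("fewer than 20 frequency bins in the fit band", call. = FALSE)
  x <- freqs[keep]
  y <- psd$power[ch, keep]
  if (all(y == 0)) stop("degenerate PSD: all zero in fit band", call. = FALSE)

  pmax_y <- max(y)
  mu0 <- if (!is.null(iaf_hz) && is.finite(iaf_hz)) iaf_hz else tallest_peak(x, y)
  mu_lo <- if (!is.null(iaf_hz) && is.finite(iaf_hz)) max(iaf_hz - 2, 2) else 7
  mu_hi <- if (!is.null(iaf_hz) && is.finite(iaf_hz)) iaf_hz + 2 else 14
  mu0 <- min(max(mu0, mu_lo), mu_hi)

  k1_0 <- max(min(y), 1e-12)
  k2_0 <- -1
  A2_0 <- max((y[1] - k1_0), 1e-9) / x[1]^k2_0
  pl0 <- k1_0 + A2_0 * x^k2_0
  A3_0 <- max(stats::approx(x, y - pl0, xout = mu0, rule = 2)$y, 1e-6) * sqrt(2 * pi)

  lower <- c(k1 = 0, A2 = 0, k2 = -3, A3 = 0, mu = mu_lo, sigma = 0.25)
  upper <- c(k1 = pmax_y, A2 = Inf, k2 = 0, A3 = Inf, mu = mu_hi, sigma = 4)
  theta0 <- c(k1 = k1_0, A2 = A2_0, k2 = k2_0, A3 = A3_0, mu = mu0, sigma = 1)
  if (two_peaks) {
    mub0 <- min(max(2 * mu0, 16), 29)
    lower <- c(lower, A3b = 0, mub = 15, sigmab = 0.25)
    upper <- c(upper, A3b = Inf, mub = 30, sigmab = 6)
    theta0 <- c(theta0, A3b = A3_0 / 4, mub = mub0, sigmab = 1.5)
  }

  transform_y <- function(v) if (log_power) 10 * log10(pmax(v, 1e-300)) else v
  yt <- transform_y(y)
  sse <- function(theta) {
    m <- eval_theta(x, theta, two_peaks)
    sum((transform_y(m) - yt)^2)
  }

  run_opt <- function(th) tryCatch(
    stats::nlminb(th, sse, lower = lower, upper = upper,
                  scale = 1 / pmax(abs(th), 1e-3),
                  control = list(iter.max = 500L, eval.max = 1500L)),
    error = function(e) NULL)

  # multi-start: jittered alpha-center inits plus a peakless start so a
  # pure power-law spectrum is fitted with the peak terms held at zero
  starts <- lapply(c(0, -1, 1), function(j) {
    th <- theta0
    th["mu"] <- min(max(theta0[["mu"]] + j, mu_lo), mu_hi)
    th
  })
  th_flat <- theta0
  th_flat["A3"] <- 0
  if (two_peaks) th_flat["A3b"] <- 0
  starts <- c(starts, list(th_flat))

  best <- NULL
  for (th in starts) {
    fit <- run_opt(th)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }

  if (is.null(best)) {
    theta <- theta0
    converged <- FALSE
  } else {
    theta <- best$par
    names(theta) <- names(theta0)
    converged <- best$convergence == 0L
  }
  params <- theta_to_params(theta, two_peaks)
  fitted <- model_psd(x, params)
  pl <- power_law(x, params)
  structure(
    list(params = params, fitted = fitted, power_law = pl, freqs_hz = x,
         observed = y,
         residual_rms = sqrt(mean((fitted - y)^2)),
         converged = converged, fit_band_hz = fit_band_hz,
         channel = psd$labels[ch]),
    class = "bci_spectral_fit")
}

eval_theta <- function(x, theta, two_peaks) {
  m <- theta[["k1"]] + theta[["A2"]] * x^theta[["k2"]] +
    gauss_peak(x, theta[["A3"]], theta[["mu"]], theta[["sigma"]])
  if (two_peaks)
    m <- m + gauss_peak(x, theta[["A3b"]], theta[["mub"]], theta[["sigmab"]])
  m
}

theta_to_params <- function(theta, two_peaks) {
  # clamp tiny numeric excursions outside bounds before validation
  p <- structure(as.list(theta), names = names(theta))
  params <- list(k1 = max(p$k1, 0), A2 = max(p$A2, 0), k2 = min(p$k2, 0),
                 A3 = max(p$A3, 0), mu = p$mu, sigma = max(p$sigma, 1e-6),
                 A3b = NULL, mub = NULL, sigmab = NULL)
  if (two_peaks) {
    params$A3b <- max(p$A3b, 0)
    params$mub <- max(p$mub, p$mu + 1e-6)
    params$sigmab <- max(p$sigmab, 1e-6)
  }
  class(params) <- "bci_model_params"
  params
}

tallest_peak <- function(x, y, band = c(7, 14)) {
  in_b <- which(x >= band[1] & x <= band[2])
  if (length(in_b) == 0L) in_b <- seq_along(x)
  cand <- in_b[y[in_b] == max(y[in_b])][1]
  # prefer a local maximum if one exists in the band
  loc <- in_b[in_b > 1 & in_b < length(y)]
  loc <- loc[y[loc] >= y[loc - 1] & y[loc] >= y[loc + 1]]
  if (length(loc)) cand <- loc[which.max(y[loc])]
  x[cand]
}

#' Neurophysiological predictor index for one fitted channel
#'
#' The primary index is the maximum elevation of the fitted model above
#' its power-law component over the fit band. When the fit failed to
#' converge, or the model degenerates onto the power law (primary index
#' below `degenerate_tol` times the in-band PSD maximum), the fallback
#' is used instead: the maximum difference between the observed PSD and
#' the power-law model, floored at zero. The method actually used is
#' always recorded.
#'
#' @param fit A `bci_spectral_fit` from [fit_psd_model()].
#' @param psd The `bci_psd` the fit was computed from.
#' @param degenerate_tol Degeneracy threshold, default 0.01.
#' @return List with `index`, `method`
#'   (`"model_minus_powerlaw"` or `"psd_minus_powerlaw"`) and `channel`.
#' @export
compute_predictor <- function(fit, psd, degenerate_tol = 0.01) {
  ch <- resolve_channels(psd, fit$channel)
  keep <- which(psd$freqs_hz >= fit$fit_band_hz[1] &
                  psd$freqs_hz <= fit$fit_band_hz[2] & psd$freqs_hz > 0)
  if (length(keep) != length(fit$freqs_hz) ||
      any(abs(psd$freqs_hz[keep] - fit$freqs_hz) > 1e-9))
    stop("fit and PSD are on different frequency grids", call. = FALSE)
  y <- psd$power[ch, keep]
  primary <- max(fit$fitted - fit$power_law)
  if (fit$converged && primary >= degenerate_tol * max(y)) {
    list(index = primary, method = "model_minus_powerlaw",
         channel = fit$channel)
  } else {
    list(index = max(max(y - fit$power_law), 0),
         method = "psd_minus_powerlaw", channel = fit$channel)
  }
}

#' Predictor indices for a set of central channels
#'
#' Convenience wrapper: fits the spectral model on each channel (C3 and
#' C4 by default) and computes the index with fallback; `combined` is
#' the plain mean across channels (reported for convenience, the
#' per-channel values are the primary outputs).
#'
#' @inheritParams fit_psd_model
#' @param channels Channels to fit, default `c("C3", "C4")`.
#' @param degenerate_tol Passed to [compute_predictor()].
#' @return A `bci_predictor` list: `index_per_channel`,
#'   `method_per_channel`, `combined`, `fits`.
#' @export
predictor_index <- function(psd, channels = c("C3", "C4"), iaf_hz = NULL,
                            fit_band_hz = c(2, 35), two_peaks = TRUE,
                            degenerate_tol = 0.01) {
  fits <- list(); idx <- c(); meth <- c()
  for (ch in channels) {
    f <- fit_psd_model(psd, ch, iaf_hz = iaf_hz, fit_band_hz = fit_band_hz,
                       two_peaks = two_peaks)
    p <- compute_predictor(f, psd, degenerate_tol = degenerate_tol)
    fits[[ch]] <- f
    idx[ch] <- p$index
    meth[ch] <- p$method
  }
  structure(list(index_per_channel = idx, method_per_channel = meth,
                 combined = mean(idx), fits = fits),
            class = "bci_predictor")
}

#' @export
print.bci_predictor <- function(x, ...) {
  cat("<bci_predictor>\n")
  for (ch in names(x$index_per_channel))
    cat(sprintf("  %s: %.4g (%s)\n", ch, x$index_per_channel[[ch]],
                x$method_per_channel[[ch]]))
  cat(sprintf("  combined (mean): %.4g\n", x$combined))
  invisible(x)
}
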