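#' High-pass preprocess an ECG trace
#'
#' Zero-phase high-pass at 0.1 Hz (FFT-domain, raised-cosine edge):
#' removes DC offset and baseline wander while leaving QRS morphology
#' and R-peak timing untouched.
#'
#' @param signal Numeric vector, single-lead ECG.
#' @param sample_rate_hz Sampling rate, Hz. Below 100 Hz a warning is
#'   issued (QRS detection degrades).
#' @param cutoff_hz High-pass cutoff, default 0.1.
#' @return Filtered vector, same length.
#' @export
preprocess_ecg <- function(signal, sample_rate_hz, cutoff_hz = 0.1) {
  if (length(signal) < 10 * sample_rate_hz)
    stop("ECG too short: need at least 10 s of samples", call. = FALSE)
  if (sample_rate_hz < 100)
    warning("ECG sample rate below 100 Hz; QRS detection may be unreliable")
  fft_bandpass(signal, sample_rate_hz, low = cutoff_hz,
               transition_hz = cutoff_hz)
}

#' Pan-Tompkins QRS detection
#'
#' The classic real-time QRS detector run offline with zero-phase
#' filtering: band-pass 5-15 Hz, five-point derivative, squaring, 150 ms
#' moving-window integration, adaptive signal/noise thresholds with a
#' 200 ms refractory period, a 360 ms T-wave slope check, and a
#' missed-beat search-back at 1.66 times the running RR average.
#' Detected fiducials are refined to the local maximum of the band-passed
#' signal.
#'
#' @param signal Numeric ECG vector (ideally from [preprocess_ecg()]).
#' @param sample_rate_hz Sampling rate, Hz.
#' @param bandpass_hz Band-pass edges, default `c(5, 15)`.
#' @param integration_ms Moving-window integration width, default 150.
#' @param refractory_ms Minimum peak spacing, default 200.
#' @param twave_ms T-wave discrimination window, default 360.
#' @return Increasing integer vector of R-peak sample indices (1-based).
#' @export
detect_r_peaks <- function(signal, sample_rate_hz,
                           bandpass_hz = c(5, 15), integration_ms = 150,
                           refractory_ms = 200, twave_ms = 360) {
  fs <- sample_rate_hz
  n <- length(signal)
  if (n < 2 * fs) stop("signal too short for QRS detection", call. = FALSE)
  if (max(signal) - min(signal) <= 0)
    stop("flat signal: no QRS complexes detectable", call. = FALSE)

  bp <- fft_bandpass(signal, fs, low = bandpass_hz[1], high = bandpass_hz[2],
                     transition_hz = 2)
  # five-point derivative (Pan-Tompkins eq.), zero-phase by symmetric lags
  d <- c(0, 0, bp[5:n] + 2 * bp[4:(n - 1)] - 2 * bp[2:(n - 3)] - bp[1:(n - 4)], 0, 0) /
    8 * fs
  sq <- d^2
  mwi <- moving_average(sq, max(1L, round(integration_ms / 1000 * fs)))

  refr <- max(1L, round(refractory_ms / 1000 * fs))
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L  # local maxima of MWI
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0L) stop("no QRS candidates found", call. = FALSE)

  # adaptive thresholding on the integrated waveform
  init_win <- seq_len(min(n, 2L * fs))
  spki <- max(mwi[init_win]) / 3
  npki <- mean(mwi[init_win]) / 2
  thr <- npki + 0.25 * (spki - npki)

  peaks <- integer(0)
  rr_avg <- NA_real_
  recent_rr <- numeric(0)
  last_qrs <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    v <- mwi[p]
    accept <- FALSE
    if (p - last_qrs >= refr) {
      if (v > thr) {
        accept <- TRUE
        # T-wave check: within 360 ms of previous QRS, compare MWI slopes
        if (is.finite(last_qrs) && (p - last_qrs) <= round(twave_ms / 1000 * fs)) {
          sl_now <- max_slope(mwi, p, fs)
          sl_prev <- max_slope(mwi, last_qrs, fs)
          if (sl_now < sl_prev / 2) accept <- FALSE
        }
      }
    }
    if (accept) {
      peaks <- c(peaks, p)
      spki <- 0.125 * v + 0.875 * spki
      if (length(peaks) > 1L) {
        rr <- p - peaks[length(peaks) - 1L]
        recent_rr <- utils::tail(c(recent_rr, rr), 8L)
        rr_avg <- mean(recent_rr)
      }
      last_qrs <- p
    } else {
      spki_keep <- spki
      npki <- 0.125 * v + 0.875 * npki
      # search-back: no beat for 1.66 * RR average -> take best sub-threshold
      if (!is.na(rr_avg) && (p - last_qrs) > 1.66 * rr_avg) {
        win <- cand[cand > last_qrs + refr & cand <= p]
        if (length(win)) {
          sb <- win[which.max(mwi[win])]
          if (mwi[sb] > thr / 2) {
            peaks <- c(peaks, sb)
            spki <- 0.25 * mwi[sb] + 0.75 * spki_keep
            rr <- sb - (if (length(peaks) > 1L) peaks[length(peaks) - 1L] else sb)
            if (rr > 0) {
              recent_rr <- utils::tail(c(recent_rr, rr), 8L)
              rr_avg <- mean(recent_rr)
            }
            last_qrs <- sb
          }
        }
      }
    }
    thr <- npki + 0.25 * (spki - npki)
    i <- i + 1L
  }
  if (length(peaks) == 0L) stop("no QRS complexes detected", call. = FALSE)

  # refine each fiducial to the local band-passed maximum (MWI lags ~ window/2)
  half <- round(integration_ms / 1000 * fs / 2) + refr %/% 2L
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(bp[lo:hi]) - 1L)
  }, integer(1))
  sort(unique(refined))
}

max_slope <- function(x, p, fs) {
  w <- max(1L, round(0.075 * fs))
  lo <- max(2L, p - w)
  hi <- min(length(x), p)
  max(abs(diff(x[lo:hi])), 0)
}

#' NN intervals from R-peak positions
#'
#' Successive R-peak differences in seconds; intervals outside the
#' physiologic plausibility window are discarded (count reported via a
#' `"discarded"` attribute and a message).
#'
#' @param r_peaks Increasing integer vector of R-peak sample indices.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param plausibility_s Retained interval range in seconds,
#'   default `c(0.3, 2.0)` (30-200 bpm).
#' @return Numeric vector of NN intervals in seconds.
#' @export
nn_intervals <- function(r_peaks, sample_rate_hz,
                         plausibility_s = c(0.3, 2.0)) {
  if (length(r_peaks) < 2L)
    stop("need at least 2 R peaks to form an NN interval", call. = FALSE)
  nn <- diff(r_peaks) / sample_rate_hz
  keep <- nn >= plausibility_s[1] & nn <= plausibility_s[2]
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("nn_intervals: discarded %d implausible interval(s)", dropped))
  nn <- nn[keep]
  if (length(nn) == 0L)
    stop("all NN intervals outside the plausibility window", call. = FALSE)
  attr(nn, "discarded") <- dropped
  nn
}

#' Cardiac frequency from NN intervals
#'
#' The NN intervals are averaged and inverted: `s = 1 / mean(nn)`, in Hz.
#'
#' @param nn_s Positive numeric vector of NN intervals, seconds.
#' @return Cardiac frequency in Hz.
#' @examples
#' cardiac_frequency(c(0.8, 0.8, 0.8))  # 1.25 Hz = 75 bpm
#' @export
cardiac_frequency <- function(nn_s) {
  if (length(nn_s) == 0L) stop("no NN intervals", call. = FALSE)
  if (any(nn_s <= 0)) stop("NN intervals must be positive", call. = FALSE)
  1 / mean(nn_s)
}

#' Harmonic brain-body frequency structure
#'
#' The harmonic series `f_d(i) = s * 2^i` that couples the cardiac
#' frequency `s` (found at `i = 0`) to the center frequencies of the
#' canonical EEG bands: i = 1 delta, 2 theta, 3 alpha, 4 beta, 5 gamma.
#'
#' @param s_hz Cardiac frequency, Hz (> 0).
#' @param i Non-negative integer harmonic index (vectorized).
#' @return `s_hz * 2^i`.
#' @examples
#' harmonic_frequency(1.25, 0:5)  # 1.25 2.5 5 10 20 40
#' @export
harmonic_frequency <- function(s_hz, i) {
  if (!is.numeric(s_hz) || any(s_hz <= 0)) stop("s_hz must be > 0", call. = FALSE)
  if (any(i < 0) || any(i != round(i)))
    stop("harmonic index i must be a non-negative integer", call. = FALSE)
  s_hz * 2^i
}

#' Theoretical IAF from cardiac frequency
#'
#' The alpha-band center of the harmonic structure, `f_d(3) = 8 * s`.
#'
#' @param s_hz Cardiac frequency, Hz.
#' @return Theoretical IAF in Hz.
#' @examples
#' theoretical_iaf(1.25)  # 10 Hz
#' @export
theoretical_iaf <- function(s_hz) {
  harmonic_frequency(s_hz, 3L)
}

#' Full cardiac validation chain
#'
#' High-pass preprocessing, Pan-Tompkins R-peak detection, NN-interval
#' extraction and cleaning, cardiac frequency, harmonic series and
#' theoretical IAF in one call.
#'
#' @param signal Raw single-lead ECG vector.
#' @param sample_rate_hz Sampling rate, Hz.
#' @return A `bci_cardiac` list: `r_peak_indices`, `nn_intervals_s`,
#'   `s_hz`, `harmonic_hz` (i = 0..5), `theoretical_iaf_hz`,
#'   `n_discarded_nn`.
#' @export
analyze_ecg <- function(signal, sample_rate_hz) {
  filt <- preprocess_ecg(signal, sample_rate_hz)
  peaks <- detect_r_peaks(filt, sample_rate_hz)
  nn <- nn_intervals(peaks, sample_rate_hz)
  s <- cardiac_frequency(nn)
  structure(
    list(r_peak_indices = peaks,
         nn_intervals_s = as.numeric(nn),
         s_hz = s,
         harmonic_hz = stats::setNames(harmonic_frequency(s, 0:5),
                                       paste0("i", 0:5)),
         theoretical_iaf_hz = theoretical_iaf(s),
         n_discarded_nn = attr(nn, "discarded")),
    class = "bci_cardiac")
}

#' @export
print.bci_cardiac <- function(x, ...) {
  cat(sprintf("<bci_cardiac> %d R peaks, s = %.3f Hz (%.0f bpm), theoretical IAF = %.2f Hz\n",
              length(x$r_peak_indices), x$s_hz, 60 * x$s_hz,
              x$theoretical_iaf_hz))
  invisible(x)
}
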