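#' Welch power spectral density estimate
#'
#' Averaged modified periodogram on overlapping Hann-windowed epochs,
#' density-scaled (microvolts^2/Hz), one-sided. The 4-s default epoch
#' gives a 0.25 Hz frequency resolution; each epoch is constant-detrended
#' and any trailing partial epoch is discarded.
#'
#' @param rec A [recording()].
#' @param epoch_seconds Epoch length in seconds (default 4).
#' @param overlap_fraction Fractional overlap between successive epochs
#'   in `[0, 1)` (default 0.5).
#' @param window Taper, `"hann"` or `"rect"`.
#' @return A `bci_psd`: list with `freqs_hz` (0 .. Nyquist, spacing
#'   `1/epoch_seconds`), `power` (channels x frequencies), `resolution_hz`,
#'   `epoch_seconds`, `labels`.
#' @examples
#' fs <- 128; t <- seq(0, 60 - 1/fs, by = 1/fs)
#' rec <- recording(matrix(sin(2*pi*10*t), 1), fs, "Cz")
#' psd <- welch_psd(rec)
#' psd$freqs_hz[which.max(psd$power[1, ])]  # 10 Hz
#' @export
welch_psd <- function(rec, epoch_seconds = 4, overlap_fraction = 0.5,
                      window = c("hann", "rect")) {
  window <- match.arg(window)
  fs <- rec$sample_rate_hz
  nper <- epoch_seconds * fs
  if (abs(nper - round(nper)) > 1e-9 || round(nper) < 8)
    stop("epoch_seconds * sample_rate must be an integer >= 8", call. = FALSE)
  nper <- as.integer(round(nper))
  if (rec$duration_s < 2 * epoch_seconds)
    stop(sprintf("recording too short: %.1f s, need at least %g s (2 epochs)",
                 rec$duration_s, 2 * epoch_seconds), call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  step <- max(1L, as.integer(round(nper * (1 - overlap_fraction))))
  n <- ncol(rec$data)
  starts <- seq(1L, n - nper + 1L, by = step)

  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(nper) - 1L) / nper)  # periodic Hann
  } else rep(1, nper)
  u <- fs * sum(w^2)  # density normalization

  nfreq <- nper %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1L) / epoch_seconds
  power <- matrix(0, nrow = nrow(rec$data), ncol = nfreq)
  for (ch in seq_len(nrow(rec$data))) {
    acc <- numeric(nfreq)
    for (s in starts) {
      seg <- rec$data[ch, s:(s + nper - 1L)]
      seg <- (seg - mean(seg)) * w
      sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / u
      # one-sided: double everything except DC and (even nper) Nyquist
      sp[2:(nfreq - 1L)] <- 2 * sp[2:(nfreq - 1L)]
      if (nper %% 2L == 1L) sp[nfreq] <- 2 * sp[nfreq]
      acc <- acc + sp
    }
    power[ch, ] <- acc / length(starts)
  }
  structure(
    list(freqs_hz = freqs, power = power,
         resolution_hz = 1 / epoch_seconds, epoch_seconds = epoch_seconds,
         labels = rec$labels, sample_rate_hz = fs),
    class = "bci_psd")
}

#' @export
print.bci_psd <- function(x, ...) {
  cat(sprintf("<bci_psd> %d channels, %g-%g Hz @ %g Hz resolution (%g s epochs)\n",
              nrow(x$power), min(x$freqs_hz), max(x$freqs_hz),
              x$resolution_hz, x$epoch_seconds))
  invisible(x)
}
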