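# Zero-phase FFT-domain filtering.
#
# The transfer function is real and symmetric (zero phase) with
# raised-cosine transition bands, applied by multiplying the full FFT
# and inverting. Adequate for offline recordings of a few minutes;
# avoids hand-rolling IIR filter design.

fft_bandpass <- function(x, fs, low = NULL, high = NULL,
                         transition_hz = NULL) {
  n <- length(x)
  freqs <- (seq_len(n) - 1L) / n * fs
  freqs <- pmin(freqs, fs - freqs)  # two-sided axis folded to [0, fs/2]
  h <- rep(1, n)
  if (!is.null(low) && low > 0) {
    tw <- if (is.null(transition_hz)) max(low / 2, 2 * fs / n) else transition_hz
    h <- h * edge_response(freqs, low, tw, rising = TRUE)
  }
  if (!is.null(high)) {
    tw <- if (is.null(transition_hz)) max(high / 10, 2 * fs / n) else transition_hz
    h <- h * edge_response(freqs, high, tw, rising = FALSE)
  }
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

# raised-cosine step from 0 to 1 (rising) or 1 to 0 across
# [f0 - tw/2, f0 + tw/2]
edge_response <- function(freqs, f0, tw, rising) {
  lo <- f0 - tw / 2
  hi <- f0 + tw / 2
  r <- ifelse(freqs <= lo, 0,
              ifelse(freqs >= hi, 1,
                     0.5 - 0.5 * cos(pi * (freqs - lo) / tw)))
  if (rising) r else 1 - r
}

# moving average of width k samples (centered), edges zero-padded
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - k %/% 2L - 1L)
  hi <- pmin(n, seq_len(n) + (k - 1L) %/% 2L)
  (cs[hi + 1L] - cs[lo + 1L]) / k
}
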