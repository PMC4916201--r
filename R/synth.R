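#' Configuration for the synthetic resting-EEG generator
#'
#' Describes the statistical structure the pipeline assumes: a 1/f^beta
#' aperiodic background on every channel, a band-limited alpha
#' oscillation whose amplitude is larger with eyes closed than open on
#' the reactive (occipital) channels, a sensorimotor (mu) peak on the
#' central channels in both conditions, and additive white sensor noise.
#' Amplitudes are standard deviations in microvolts.
#'
#' @param duration_s Recording length, seconds (>= 16; default 180, the
#'   3-minute resting protocol).
#' @param sample_rate_hz Sampling rate (default 128).
#' @param labels Channel labels (default O1, O2, C3, C4 — the four
#'   channels the pipeline consumes).
#' @param background_exponent 1/f exponent beta (default 1).
#' @param background_scale Background SD, microvolts (default 5).
#' @param alpha_center_hz Alpha center (default 10.25, off-bin-center at
#'   coarser resolutions but exactly on the 0.25 Hz grid of 4-s epochs).
#' @param alpha_bandwidth_hz Alpha bandwidth (default 2).
#' @param alpha_amp_ec,alpha_amp_eo Alpha SD with eyes closed / open on
#'   reactive channels (defaults 4 and 1; EC >= EO required).
#' @param reactive_channels Channels with EC-reactive alpha
#'   (default O1, O2).
#' @param smr_center_hz Sensorimotor peak center (default 11).
#' @param smr_amp Sensorimotor peak SD on C3/C4 (default 2.5).
#' @param noise_sd White-noise SD (default 1).
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @return A `bci_synth_config` list.
#' @export
synth_eeg_config <- function(duration_s = 180, sample_rate_hz = 128,
                             labels = c("O1", "O2", "C3", "C4"),
                             background_exponent = 1, background_scale = 5,
                             alpha_center_hz = 10.25, alpha_bandwidth_hz = 2,
                             alpha_amp_ec = 4, alpha_amp_eo = 1,
                             reactive_channels = c("O1", "O2"),
                             smr_center_hz = 11, smr_amp = 2.5,
                             noise_sd = 1, seed = 1L) {
  if (duration_s < 16) stop("duration_s must be >= 16 s", call. = FALSE)
  if (alpha_amp_eo < 0 || alpha_amp_ec < alpha_amp_eo)
    stop("need alpha_amp_ec >= alpha_amp_eo >= 0", call. = FALSE)
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "bci_synth_config")
}

# 1/f^(beta) power-shaped Gaussian noise with unit variance
pink_noise <- function(n, fs, beta) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)
  amp <- ifelse(f > 0, f^(-beta / 2), 0)
  x <- Re(stats::fft(sp * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# narrow-band Gaussian noise, unit variance: white noise shaped by a
# Gaussian spectral profile (FWHM = bandwidth), so the expected PSD is a
# bell-shaped bump centered at `center` like a physiological alpha peak
narrowband_noise <- function(n, fs, center, bandwidth) {
  white <- stats::rnorm(n)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)
  sf <- bandwidth / 2.355  # FWHM -> Gaussian sigma
  amp <- exp(-(f - center)^2 / (2 * sf^2))
  x <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a paired eyes-closed / eyes-open synthetic EEG recording
#'
#' Each channel is the sum of 1/f background, band-limited alpha (with
#' condition-dependent amplitude on reactive channels), a sensorimotor
#' mu oscillation on C3/C4, and white noise. The EC and EO recordings
#' use independent noise streams derived from the single config seed, so
#' the pair is bit-reproducible.
#'
#' @param config A [synth_eeg_config()].
#' @return List with elements `ec` and `eo`, each a [recording()].
#' @export
generate_eeg_pair <- function(config) {
  if (!inherits(config, "bci_synth_config"))
    stop("config must come from synth_eeg_config()", call. = FALSE)
  old <- globalenv()$.Random.seed
  set.seed(config$seed)
  on.exit(restore_seed(old))
  n <- round(config$duration_s * config$sample_rate_hz)
  out <- list()
  for (cond in c("EC", "EO")) {
    mat <- matrix(0, nrow = length(config$labels), ncol = n)
    for (k in seq_along(config$labels)) {
      ch <- config$labels[k]
      alpha_amp <- if (ch %in% config$reactive_channels) {
        if (cond == "EC") config$alpha_amp_ec else config$alpha_amp_eo
      } else 0
      x <- config$background_scale *
        pink_noise(n, config$sample_rate_hz, config$background_exponent)
      if (alpha_amp > 0)
        x <- x + alpha_amp * narrowband_noise(n, config$sample_rate_hz,
                                              config$alpha_center_hz,
                                              config$alpha_bandwidth_hz)
      if (ch %in% c("C3", "C4") && config$smr_amp > 0)
        x <- x + config$smr_amp * narrowband_noise(n, config$sample_rate_hz,
                                                   config$smr_center_hz,
                                                   config$alpha_bandwidth_hz)
      if (config$noise_sd > 0)
        x <- x + stats::rnorm(n, sd = config$noise_sd)
      mat[k, ] <- x
    }
    out[[tolower(cond)]] <- recording(mat, config$sample_rate_hz,
                                      config$labels, cond)
  }
  out
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Sample a noisy PSD from the spectral model
#'
#' Direct sampler of the constant + power-law + peak model for fit
#' testing: `model_psd(freqs, params) * (1 + eps)` with zero-mean
#' Gaussian relative noise, clipped so power stays positive.
#'
#' @param params A [model_params()].
#' @param freqs Strictly positive frequency grid, Hz.
#' @param noise_sd_fraction Relative noise SD (0 = noiseless).
#' @param seed Integer RNG seed.
#' @param labels Channel label for the single synthetic channel.
#' @return A `bci_psd` with one channel.
#' @export
sample_model_psd <- function(params, freqs, noise_sd_fraction = 0,
                             seed = 1L, labels = "C3") {
  clean <- model_psd(freqs, params)
  if (noise_sd_fraction > 0) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(restore_seed(old))
    eps <- stats::rnorm(length(freqs), sd = noise_sd_fraction)
    clean <- clean * pmax(1 + eps, 1e-6)
  }
  df <- diff(freqs)[1]
  structure(
    list(freqs_hz = freqs, power = matrix(clean, nrow = 1),
         resolution_hz = df, epoch_seconds = 1 / df,
         labels = labels, sample_rate_hz = 2 * max(freqs)),
    class = "bci_psd")
}

#' Generate a synthetic single-lead ECG
#'
#' Morphological beat template (narrow R spike with Q/S deflections plus
#' smaller P and T bumps) repeated at the requested heart rate with
#' optional Gaussian timing jitter. Returns ground-truth R-peak times
#' for scoring detection.
#'
#' @param duration_s Length in seconds (> 0).
#' @param sample_rate_hz Sampling rate, Hz.
#' @param bpm Heart rate, beats per minute, in (20, 240).
#' @param jitter_sd_s SD of beat-time jitter, seconds (0 = regular).
#' @param seed Integer RNG seed (used only when jitter > 0).
#' @return List: `signal` (numeric vector), `peak_times_s`,
#'   `peak_indices` (1-based), `sample_rate_hz`.
#' @export
generate_ecg <- function(duration_s, sample_rate_hz, bpm,
                         jitter_sd_s = 0, seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  if (bpm <= 20 || bpm >= 240) stop("bpm must be in (20, 240)", call. = FALSE)
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  period <- 60 / bpm
  # margins leave room for the P wave before the first R and keep
  # duration/period beats in the record (e.g. 150 beats in 120 s at 75 bpm)
  beats <- seq(0.4, duration_s - 0.35, by = period)
  if (jitter_sd_s > 0) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(restore_seed(old))
    beats <- beats + stats::rnorm(length(beats), sd = jitter_sd_s)
    beats <- sort(beats[beats > 0.1 & beats < duration_s - 0.1])
  }
  # bump: amplitude, center offset (s), width (s)
  template <- rbind(
    c(0.15, -0.20, 0.025),   # P
    c(-0.10, -0.028, 0.010), # Q
    c(1.00, 0.000, 0.012),   # R
    c(-0.20, 0.030, 0.010),  # S
    c(0.30, 0.30, 0.060))    # T
  sig <- numeric(n)
  for (b in beats) {
    for (r in seq_len(nrow(template))) {
      a <- template[r, 1]; off <- template[r, 2]; w <- template[r, 3]
      lo <- max(1L, floor((b + off - 5 * w) * fs) + 1L)
      hi <- min(n, ceiling((b + off + 5 * w) * fs) + 1L)
      if (lo <= hi) {
        idx <- lo:hi
        sig[idx] <- sig[idx] + a * exp(-(t[idx] - b - off)^2 / (2 * w^2))
      }
    }
  }
  list(signal = sig, peak_times_s = beats,
       peak_indices = round(beats * fs) + 1L, sample_rate_hz = fs)
}
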