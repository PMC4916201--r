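#' Eyes-closed minus eyes-open reactivity spectrum
#'
#' The raw difference PSD_EC - PSD_EO for one channel. Closing the eyes
#' enhances occipital alpha power, so the difference peaks at the
#' subject's alpha frequency; negative values are preserved (no clipping).
#'
#' @param psd_ec,psd_eo `bci_psd` objects on an identical frequency grid.
#' @param channel Channel label present in both.
#' @return Numeric vector, same length as the frequency grid.
#' @export
reactivity_spectrum <- function(psd_ec, psd_eo, channel) {
  check_same_grid(psd_ec, psd_eo)
  i_ec <- resolve_channels(psd_ec, channel)
  i_eo <- resolve_channels(psd_eo, channel)
  psd_ec$power[i_ec, ] - psd_eo$power[i_eo, ]
}

check_same_grid <- function(a, b) {
  if (length(a$freqs_hz) != length(b$freqs_hz) ||
      any(abs(a$freqs_hz - b$freqs_hz) > 1e-9))
    stop("PSD frequency grids differ; recompute with equal epoch settings",
         call. = FALSE)
  invisible(TRUE)
}

#' Estimate the individual alpha frequency
#'
#' Per channel (occipital O1/O2 by default) the peak of the EC-EO
#' reactivity spectrum inside `search_band_hz` is located; the IAF is the
#' arithmetic mean of the per-channel peak frequencies. The estimate is
#' flagged invalid unless every channel shows a strictly positive
#' EC-EO difference at its peak (i.e. genuine alpha reactivity). From a
#' valid IAF the two individualized 2-Hz alpha sub-bands
#' (IAF-2, IAF) and (IAF, IAF+2) are derived.
#'
#' @param psd_ec,psd_eo `bci_psd` of the eyes-closed / eyes-open
#'   recordings on the same grid.
#' @param channels Channels to use, default `c("O1", "O2")`.
#' @param search_band_hz Frequency window searched for the reactivity
#'   peak, default `c(7, 14)`.
#' @param smooth If `TRUE`, apply a 3-bin moving average to the
#'   difference spectrum before peak picking (off by default).
#' @return A `bci_iaf` list: `peak_hz_per_channel`, `iaf_hz` (`NA` when
#'   invalid), `lower_band_hz`, `upper_band_hz`, `search_band_hz`,
#'   `valid`, `diagnostic`, `diff_spectra`, `freqs_hz`.
#' @export
estimate_iaf <- function(psd_ec, psd_eo, channels = c("O1", "O2"),
                         search_band_hz = c(7, 14), smooth = FALSE) {
  check_same_grid(psd_ec, psd_eo)
  if (abs(psd_ec$epoch_seconds - psd_eo$epoch_seconds) > 1e-12)
    stop("EC and EO PSDs must use equal epoch lengths", call. = FALSE)
  freqs <- psd_ec$freqs_hz
  in_band <- which(freqs >= search_band_hz[1] & freqs <= search_band_hz[2])
  if (length(in_band) < 2L)
    stop("search band contains fewer than 2 frequency bins", call. = FALSE)

  peaks <- stats::setNames(numeric(length(channels)), channels)
  diffs <- list()
  diagnostic <- character(0)
  valid <- TRUE
  for (ch in channels) {
    d <- reactivity_spectrum(psd_ec, psd_eo, ch)
    diffs[[ch]] <- d
    ds <- if (smooth) moving_average(d, 3L) else d
    k <- in_band[which.max(ds[in_band])]  # which.max ties -> lowest freq
    peaks[[ch]] <- freqs[k]
    # reactivity must be genuine: the positive peak must exist and also
    # dominate any negative excursion in the band (a noise-only
    # difference spectrum is symmetric, so its maximum rarely does)
    if (!(ds[k] > 0) || ds[k] <= -min(ds[in_band])) {
      valid <- FALSE
      diagnostic <- c(diagnostic, sprintf(
        "channel %s: no dominant positive EC-EO difference in %g-%g Hz",
        ch, search_band_hz[1], search_band_hz[2]))
    }
  }
  iaf <- if (valid) mean(peaks) else NA_real_
  structure(
    list(peak_hz_per_channel = peaks,
         iaf_hz = iaf,
         lower_band_hz = if (valid) individual_bands(iaf)$lower else NULL,
         upper_band_hz = if (valid) individual_bands(iaf)$upper else NULL,
         search_band_hz = search_band_hz,
         valid = valid, diagnostic = diagnostic,
         diff_spectra = diffs, freqs_hz = freqs),
    class = "bci_iaf")
}

#' @export
print.bci_iaf <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<bci_iaf> IAF = %.2f Hz (peaks: %s); bands %.2f-%.2f / %.2f-%.2f Hz\n",
                x$iaf_hz,
                paste(sprintf("%s %.2f", names(x$peak_hz_per_channel),
                              x$peak_hz_per_channel), collapse = ", "),
                x$lower_band_hz[1], x$lower_band_hz[2],
                x$upper_band_hz[1], x$upper_band_hz[2]))
  } else {
    cat("<bci_iaf> invalid:", paste(x$diagnostic, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Individualized alpha sub-bands
#'
#' The two narrow alpha bands around an IAF value: (IAF-2, IAF) and
#' (IAF, IAF+2), each exactly 2 Hz wide.
#'
#' @param iaf_hz IAF in Hz; must exceed 2 so the lower edge stays positive.
#' @return List with `lower` and `upper`, each a length-2 numeric band.
#' @examples
#' individual_bands(10)  # (8,10) and (10,12)
#' @export
individual_bands <- function(iaf_hz) {
  if (!is.numeric(iaf_hz) || length(iaf_hz) != 1L || !is.finite(iaf_hz) ||
      iaf_hz <= 2)
    stop("iaf_hz must be a single finite value > 2 Hz", call. = FALSE)
  list(lower = c(iaf_hz - 2, iaf_hz), upper = c(iaf_hz, iaf_hz + 2))
}
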