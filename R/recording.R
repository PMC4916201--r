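#' Multichannel physiological recording
#'
#' Constructs a `bci_recording`, the package's container for a raw
#' multichannel time series: a channels-by-samples numeric matrix in
#' microvolts, a sample rate, ordered channel labels and a condition tag.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param labels Character vector of channel labels, one per row of `data`.
#' @param condition One of `"EO"`, `"EC"`, `"ECG"`, `"UNKNOWN"`.
#' @return An object of class `bci_recording` with fields `data`,
#'   `sample_rate_hz`, `labels`, `condition` and derived `duration_s`.
#' @examples
#' r <- recording(matrix(rnorm(256), 2, 128), 128, c("O1", "O2"), "EC")
#' r$duration_s
#' @export
recording <- function(data, sample_rate_hz, labels = NULL,
                      condition = c("UNKNOWN", "EO", "EC", "ECG")) {
  condition <- match.arg(condition)
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be a positive number", call. = FALSE)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop(sprintf("%d labels supplied for %d channels", length(labels),
                 nrow(data)), call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("recording contains NaN/Inf samples", call. = FALSE)
  structure(
    list(data = data, sample_rate_hz = as.numeric(sample_rate_hz),
         labels = labels, condition = condition,
         duration_s = ncol(data) / sample_rate_hz),
    class = "bci_recording")
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d channels x %d samples @ %g Hz (%.1f s), condition %s\n",
              nrow(x$data), ncol(x$data), x$sample_rate_hz, x$duration_s,
              x$condition))
  invisible(x)
}

#' Resolve channel labels to row indices
#'
#' Case-insensitive lookup of channel labels in a recording or PSD
#' estimate, returned in the order requested.
#'
#' @param x A `bci_recording` or `bci_psd` (anything with a `labels` field).
#' @param wanted Character vector of labels to locate (e.g. `c("O1","O2")`).
#' @return Integer vector of row indices, one per requested label.
#' @export
resolve_channels <- function(x, wanted) {
  labels <- x$labels
  idx <- match(toupper(wanted), toupper(labels))
  if (anyNA(idx)) {
    missing <- wanted[is.na(idx)]
    stop(sprintf("channel(s) not found: %s; available: %s",
                 paste(missing, collapse = ", "),
                 paste(labels, collapse = ", ")), call. = FALSE)
  }
  idx
}

#' Default BioSemi 64-channel 10/10 label map
#'
#' Returns the canonical BioSemi ordering of the 64-channel 10/10 montage
#' (A1..B32) as a character vector; `O1` is row 27 and `O2` row 64 in this
#' layout. Shipped as a plain-text fixture in `inst/extdata`.
#'
#' @return Character vector of 64 labels in amplifier order.
#' @export
biosemi64_labels <- function() {
  path <- system.file("extdata", "biosemi64_1010_labels.tsv",
                      package = "bcindex", mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  tab$label[order(tab$index)]
}

#' Read a channel map file
#'
#' A channel map is a two-column TSV `label<TAB>index` with zero-based row
#' indices into the data matrix.
#'
#' @param path Path to the TSV file.
#' @return Named integer vector of one-based row indices.
#' @export
read_channel_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("label", "index") %in% names(tab)))
    stop("channel map must have columns `label` and `index`", call. = FALSE)
  idx <- as.integer(tab$index) + 1L
  if (anyDuplicated(idx)) stop("channel map indices must be unique", call. = FALSE)
  stats::setNames(idx, tab$label)
}
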