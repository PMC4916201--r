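#' Read a recording from delimited text
#'
#' Reads an EEG or ECG recording from a delimited numeric text file.
#' The delimiter (comma, tab or whitespace) is sniffed from the first
#' line. An optional single header row of channel labels is honoured;
#' otherwise labels come from `channel_map` or, for 64-row data, the
#' shipped BioSemi 10/10 map. Orientation is auto-resolved: the longer
#' axis is taken as time.
#'
#' @param path Path to the file.
#' @param sample_rate_hz Sampling rate in Hz (files carry no rate).
#' @param channel_map Optional named integer vector (label -> one-based
#'   row index) as returned by [read_channel_map()], or `NULL`.
#' @param condition Condition tag, one of `"EO"`, `"EC"`, `"ECG"`,
#'   `"UNKNOWN"`.
#' @return A [recording()] object.
#' @export
read_recording <- function(path, sample_rate_hz, channel_map = NULL,
                           condition = c("UNKNOWN", "EO", "EC", "ECG")) {
  condition <- match.arg(condition)
  if (grepl("\\.mat$", path, ignore.case = TRUE))
    stop("MAT-file input is not supported; export the array as delimited text",
         call. = FALSE)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file", call. = FALSE)
  sep <- sniff_delim(first)
  header_labels <- sniff_header(first, sep)
  mat <- parse_numeric_matrix(path, sep, skip = if (is.null(header_labels)) 0L else 1L)
  if (anyNA(mat) || any(!is.finite(mat)))
    stop("recording contains NaN/Inf values", call. = FALSE)

  labels <- header_labels
  if (!is.null(labels)) {
    # the header length disambiguates orientation when it can
    if (length(labels) == nrow(mat)) {
      # rows already channels
    } else if (length(labels) == ncol(mat)) {
      mat <- t(mat)
    } else {
      stop(sprintf("header has %d labels but data is %d x %d",
                   length(labels), nrow(mat), ncol(mat)), call. = FALSE)
    }
  } else if (nrow(mat) > ncol(mat)) {
    # orientation: rows = channels when rows <= cols, else transpose
    mat <- t(mat)
  }
  if (is.null(labels)) {
    if (!is.null(channel_map)) {
      if (max(channel_map) > nrow(mat))
        stop("channel map index exceeds number of data rows", call. = FALSE)
      labels <- character(nrow(mat))
      labels[channel_map] <- names(channel_map)
      empty <- labels == ""
      labels[empty] <- paste0("ch", which(empty))
    } else if (nrow(mat) == 64L) {
      labels <- biosemi64_labels()
    } else if (nrow(mat) == 1L) {
      labels <- if (condition == "ECG") "ECG" else "ch1"
    } else {
      stop(sprintf(paste0("no header and no channel map: cannot label %d ",
                          "channels (the default BioSemi map needs 64)"),
                   nrow(mat)), call. = FALSE)
    }
  } else if (length(labels) != nrow(mat)) {
    stop(sprintf("header has %d labels but data has %d channels",
                 length(labels), nrow(mat)), call. = FALSE)
  }
  recording(mat, sample_rate_hz, labels, condition)
}

#' Write a recording as delimited text
#'
#' Writes channels-in-rows, tab-separated, full precision, with a header
#' row of labels, so that [read_recording()] round-trips bit-identically.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$labels, collapse = "\t"), con)
  body <- apply(rec$data, 1L, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

sniff_delim <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  ""
}

# returns label vector if the first line is non-numeric, else NULL
sniff_header <- function(line, sep) {
  tokens <- split_line(line, sep)
  suppressWarnings(vals <- as.numeric(tokens))
  if (anyNA(vals)) tokens else NULL
}

split_line <- function(line, sep) {
  if (sep == "") {
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  } else {
    tok <- trimws(strsplit(line, sep, fixed = TRUE)[[1]])
  }
  tok[tok != ""]
}

parse_numeric_matrix <- function(path, sep, skip = 0L) {
  lines <- readLines(path)
  if (skip > 0L) lines <- lines[-seq_len(skip)]
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, split_line, sep = sep)
  ncols <- unique(vapply(rows, length, 1L))
  if (length(ncols) != 1L)
    stop("ragged rows: all data lines must have the same number of fields",
         call. = FALSE)
  out <- matrix(NA_real_, nrow = length(rows), ncol = ncols)
  for (i in seq_along(rows)) {
    suppressWarnings(v <- as.numeric(rows[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric value %s at data row %d, column %d",
                   dQuote(rows[[i]][j]), i + skip, j), call. = FALSE)
    }
    out[i, ] <- v
  }
  out
}
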