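#' Default pipeline configuration
#'
#' All tunables of the pipeline with their defaults; any subset can be
#' overridden via the `config` argument of [run_pipeline()] or a
#' key = value config file (see [read_config()]). A commented reference
#' copy ships in `inst/extdata/default_config.toml`.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    welch.epoch_seconds = 4,
    welch.overlap = 0.5,
    welch.window = "hann",
    iaf.channels = c("O1", "O2"),
    iaf.search_low_hz = 7,
    iaf.search_high_hz = 14,
    iaf.smooth = FALSE,
    predictor.channels = c("C3", "C4"),
    predictor.fit_low_hz = 2,
    predictor.fit_high_hz = 35,
    predictor.two_peaks = TRUE,
    predictor.degenerate_tol = 0.01,
    predictor.truncate_eo_s = NA,   # set to 120 to use only the first 2 min
    ecg.nn_min_s = 0.3,
    ecg.nn_max_s = 2.0
  )
}

#' Read a key = value configuration file
#'
#' Flat TOML-style file: one `key = value` per line, `#` comments,
#' dotted keys matching [default_config()]. Values are parsed as
#' numbers, logicals (`true`/`false`) or bare strings.
#'
#' @param path Path to the file.
#' @return Named list of overrides.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop(sprintf("bad config line: %s", ln), call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else val
  }
  out
}

#' Run the full analysis pipeline
#'
#' Computes Welch PSDs of the eyes-open and eyes-closed recordings,
#' estimates the IAF from the occipital reactivity spectrum, fits the
#' spectral model on the central channels of the eyes-open recording
#' (seeding the alpha-peak center with the IAF when valid) and computes
#' the aptitude predictor, optionally runs the ECG validation chain,
#' then writes `report.json` plus `iaf.png` and `predictor.png` to
#' `out_dir`. Any fallback or invalid stage is recorded as a warning in
#' the report rather than raising an error.
#'
#' @param eo,ec Eyes-open / eyes-closed input: a file path or a
#'   [recording()].
#' @param sample_rate_hz Sampling rate for file inputs.
#' @param ecg Optional ECG input (path or numeric vector or recording).
#' @param out_dir Output directory (default: directory of `eo` for file
#'   input, else the working directory). `NULL` suppresses all output
#'   files.
#' @param config Named list of overrides of [default_config()].
#' @return A `bci_report` list with `iaf`, `predictor`, `cardiac`,
#'   `warnings`, `config`, `report_path`.
#' @export
run_pipeline <- function(eo, ec, sample_rate_hz = NULL, ecg = NULL,
                         out_dir = NA, config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  load_rec <- function(x, cond) {
    if (inherits(x, "bci_recording")) return(x)
    if (is.null(sample_rate_hz))
      stop("sample_rate_hz is required for file input", call. = FALSE)
    read_recording(x, sample_rate_hz, condition = cond)
  }
  rec_eo <- load_rec(eo, "EO")
  rec_ec <- load_rec(ec, "EC")
  if (!is.null(out_dir) && length(out_dir) == 1L && is.na(out_dir))
    out_dir <- if (is.character(eo)) dirname(eo) else "."

  psd_args <- function(rec) welch_psd(rec,
                                      epoch_seconds = cfg$welch.epoch_seconds,
                                      overlap_fraction = cfg$welch.overlap,
                                      window = cfg$welch.window)
  psd_ec <- psd_args(rec_ec)
  psd_eo <- psd_args(rec_eo)

  iaf <- estimate_iaf(psd_ec, psd_eo, channels = cfg$iaf.channels,
                      search_band_hz = c(cfg$iaf.search_low_hz,
                                         cfg$iaf.search_high_hz),
                      smooth = isTRUE(cfg$iaf.smooth))
  if (!iaf$valid)
    note(paste("IAF invalid:", paste(iaf$diagnostic, collapse = "; ")))

  # predictor path runs on the EO recording, optionally truncated to 2 min
  rec_pred <- rec_eo
  if (!is.na(cfg$predictor.truncate_eo_s) &&
      rec_eo$duration_s > cfg$predictor.truncate_eo_s) {
    nkeep <- round(cfg$predictor.truncate_eo_s * rec_eo$sample_rate_hz)
    rec_pred <- recording(rec_eo$data[, seq_len(nkeep), drop = FALSE],
                          rec_eo$sample_rate_hz, rec_eo$labels, "EO")
  }
  psd_pred <- if (identical(rec_pred, rec_eo)) psd_eo else psd_args(rec_pred)
  pred <- tryCatch(
    predictor_index(psd_pred, channels = cfg$predictor.channels,
                    iaf_hz = if (iaf$valid) iaf$iaf_hz else NULL,
                    fit_band_hz = c(cfg$predictor.fit_low_hz,
                                    cfg$predictor.fit_high_hz),
                    two_peaks = isTRUE(cfg$predictor.two_peaks),
                    degenerate_tol = cfg$predictor.degenerate_tol),
    error = function(e) {
      note(paste("predictor failed:", conditionMessage(e)))
      NULL
    })
  if (!is.null(pred))
    for (ch in names(pred$method_per_channel))
      if (pred$method_per_channel[[ch]] == "psd_minus_powerlaw")
        note(sprintf("predictor %s: fell back to PSD - power-law", ch))

  cardiac <- NULL
  if (!is.null(ecg)) {
    sig <- if (inherits(ecg, "bci_recording")) {
      as.numeric(ecg$data[1, ])
    } else if (is.numeric(ecg)) {
      ecg
    } else {
      as.numeric(read_recording(ecg, sample_rate_hz, condition = "ECG")$data[1, ])
    }
    fs_ecg <- if (inherits(ecg, "bci_recording")) {
      ecg$sample_rate_hz
    } else if (!is.null(sample_rate_hz)) {
      sample_rate_hz
    } else {
      rec_eo$sample_rate_hz  # bare vector, no rate given: assume EEG rate
    }
    cardiac <- tryCatch(analyze_ecg(sig, fs_ecg), error = function(e) {
      note(paste("cardiac failed:", conditionMessage(e)))
      NULL
    })
    if (!is.null(cardiac) && cardiac$n_discarded_nn > 0)
      note(sprintf("cardiac: %d NN interval(s) discarded", cardiac$n_discarded_nn))
  }

  report <- structure(
    list(version = as.character(utils::packageVersion("bcindex")),
         inputs = list(
           eo = if (is.character(eo)) eo else "<in-memory>",
           ec = if (is.character(ec)) ec else "<in-memory>",
           sample_rate_hz = rec_eo$sample_rate_hz),
         iaf = iaf, predictor = pred, cardiac = cardiac,
         psd_ec = psd_ec, psd_eo = psd_eo,
         warnings = warnings, config = cfg, report_path = NULL),
    class = "bci_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report$report_path <- file.path(out_dir, "report.json")
    write_report(report, report$report_path)
    try_figure(file.path(out_dir, "iaf.png"),
               function() plot_iaf(report), note)
    if (!is.null(pred))
      try_figure(file.path(out_dir, "predictor.png"),
                 function() plot_predictor(pred), note)
    report$warnings <- warnings
    write_report(report, report$report_path)  # include figure warnings
  }
  report
}

try_figure <- function(path, fun, note) {
  ok <- tryCatch({
    grDevices::png(path, width = 1400, height = 900, res = 120)
    on.exit(grDevices::dev.off())
    fun()
    TRUE
  }, error = function(e) {
    note(sprintf("figure %s not written: %s", basename(path),
                 conditionMessage(e)))
    FALSE
  })
  invisible(ok)
}

#' Serialize a pipeline report to JSON
#'
#' @param report A `bci_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- list(
    version = report$version,
    inputs = report$inputs,
    iaf_hz = if (report$iaf$valid) report$iaf$iaf_hz else NULL,
    iaf_valid = report$iaf$valid,
    per_channel_peaks = as.list(report$iaf$peak_hz_per_channel),
    bands = if (report$iaf$valid)
      list(lower = report$iaf$lower_band_hz,
           upper = report$iaf$upper_band_hz) else NULL,
    predictor = if (!is.null(report$predictor))
      as.list(report$predictor$index_per_channel) else NULL,
    predictor_method = if (!is.null(report$predictor))
      as.list(report$predictor$method_per_channel) else NULL,
    predictor_combined = report$predictor$combined,
    cardiac = if (!is.null(report$cardiac)) list(
      s_hz = report$cardiac$s_hz,
      n_beats = length(report$cardiac$r_peak_indices),
      harmonic_hz = as.list(report$cardiac$harmonic_hz),
      theoretical_iaf_hz = report$cardiac$theoretical_iaf_hz) else NULL,
    warnings = report$warnings,
    config = report$config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.bci_report <- function(x, ...) {
  cat("<bci_report>\n")
  print(x$iaf)
  if (!is.null(x$predictor)) print(x$predictor)
  if (!is.null(x$cardiac)) print(x$cardiac)
  if (length(x$warnings))
    cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Plot the IAF estimation (EC, EO and reactivity spectra)
#'
#' One column per channel with eyes-closed PSD, eyes-open PSD and their
#' difference; the per-channel reactivity peak and the mean IAF are
#' marked.
#'
#' @param report A `bci_report` (or a list with `iaf`, `psd_ec`, `psd_eo`).
#' @param xlim_hz Frequency axis range, default `c(0, 30)`.
#' @return Invisibly, `NULL`.
#' @export
plot_iaf <- function(report, xlim_hz = c(0, 30)) {
  iaf <- report$iaf
  chans <- names(iaf$peak_hz_per_channel)
  freqs <- iaf$freqs_hz
  keep <- freqs >= xlim_hz[1] & freqs <= xlim_hz[2]
  old <- graphics::par(mfrow = c(3, length(chans)),
                       mar = c(3.5, 3.5, 2, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  for (row in c("EC", "EO", "EC-EO")) {
    for (ch in chans) {
      i_ec <- resolve_channels(report$psd_ec, ch)
      y <- switch(row,
                  "EC" = report$psd_ec$power[i_ec, ],
                  "EO" = report$psd_eo$power[resolve_channels(report$psd_eo, ch), ],
                  "EC-EO" = iaf$diff_spectra[[ch]])
      graphics::plot(freqs[keep], y[keep], type = "l",
                     xlab = "Frequency (Hz)",
                     ylab = expression(PSD ~ (mu * V^2 / Hz)),
                     main = sprintf("%s %s", ch, row))
      if (row == "EC-EO") {
        graphics::abline(v = iaf$peak_hz_per_channel[[ch]], col = "blue",
                         lty = 3)
        if (iaf$valid) graphics::abline(v = iaf$iaf_hz, col = "red")
      }
    }
  }
  if (iaf$valid)
    graphics::mtext(sprintf("IAF = %.2f Hz", iaf$iaf_hz), outer = TRUE,
                    line = -1.2)
  invisible(NULL)
}

#' Plot the predictor fits (PSD, model, power law) per channel
#'
#' @param pred A `bci_predictor` from [predictor_index()].
#' @return Invisibly, `NULL`.
#' @export
plot_predictor <- function(pred) {
  chans <- names(pred$fits)
  old <- graphics::par(mfrow = c(1, length(chans)),
                       mar = c(3.5, 3.5, 3, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  for (ch in chans) {
    f <- pred$fits[[ch]]
    graphics::plot(f$freqs_hz, f$observed, type = "l", col = "black",
                   xlab = "Frequency (Hz)",
                   ylab = expression(PSD ~ (mu * V^2 / Hz)),
                   main = sprintf("%s: index %.3g (%s)", ch,
                                  pred$index_per_channel[[ch]],
                                  pred$method_per_channel[[ch]]))
    graphics::lines(f$freqs_hz, f$fitted, col = "blue", lwd = 2)
    graphics::lines(f$freqs_hz, f$power_law, col = "darkgreen", lty = 2,
                    lwd = 2)
    graphics::legend("topright", c("PSD", "model", "power law"),
                     col = c("black", "blue", "darkgreen"),
                     lty = c(1, 1, 2), bty = "n", cex = 0.8)
  }
  invisible(NULL)
}
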