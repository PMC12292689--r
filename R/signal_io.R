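#' Preprocessing configuration
#'
#' Settings for the preprocessing chain the tensorization assumes: an
#' anti-aliased resample to `target_fs` (the analysis rate, default 400 Hz),
#' a zero-phase Butterworth band-pass (default 20-150 Hz, the band carrying
#' the bulk of sEMG energy), and an optional mains notch.
#'
#' @param target_fs analysis sampling rate in Hz (default 400).
#' @param bandpass length-2 (low, high) pass band in Hz with
#'   `0 < low < high < target_fs / 2`.
#' @param notch_hz optional mains frequency to notch out (e.g. 50), or `NULL`.
#' @param zero_phase apply filters forward-backward (no phase distortion).
#' @param rectify full-wave rectify after filtering (used upstream of the
#'   non-negative 2-D factorization path; keep off before the wavelet
#'   transform).
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 400, bandpass = c(20, 150),
                              notch_hz = NULL, zero_phase = TRUE,
                              rectify = FALSE) {
  if (!is_number(target_fs) || target_fs <= 0) {
    abort_argument("`target_fs` must be positive")
  }
  if (length(bandpass) != 2 || bandpass[1] <= 0 ||
    bandpass[2] <= bandpass[1] || bandpass[2] >= target_fs / 2) {
    abort_argument("`bandpass` must satisfy 0 < low < high < target_fs / 2")
  }
  if (!is.null(notch_hz) && (!is_number(notch_hz) || notch_hz <= 0)) {
    abort_argument("`notch_hz` must be NULL or a positive number")
  }
  structure(
    list(
      target_fs = target_fs, bandpass = as.numeric(bandpass),
      notch_hz = notch_hz, zero_phase = isTRUE(zero_phase),
      rectify = isTRUE(rectify)
    ),
    class = "preprocess_config"
  )
}

sniff_sep <- function(line) {
  counts <- c(
    "," = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
    "\t" = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))),
    ";" = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE)))
  )
  if (all(counts == 0)) abort_format("could not detect a delimiter")
  names(counts)[which.max(counts)]
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read an EMG recording from delimited text
#'
#' Reads a CSV/TSV file (dialect sniffed from the first line). With a header,
#' the first column is interpreted as time in seconds when it is strictly
#' monotone (the sampling rate is inferred from its span) and the remaining
#' columns are channels labelled by the header; otherwise `fs_override` must
#' be supplied. Headerless files require `fs_override` and treat every column
#' as a channel. A JSON sidecar written by [write_emg()] (same path plus
#' `.json`) restores the original sampling rate and labels exactly.
#'
#' @param path file path.
#' @param fs_override sampling rate in Hz, required when no time column or
#'   sidecar is available.
#' @return An [emg_recording()].
#' @export
read_emg <- function(path, fs_override = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (!length(first)) abort_format("empty file")
  sep <- sniff_sep(first)
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- tryCatch(
    read.table(path, sep = sep, header = has_header, check.names = FALSE),
    error = function(e) abort_format(paste("could not parse file:", conditionMessage(e)))
  )
  if (ncol(df) < 2 && has_header) abort_format("need at least 2 columns")
  mat <- suppressWarnings(as.matrix(sapply(df, as.numeric)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(df))
  if (any(!is.finite(mat))) abort_format("non-numeric or missing cells in data")

  side <- NULL
  if (file.exists(sidecar_path(path))) {
    side <- tryCatch(jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE),
      error = function(e) NULL
    )
  }

  if (!has_header) {
    if (is.null(fs_override) && is.null(side$fs)) {
      abort_format("headerless file: supply `fs_override` (no sampling rate available)")
    }
    fs <- fs_override %||% side$fs
    ch <- side$channel_names %||% sprintf("ch%02d", seq_len(ncol(mat)))
    return(emg_recording(t(mat), fs = fs, channel_names = ch))
  }

  t_col <- mat[, 1]
  monotone <- all(diff(t_col) > 0)
  if (monotone && nrow(mat) >= 2) {
    fs <- fs_override %||% side$fs %||% ((nrow(mat) - 1) / (t_col[nrow(mat)] - t_col[1]))
    ch <- colnames(df)[-1]
    emg_recording(t(mat[, -1, drop = FALSE]), fs = fs, channel_names = ch)
  } else {
    if (is.null(fs_override) && is.null(side$fs)) {
      abort_format("first column is not a monotone time axis: supply `fs_override`")
    }
    emg_recording(t(mat), fs = fs_override %||% side$fs, channel_names = colnames(df))
  }
}

#' Write an EMG recording to delimited text
#'
#' Writes `time_s, <channel>, ...` in the requested dialect plus a JSON
#' sidecar `<path>.json` holding `fs`, `channel_names` and optionally the
#' generating `seed`, so a read round-trip is exact.
#'
#' @param rec an [emg_recording()].
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @param seed optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_emg <- function(rec, path, sep = ",", seed = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- rec_fs(rec)
  df <- data.frame((seq_len(ncol(rec)) - 1) / fs, t(unclass(rec)))
  names(df) <- c("time_s", rec_channels(rec))
  write.table(df, path,
    sep = sep, row.names = FALSE, col.names = TRUE, quote = FALSE
  )
  meta <- list(fs = fs, channel_names = rec_channels(rec))
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

resample_channel <- function(x, fs_from, fs_to) {
  if (fs_from == fs_to) return(x)
  # sharpen the polyphase FIR anti-alias with an explicit zero-phase
  # low-pass at 0.45 * fs_to (the FIR transition band alone leaks
  # near-Nyquist tones into the passband)
  aa <- signal::butter(8, 0.9 * fs_to / fs_from, type = "low")
  x <- signal::filtfilt(aa, x)
  p <- round(fs_to)
  q <- round(fs_from)
  g <- pracma::gcd(p, q)
  signal::resample(x, p / g, q / g)
}

#' Preprocess a recording for tensorization
#'
#' Anti-aliased polyphase resampling down to `cfg$target_fs`, zero-phase
#' 4th-order Butterworth band-pass, optional mains notch, residual DC
#' removal, and optional full-wave rectification. Upsampling is refused.
#'
#' @param rec an [emg_recording()] with `fs >= cfg$target_fs`.
#' @param cfg a [preprocess_config()].
#' @return An [emg_recording()] at `cfg$target_fs`.
#' @examples
#' rec <- emg_recording(matrix(rnorm(4000), 2), fs = 1000)
#' out <- preprocess(rec, preprocess_config(target_fs = 400))
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  stopifnot(inherits(cfg, "preprocess_config"))
  fs <- rec_fs(rec)
  if (fs < cfg$target_fs) {
    abort_argument("`target_fs` exceeds the recording rate (no upsampling)")
  }
  ny <- cfg$target_fs / 2
  bf <- signal::butter(4, cfg$bandpass / ny, type = "pass")
  nf <- if (!is.null(cfg$notch_hz)) {
    signal::butter(2, c(cfg$notch_hz - 2, cfg$notch_hz + 2) / ny, type = "stop")
  }
  out <- t(apply(unclass(rec), 1, function(x) {
    y <- resample_channel(x, fs, cfg$target_fs)
    y <- if (cfg$zero_phase) signal::filtfilt(bf, y) else as.numeric(signal::filter(bf, y))
    if (!is.null(nf)) {
      y <- if (cfg$zero_phase) signal::filtfilt(nf, y) else as.numeric(signal::filter(nf, y))
    }
    y <- y - mean(y)
    if (cfg$rectify) abs(y) else y
  }))
  emg_recording(out, fs = cfg$target_fs, channel_names = rec_channels(rec))
}
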