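#' Multichannel surface-EMG recording
#'
#' Container for a multichannel sEMG recording: a channels x samples matrix
#' (millivolt scale), its sampling rate, and muscle labels (defaults follow
#' the forearm montage ED, FDS, ECU, FCU).
#'
#' @param samples numeric matrix, channels x samples; all values finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector of muscle labels, one per row of
#'   `samples`.
#' @return An object of class `emg_recording`: the samples matrix with
#'   attributes `fs` and `channel_names` (rows are named after the channels).
#' @examples
#' rec <- emg_recording(matrix(rnorm(800), 2), fs = 400)
#' rec
#' @export
emg_recording <- function(samples, fs, channel_names = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort_argument("`samples` must be a numeric channels x samples matrix")
  }
  if (!all(is.finite(samples))) abort_data("`samples` contains non-finite values")
  if (!is_number(fs) || fs <= 0) abort_argument("`fs` must be a positive number")
  channel_names <- channel_names %||% default_channel_names(nrow(samples))
  if (length(channel_names) != nrow(samples)) {
    abort_argument("channel count must equal the number of labels")
  }
  rownames(samples) <- channel_names
  structure(samples,
    fs = fs, channel_names = as.character(channel_names),
    class = c("emg_recording", "matrix", "array")
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
    nrow(x), ncol(x), attr(x, "fs"), ncol(x) / attr(x, "fs")
  ))
  cat("channels:", paste(attr(x, "channel_names"), collapse = ", "), "\n")
  invisible(x)
}

n_channels <- function(rec) nrow(rec)
rec_fs <- function(rec) attr(rec, "fs")
rec_channels <- function(rec) attr(rec, "channel_names")

#' Convert a recording to a tidy tibble
#'
#' @param x an [emg_recording()].
#' @param ... unused.
#' @return Tibble with columns `time_s`, `channel`, `value`.
#' @export
tidy.emg_recording <- function(x, ...) {
  fs <- attr(x, "fs")
  tibble::tibble(
    time_s = rep((seq_len(ncol(x)) - 1) / fs, each = nrow(x)),
    channel = rep(attr(x, "channel_names"), ncol(x)),
    value = as.vector(x)
  )
}
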