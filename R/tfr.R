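#' Morlet wavelet configuration
#'
#' Parameters of the complex Morlet transform used to build the EMG tensor:
#' the wavelet width `sigma` (natural units), the center frequency `fc`
#' (conventionally about 0.849, giving the scale-to-frequency map
#' `f = fc * fs / scale`), the number of integer scales (default 30, so the
#' frequency axis spans fc*fs/30 ... fc*fs at fs = 400 Hz), and the sampling
#' rate. The center angular frequency is `omega0 = 2 * pi * fc`.
#'
#' @param sigma Gaussian width of the mother wavelet (> 0, default 1).
#' @param fc center frequency in cycles per natural unit (default 0.849).
#' @param n_scales number of integer scales (default 30).
#' @param fs sampling rate in Hz the transform assumes (default 400).
#' @return Object of class `wavelet_config` with derived field `omega0`.
#' @export
wavelet_config <- function(sigma = 1, fc = 0.849, n_scales = 30, fs = 400) {
  if (!is_number(sigma) || sigma <= 0) abort_argument("`sigma` must be > 0")
  if (!is_number(fc) || fc <= 0) abort_argument("`fc` must be > 0")
  if (!is_count(n_scales)) abort_argument("`n_scales` must be a positive integer")
  if (!is_number(fs) || fs <= 0) abort_argument("`fs` must be > 0")
  structure(
    list(
      sigma = sigma, fc = fc, omega0 = 2 * pi * fc,
      n_scales = as.integer(n_scales), fs = fs
    ),
    class = "wavelet_config"
  )
}

#' Complex Morlet mother wavelet
#'
#' L2-normalized complex Morlet
#' \eqn{\psi(t) = \sigma^{-1/2} \pi^{-1/4} e^{j\omega_0 t} e^{-t^2/(2\sigma^2)}}
#' evaluated at `t` (natural units). At `t = 0`, `sigma = 1` the value is
#' \eqn{\pi^{-1/4} \approx 0.7511}.
#'
#' @param t numeric vector of times in natural units.
#' @param cfg a [wavelet_config()].
#' @return Complex vector of wavelet values.
#' @export
morlet <- function(t, cfg = wavelet_config()) {
  stopifnot(inherits(cfg, "wavelet_config"))
  cfg$sigma^(-1 / 2) * pi^(-1 / 4) *
    exp(1i * cfg$omega0 * t) * exp(-t^2 / (2 * cfg$sigma^2))
}

#' Map a wavelet scale index to frequency
#'
#' Per-scale reading of the conventional map `f = fc * Fs / scale`: the
#' integer scales 1..n_scales give a descending frequency axis
#' (339.6 Hz down to 11.32 Hz at the defaults).
#'
#' @param scale_index integer vector of scale indices in 1..`cfg$n_scales`.
#' @param cfg a [wavelet_config()].
#' @return Frequencies in Hz.
#' @examples
#' scale_to_freq(c(1, 30))
#' @export
scale_to_freq <- function(scale_index, cfg = wavelet_config()) {
  stopifnot(inherits(cfg, "wavelet_config"))
  if (any(scale_index < 1 | scale_index > cfg$n_scales |
    scale_index != round(scale_index))) {
    abort_argument(sprintf("scale index must be an integer in 1..%d", cfg$n_scales))
  }
  cfg$fc * cfg$fs / scale_index
}

#' Continuous wavelet transform of one channel
#'
#' Row j holds the correlation of the signal with the scale-j Morlet wavelet,
#' \eqn{C_j[n] = a_j^{-1/2} \sum_k e[n+k] \psi(k/a_j)} with `a_j = j`,
#' computed by FFT convolution with zero padding; the central `length(x)`
#' samples are retained.
#'
#' @param x real numeric signal (length >= 8, no NaN).
#' @param cfg a [wavelet_config()].
#' @return Complex matrix `n_scales x length(x)`.
#' @export
cwt_channel <- function(x, cfg = wavelet_config()) {
  stopifnot(inherits(cfg, "wavelet_config"))
  if (any(is.nan(x)) || any(!is.finite(x))) abort_data("signal contains NaN or non-finite values")
  n <- length(x)
  if (n < 8) abort_argument("signal length must be at least 8")
  out <- matrix(0i, cfg$n_scales, n)
  for (j in seq_len(cfg$n_scales)) {
    a <- j
    K <- ceiling(6 * cfg$sigma * a)
    w <- Conj(morlet(((-K):K) / a, cfg)) / sqrt(a)
    N <- stats::nextn(n + 2 * K + 1, 2)
    Xf <- fft(c(x, rep(0, N - n)))
    Wf <- fft(c(w, rep(0i, N - length(w))))
    conv <- fft(Xf * Wf, inverse = TRUE) / N
    out[j, ] <- conv[(1:n) + K]
  }
  out
}

#' Non-negative frequency x time x space EMG tensor
#'
#' Low-level constructor; see [build_emg_tensor()] for the usual entry point.
#'
#' @param values non-negative array `f_bins x t_samples x channels`.
#' @param freqs_hz descending positive frequency axis, length `f_bins`.
#' @param channel_names channel labels, length `dim(values)[3]`.
#' @return Object of class `emg_tensor` (a 3-way array with attributes).
#' @export
emg_tensor <- function(values, freqs_hz, channel_names) {
  if (!is.array(values) || length(dim(values)) != 3) {
    abort_argument("`values` must be a 3-way array")
  }
  if (any(values < 0) || any(!is.finite(values))) {
    abort_argument("tensor values must be finite and non-negative")
  }
  if (length(freqs_hz) != dim(values)[1] || any(freqs_hz <= 0) ||
    is.unsorted(rev(freqs_hz))) {
    abort_argument("`freqs_hz` must be a descending positive axis matching dim 1")
  }
  if (length(channel_names) != dim(values)[3]) {
    abort_argument("channel labels must match dim 3")
  }
  structure(values,
    freqs_hz = as.numeric(freqs_hz),
    channel_names = as.character(channel_names),
    class = c("emg_tensor", "array")
  )
}

#' @export
print.emg_tensor <- function(x, ...) {
  d <- dim(x)
  f <- attr(x, "freqs_hz")
  cat(sprintf(
    "<emg_tensor> %d freqs x %d samples x %d channels (%.1f-%.1f Hz)\n",
    d[1], d[2], d[3], min(f), max(f)
  ))
  invisible(x)
}

#' Build the EMG tensor from a preprocessed recording
#'
#' Computes the Morlet CWT magnitude of every channel and stacks the
#' `n_scales x samples` scalograms along the spatial (channel) dimension.
#' Magnitudes are optionally smoothed in time (`smooth_s`, default 0.4 s
#' moving average): the scalogram magnitude of a stochastic interference
#' pattern fluctuates pointwise (Rayleigh-like) around the activation
#' envelope, and the smoothed envelope - not the fluctuation - is what a
#' low-rank synergy model can represent. Smoothing acts linearly in time so
#' it preserves the CP rank of the underlying structure. Set `smooth_s = 0`
#' for raw magnitudes.
#'
#' @param rec an [emg_recording()] already preprocessed to `cfg$fs`.
#' @param cfg a [wavelet_config()].
#' @param smooth_s temporal moving-average window in seconds (0 disables).
#' @return An [emg_tensor()] of shape `(n_scales, samples, channels)`.
#' @examples
#' rec <- emg_recording(matrix(rnorm(1600), 2), fs = 400)
#' tens <- build_emg_tensor(rec, wavelet_config(), smooth_s = 0)
#' dim(tens)
#' @export
build_emg_tensor <- function(rec, cfg = wavelet_config(), smooth_s = 0.4) {
  stopifnot(inherits(rec, "emg_recording"), inherits(cfg, "wavelet_config"))
  if (abs(rec_fs(rec) - cfg$fs) > 1e-9) {
    abort_argument("recording must be preprocessed to `cfg$fs` before tensorization")
  }
  if (!is_number(smooth_s) || smooth_s < 0) abort_argument("`smooth_s` must be >= 0")
  ne <- n_channels(rec)
  n <- ncol(rec)
  vals <- array(0, c(cfg$n_scales, n, ne))
  win <- round(smooth_s * cfg$fs)
  for (i in seq_len(ne)) {
    M <- abs(cwt_channel(unclass(rec)[i, ], cfg))
    if (win >= 2) M <- t(apply(M, 1, moving_average, width = win))
    vals[, , i] <- M
  }
  emg_tensor(vals, scale_to_freq(seq_len(cfg$n_scales), cfg), rec_channels(rec))
}
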