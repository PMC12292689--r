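#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram over 50%-overlapping segments;
#' one-sided.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (default `min(256, length(x))`).
#' @return List with `freq` (Hz) and `psd`.
#' @keywords internal
welch_psd <- function(x, fs, seg_len = min(256L, length(x))) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  scale <- sum(w^2) * fs
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    P <- abs(fft(seg))^2 / scale
    half <- P[seq_len(nf)]
    if (seg_len %% 2 == 0) {
      half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    } else {
      half[2:nf] <- 2 * half[2:nf]
    }
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1) * fs / seg_len, psd = acc / length(starts))
}

#' Median frequency of a window
#'
#' Frequency splitting the Welch PSD into two equal-power halves, located by
#' linear interpolation of the cumulative power crossing.
#'
#' @param x numeric signal window.
#' @param fs sampling rate in Hz.
#' @return Median frequency in Hz (0 for an all-zero or DC-only window).
#' @export
median_frequency <- function(x, fs) {
  p <- welch_psd(x, fs)
  cum <- cumsum(p$psd)
  tot <- cum[length(cum)]
  if (tot <= 0) return(0)
  half <- tot / 2
  k <- which(cum >= half)[1]
  if (k == 1L) return(p$freq[1])
  f0 <- p$freq[k - 1L]
  frac <- (half - cum[k - 1L]) / (cum[k] - cum[k - 1L])
  f0 + frac * (p$freq[k] - p$freq[k - 1L])
}

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution of embedding vectors
#' (ties broken by position), normalized by `log(order!)` so the value lies
#' in [0, 1]. Degenerate windows (a single pattern, e.g. a constant or a
#' monotone ramp) give 0.
#'
#' @param x numeric signal window.
#' @param order embedding dimension (default 4).
#' @param delay embedding delay in samples (default 1).
#' @return Normalized permutation entropy in [0, 1].
#' @export
permutation_entropy <- function(x, order = 4L, delay = 1L) {
  if (!is_count(order) || order < 2) abort_argument("`order` must be an integer >= 2")
  if (!is_count(delay)) abort_argument("`delay` must be a positive integer")
  n <- length(x)
  n_pat <- n - (order - 1L) * delay
  if (n_pat < 1L) return(0)
  emb <- matrix(0, order, n_pat)
  for (k in seq_len(order)) emb[k, ] <- x[seq_len(n_pat) + (k - 1L) * delay]
  # Lehmer code: digit k counts later elements strictly smaller (position
  # breaks ties), which identifies the ordinal pattern uniquely
  code <- numeric(n_pat)
  for (k in seq_len(order - 1L)) {
    digit <- numeric(n_pat)
    for (j in seq((k + 1L), order)) digit <- digit + (emb[j, ] < emb[k, ])
    code <- code * (order - k + 1L) + digit
  }
  p <- tabulate(as.integer(factor(code)))
  p <- p / sum(p)
  h <- -sum(p * log(p))
  h / log(factorial(order))
}

#' Higuchi fractal dimension
#'
#' Waveform-complexity estimate: slope of `log(L(k))` against `log(1/k)`
#' where `L(k)` is Higuchi's mean curve length at lag `k = 1..k_max`. A
#' straight line has dimension 1; white noise approaches 2.
#'
#' @param x numeric signal window.
#' @param k_max largest lag (default 8).
#' @return Fractal dimension (1 for flat/degenerate windows).
#' @export
higuchi_fd <- function(x, k_max = 8L) {
  if (!is_count(k_max) || k_max < 2) abort_argument("`k_max` must be an integer >= 2")
  n <- length(x)
  L <- numeric(k_max)
  for (k in seq_len(k_max)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) {
        Lm[m] <- NA_real_
        next
      }
      nseg <- length(idx) - 1L
      Lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / (nseg * k) / k
    }
    L[k] <- mean(Lm, na.rm = TRUE)
  }
  if (any(!is.finite(L)) || any(L <= 0)) return(1)
  as.numeric(coef(lm(log(L) ~ log(1 / seq_len(k_max))))[2])
}

#' Windowed fatigue features
#'
#' Slides a window over every channel and extracts the four sEMG fatigue
#' features: root-mean-square amplitude (RMS, rises with fatigue), median
#' frequency (MF, falls as the spectrum compresses), normalized permutation
#' entropy (PE, falls as the signal grows more regular) and Higuchi fractal
#' dimension (FD, falls as waveform complexity drops).
#'
#' @param rec an [emg_recording()].
#' @param window_s window length in seconds; must cover >= 64 samples.
#' @param step_s hop between window starts in seconds (<= `window_s`).
#' @param pe_order,pe_delay permutation-entropy embedding (defaults 4, 1).
#' @param fd_kmax Higuchi lag bound (default 8).
#' @return Object of class `feature_windows`: tibble with columns `window`,
#'   `time_s` (window center), `channel`, `rms`, `mf`, `pe`, `fd`;
#'   attributes `fs`, `window_s`, `step_s`, `n_windows`, `starts`,
#'   `window_len`.
#' @examples
#' rec <- emg_recording(matrix(rnorm(3200), 2), fs = 400)
#' fw <- window_features(rec)
#' head(fw)
#' @export
window_features <- function(rec, window_s = 1, step_s = 0.5,
                            pe_order = 4L, pe_delay = 1L, fd_kmax = 8L) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- rec_fs(rec)
  wlen <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  if (wlen < 64) abort_argument("window must cover at least 64 samples")
  if (step_s > window_s) abort_argument("`step_s` must not exceed `window_s`")
  n <- ncol(rec)
  if (wlen > n) abort_argument("window longer than the recording")
  starts <- seq(1L, n - wlen + 1L, by = step)
  channels <- rec_channels(rec)
  X <- unclass(rec)
  rows <- vector("list", length(starts) * length(channels))
  idx <- 1L
  for (w in seq_along(starts)) {
    sl <- starts[w]:(starts[w] + wlen - 1L)
    tc <- (starts[w] - 1 + (wlen - 1) / 2) / fs
    for (i in seq_along(channels)) {
      x <- X[i, sl]
      rows[[idx]] <- tibble::tibble(
        window = w, time_s = tc, channel = channels[i],
        rms = sqrt(mean(x^2)),
        mf = median_frequency(x, fs),
        pe = permutation_entropy(x, pe_order, pe_delay),
        fd = higuchi_fd(x, fd_kmax)
      )
      idx <- idx + 1L
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("feature_windows", class(out)),
    fs = fs, window_s = window_s, step_s = step_s,
    n_windows = length(starts), starts = starts, window_len = wlen,
    normalized = FALSE
  )
}

minmax01 <- function(x, what) {
  rng <- range(x)
  if (diff(rng) == 0) {
    warn(sprintf("feature %s has zero range; normalized to 0", what))
    return(rep(0, length(x)))
  }
  (x - rng[1]) / diff(rng)
}

baseline01 <- function(x, what, n_base) {
  b <- mean(x[seq_len(n_base)])
  hi <- max(x)
  if (hi - b <= 0) {
    warn(sprintf("feature %s has zero range above baseline; normalized to 0", what))
    return(rep(0, length(x)))
  }
  pmin(pmax((x - b) / (hi - b), 0), 1)
}

#' Normalize fatigue features to [0, 1]
#'
#' Maps each feature into [0, 1] per channel and aligns its direction with
#' fatigue, so every normalized feature increases as fatigue grows:
#' `rf = minmax(RMS)`, `mf_n = 1 - minmax(MF)`, `pf = 1 - minmax(PE)`,
#' `ff = 1 - minmax(FD)`. Mode `"recording_minmax"` uses the recording range;
#' `"baseline_relative"` anchors the minimum at the mean of the first windows
#' instead (useful online, where the final range is unknown).
#'
#' @param fw a [window_features()] result with >= 2 windows.
#' @param mode `"recording_minmax"` (default) or `"baseline_relative"`.
#' @return The tibble with added columns `rf`, `mf_n`, `pf`, `ff`.
#' @export
normalize_features <- function(fw, mode = c("recording_minmax", "baseline_relative")) {
  stopifnot(inherits(fw, "feature_windows"))
  mode <- match.arg(mode)
  if (attr(fw, "n_windows") < 2) abort_argument("need at least 2 windows")
  at <- attributes(fw)
  n_base <- max(2L, ceiling(0.05 * attr(fw, "n_windows")))
  norm_one <- function(x, invert, what) {
    d <- if (invert) -x else x
    v <- if (mode == "recording_minmax") {
      minmax01(d, what)
    } else {
      baseline01(d, what, n_base)
    }
    v
  }
  out <- fw |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(
      rf = norm_one(.data$rms, FALSE, "RMS"),
      mf_n = norm_one(.data$mf, TRUE, "MF"),
      pf = norm_one(.data$pe, TRUE, "PE"),
      ff = norm_one(.data$fd, TRUE, "FD")
    ) |>
    dplyr::ungroup()
  for (nm in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(out, nm) <- at[[nm]]
  }
  attr(out, "normalized") <- TRUE
  attr(out, "normalize_mode") <- mode
  class(out) <- c("feature_windows", setdiff(class(out), "feature_windows"))
  out
}

#' Fatigue-feature weighting coefficients
#'
#' Non-negative weights for RMS, MF, PE and FD in the single-muscle fatigue
#' index. Weights not summing to 1 are renormalized with a warning. Defaults
#' are equal (0.25 each) until calibrated with [calibrate_weights()].
#'
#' @param TR,TM,TP,TF weights for RMS, MF, PE, FD.
#' @return Object of class `fatigue_weights` (named numeric, sums to 1).
#' @export
fatigue_weights <- function(TR = 0.25, TM = 0.25, TP = 0.25, TF = 0.25) {
  w <- c(TR = TR, TM = TM, TP = TP, TF = TF)
  if (any(!is.finite(w)) || any(w < 0)) {
    abort_argument("weights must be finite and non-negative")
  }
  s <- sum(w)
  if (s == 0) abort_argument("weights must not all be zero")
  if (abs(s - 1) > 1e-9) {
    warn("weights do not sum to 1; renormalizing")
    w <- w / s
  }
  structure(w, class = "fatigue_weights")
}

#' Single-muscle fatigue index
#'
#' Convex combination of the normalized fatigue features per muscle and
#' window: `ifmi = TR * rf + TM * mf_n + TP * pf + TF * ff`, in [0, 1].
#'
#' @param fw a normalized [window_features()] result (see
#'   [normalize_features()]).
#' @param w a [fatigue_weights()].
#' @return Object of class `fmi_series`: tibble `window`, `time_s`,
#'   `channel`, `ifmi`.
#' @export
single_muscle_fmi <- function(fw, w = fatigue_weights()) {
  stopifnot(inherits(fw, "feature_windows"))
  if (!isTRUE(attr(fw, "normalized"))) {
    abort_argument("normalized features missing: run normalize_features() first")
  }
  if (!inherits(w, "fatigue_weights")) w <- do.call(fatigue_weights, as.list(w))
  out <- tibble::tibble(
    window = fw$window, time_s = fw$time_s, channel = fw$channel,
    ifmi = w[["TR"]] * fw$rf + w[["TM"]] * fw$mf_n +
      w[["TP"]] * fw$pf + w[["TF"]] * fw$ff
  )
  structure(out,
    class = c("fmi_series", class(out)),
    weights = w, n_windows = attr(fw, "n_windows"),
    starts = attr(fw, "starts"), window_len = attr(fw, "window_len"),
    fs = attr(fw, "fs")
  )
}

#' Dominant synergy mode per sample
#'
#' For each time sample, the index of the synergy mode with the largest
#' activation coefficient (rows of `H`); ties break toward the lower index.
#' With two modes this is the Boolean rule "mode 1 dominates when its
#' activation coefficient exceeds mode 2's".
#'
#' @param H non-negative R x samples activation matrix (e.g. from [nmf()]).
#' @return Integer vector of mode indices in 1..R with attribute `rank`.
#' @examples
#' dominant_modes(rbind(c(0.9, 0.1), c(0.1, 0.9)))
#' @export
dominant_modes <- function(H) {
  H <- as.matrix(H)
  if (!nrow(H)) abort_argument("`H` must have at least one row")
  modes <- max.col(t(H), ties.method = "first")
  structure(as.integer(modes), rank = nrow(H))
}

#' Duration multi-muscle weight coefficient matrix (DMWCM)
#'
#' Column t of the output is the muscle-weight column of the synergy mode
#' dominant at t, optionally renormalized to sum 1 per sample so the
#' comprehensive fatigue index is a convex combination of per-muscle indices.
#'
#' @param W channels x R muscle-weight matrix; columns correspond to mode
#'   indices.
#' @param modes integer vector of dominant modes (from [dominant_modes()],
#'   possibly aggregated per window).
#' @param renormalize divide each column by its sum (default TRUE).
#' @return channels x length(modes) weight matrix.
#' @export
dmwcm <- function(W, modes, renormalize = TRUE) {
  W <- as.matrix(W)
  modes <- as.integer(modes)
  if (any(modes < 1L) || any(modes > ncol(W))) {
    abort("dominant-mode index out of range", class = "pianosynergy_internal_error")
  }
  out <- W[, modes, drop = FALSE]
  if (renormalize) {
    cs <- colSums(out)
    zero <- cs <= 0
    cs[zero] <- 1
    out <- sweep(out, 2, cs, "/")
    if (any(zero)) out[, zero] <- 1 / nrow(W)
  }
  dimnames(out) <- list(rownames(W), NULL)
  out
}

#' Aggregate sample-level dominant modes to feature windows
#'
#' Majority vote of the per-sample dominant mode inside each feature window
#' (ties toward the lower mode index), aligning the DMWCM time base with the
#' windowed fatigue features.
#'
#' @param modes integer vector from [dominant_modes()] (one entry per sample).
#' @param starts window start samples (attribute `starts` of a
#'   [window_features()] result).
#' @param window_len window length in samples.
#' @return Integer vector, one dominant mode per window.
#' @export
modes_by_window <- function(modes, starts, window_len) {
  vapply(starts, function(s) {
    sl <- s:min(s + window_len - 1L, length(modes))
    tab <- tabulate(modes[sl])
    which.max(tab)
  }, integer(1))
}

#' Comprehensive Muscle Fatigue Index (CMFI)
#'
#' Weighted sum of the per-muscle fatigue indices under the dominant-mode
#' muscle weights: `cmfi(t) = sum_i s_i_main(t) * ifmi_i(t)`. With
#' renormalized DMWCM columns and normalized features the index lies in
#' [0, 1].
#'
#' @param dmwcm_mat channels x windows weight matrix (see [dmwcm()] and
#'   [modes_by_window()]).
#' @param ifmi an `fmi_series` from [single_muscle_fmi()], or a channels x
#'   windows matrix.
#' @return Object of class `cmfi_series`: tibble `window`, `time_s`, `cmfi`;
#'   attributes `ifmi` (channels x windows matrix), `dmwcm`, `channels`.
#' @export
cmfi <- function(dmwcm_mat, ifmi) {
  if (inherits(ifmi, "fmi_series")) {
    times <- unique(ifmi[, c("window", "time_s")])
    M <- t(matrix_from_long(ifmi, "ifmi"))
  } else {
    M <- as.matrix(ifmi)
    times <- tibble::tibble(
      window = seq_len(ncol(M)),
      time_s = NA_real_
    )
  }
  if (ncol(dmwcm_mat) != ncol(M) || nrow(dmwcm_mat) != nrow(M)) {
    abort_argument("DMWCM and IFMI time bases or channel counts are misaligned")
  }
  vals <- colSums(dmwcm_mat * M)
  out <- tibble::tibble(window = times$window, time_s = times$time_s, cmfi = vals)
  structure(out,
    class = c("cmfi_series", class(out)),
    ifmi = M, dmwcm = dmwcm_mat, channels = rownames(M)
  )
}

# long (window x channel) tibble -> windows x channels matrix for one column
matrix_from_long <- function(df, col) {
  wide <- tidyr::pivot_wider(
    df[, c("window", "channel", col)],
    names_from = "channel", values_from = dplyr::all_of(col)
  )
  as.matrix(wide[, -1, drop = FALSE])
}

#' Threshold-based rest prompting with hysteresis
#'
#' Raises a rest flag at the first window where the CMFI reaches `threshold`
#' and keeps it raised until the value drops below `resume_below` (training
#' resumes only then).
#'
#' @param series a [cmfi()] result.
#' @param threshold rest threshold in (0, 1].
#' @param resume_below clearing level (<= `threshold`; default `threshold`).
#' @return The series with added logical column `rest_flag` and attributes
#'   `threshold`, `resume_below`.
#' @examples
#' s <- cmfi(matrix(1, 1, 4), matrix(c(0.2, 0.8, 0.9, 0.5), 1))
#' monitor_fatigue(s, threshold = 0.7, resume_below = 0.7)$rest_flag
#' @export
monitor_fatigue <- function(series, threshold = 0.7, resume_below = 0.6) {
  stopifnot(inherits(series, "cmfi_series"))
  if (!is_number(threshold) || threshold <= 0 || threshold > 1) {
    abort_argument("`threshold` must lie in (0, 1]")
  }
  if (!is_number(resume_below) || resume_below > threshold) {
    abort_argument("`resume_below` must not exceed `threshold`")
  }
  at <- attributes(series)
  flags <- logical(nrow(series))
  on <- FALSE
  for (i in seq_len(nrow(series))) {
    v <- series$cmfi[i]
    if (!on && v >= threshold) on <- TRUE
    if (on && v < resume_below) on <- FALSE
    flags[i] <- on
  }
  out <- series
  out$rest_flag <- flags
  for (nm in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(out, nm) <- at[[nm]]
  }
  attr(out, "threshold") <- threshold
  attr(out, "resume_below") <- resume_below
  class(out) <- at$class
  out
}

#' Calibrate feature weights against a fatigue ground truth
#'
#' Non-negative least squares regression of an external fatigue reference
#' (e.g. a perceived-exertion trajectory) on the four channel-averaged
#' normalized features, renormalized to sum 1. Falls back to equal weights
#' (with a warning) when the design is rank deficient or the regression
#' degenerates; warns when the reference is poorly explained.
#'
#' @param fw a normalized [window_features()] result with >= 8 windows.
#' @param ground_truth numeric vector, one fatigue value per window.
#' @return A [fatigue_weights()].
#' @export
calibrate_weights <- function(fw, ground_truth) {
  stopifnot(inherits(fw, "feature_windows"))
  if (!isTRUE(attr(fw, "normalized"))) {
    abort_argument("normalized features missing: run normalize_features() first")
  }
  nw <- attr(fw, "n_windows")
  if (nw < 8) abort_argument("need at least 8 windows to calibrate")
  if (length(ground_truth) != nw) {
    abort_argument("`ground_truth` must have one value per window")
  }
  means <- fw |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(
      rf = mean(.data$rf), mf_n = mean(.data$mf_n),
      pf = mean(.data$pf), ff = mean(.data$ff), .groups = "drop"
    )
  X <- as.matrix(means[, c("rf", "mf_n", "pf", "ff")])
  if (qr(X)$rank < 4) {
    warn("rank-deficient feature design; falling back to equal weights")
    return(fatigue_weights())
  }
  w <- tryCatch(pracma::lsqnonneg(X, as.numeric(ground_truth))$x,
    error = function(e) NULL
  )
  if (is.null(w) || sum(w) <= 0) {
    warn("non-negative regression degenerated; falling back to equal weights")
    return(fatigue_weights())
  }
  pred <- X %*% w
  ss_tot <- sum((ground_truth - mean(ground_truth))^2)
  if (ss_tot > 0 && 1 - sum((ground_truth - pred)^2) / ss_tot < 0.2) {
    warn("calibration explains little of the ground-truth variance")
  }
  w <- w / sum(w)
  fatigue_weights(TR = w[1], TM = w[2], TP = w[3], TF = w[4])
}

#' End-to-end CMFI computation from a recording
#'
#' Runs the full fatigue-monitoring chain: windowed feature extraction and
#' normalization, single-muscle fatigue indices, rank-R NMF of the rectified
#' smoothed envelope, per-window dominant synergy modes, the DMWCM, the CMFI
#' trajectory, and threshold-based rest flags.
#'
#' @param rec an [emg_recording()].
#' @param rank NMF synergy modes (default 2).
#' @param weights a [fatigue_weights()] (default equal).
#' @param window_s,step_s feature windows (defaults 1 s, 50% overlap).
#' @param threshold,resume_below rest-prompt hysteresis (defaults 0.7, 0.6).
#' @param envelope_s moving-average envelope window before NMF (default
#'   0.125 s).
#' @param normalize_mode passed to [normalize_features()].
#' @param seed integer seed for the NMF restarts.
#' @param nmf_restarts NMF restarts (default 2).
#' @param pe_order,pe_delay,fd_kmax feature parameters.
#' @return A monitored `cmfi_series` (see [cmfi()] and [monitor_fatigue()])
#'   with attributes `features` (the normalized [window_features()] tibble),
#'   `nmf_model` and `weights`.
#' @export
cmfi_pipeline <- function(rec, rank = 2L, weights = fatigue_weights(),
                          window_s = 1, step_s = 0.5,
                          threshold = 0.7, resume_below = 0.6,
                          envelope_s = 0.125,
                          normalize_mode = "recording_minmax",
                          seed = 1L, nmf_restarts = 2L,
                          pe_order = 4L, pe_delay = 1L, fd_kmax = 8L) {
  stopifnot(inherits(rec, "emg_recording"))
  fw <- window_features(rec, window_s, step_s, pe_order, pe_delay, fd_kmax)
  fw <- normalize_features(fw, normalize_mode)
  ifmi <- single_muscle_fmi(fw, weights)
  env_win <- max(1L, round(envelope_s * rec_fs(rec)))
  env <- t(apply(abs(unclass(rec)), 1, moving_average, width = env_win))
  model <- nmf(env, rank = rank, seed = seed, restarts = nmf_restarts)
  modes <- dominant_modes(model$H)
  wmodes <- modes_by_window(modes, attr(fw, "starts"), attr(fw, "window_len"))
  Smat <- dmwcm(model$W, wmodes)
  series <- cmfi(Smat, ifmi)
  series <- monitor_fatigue(series, threshold, resume_below)
  attr(series, "features") <- fw
  attr(series, "nmf_model") <- model
  attr(series, "weights") <- if (inherits(weights, "fatigue_weights")) {
    weights
  } else {
    do.call(fatigue_weights, as.list(weights))
  }
  series
}
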