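#' Ground-truth synergy structure for synthetic sEMG
#'
#' Defines the latent low-rank structure a synthetic recording is generated
#' from: non-negative muscle weights (one column per synergy, unit Euclidean
#' norm), non-negative temporal activation waveforms, the carrier band of the
#' sEMG interference pattern, and the additive sensor-noise level.
#'
#' @param muscle_weights non-negative channels x R matrix; columns are
#'   normalized to unit Euclidean norm.
#' @param activations non-negative R x samples matrix of activation waveforms.
#' @param carrier_band length-2 frequency interval in Hz for the band-limited
#'   carrier (default 20-150 Hz, the band holding the bulk of sEMG energy).
#' @param noise_sd standard deviation of additive Gaussian sensor noise (mV).
#' @param seed integer seed; generation is bitwise reproducible under it.
#' @return Object of class `synergy_ground_truth`.
#' @examples
#' W <- matrix(c(1, 0.2, 0.1, 1), 2)
#' H <- make_activation_waveforms(2, 400, fs = 400, seed = 1)
#' truth <- synergy_ground_truth(W, H, seed = 1)
#' @export
synergy_ground_truth <- function(muscle_weights, activations,
                                 carrier_band = c(20, 150),
                                 noise_sd = 0, seed = 1L) {
  if (!is.matrix(muscle_weights) || any(muscle_weights < 0)) {
    abort_argument("`muscle_weights` must be a non-negative matrix")
  }
  if (!is.matrix(activations) || any(activations < 0) ||
    !all(is.finite(activations))) {
    abort_argument("`activations` must be a finite non-negative matrix")
  }
  if (ncol(muscle_weights) != nrow(activations)) {
    abort_argument("ncol(muscle_weights) must equal nrow(activations)")
  }
  if (length(carrier_band) != 2 || carrier_band[1] <= 0 ||
    carrier_band[2] <= carrier_band[1]) {
    abort_argument("`carrier_band` must be an increasing positive interval")
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    abort_argument("`noise_sd` must be a non-negative number")
  }
  nrm <- sqrt(colSums(muscle_weights^2))
  nrm[nrm == 0] <- 1
  structure(
    list(
      muscle_weights = sweep(muscle_weights, 2, nrm, "/"),
      activations = activations,
      carrier_band = as.numeric(carrier_band),
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "synergy_ground_truth"
  )
}

#' @export
print.synergy_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<synergy_ground_truth> %d channels, R = %d, %d samples, band %g-%g Hz, noise_sd %g\n",
    nrow(x$muscle_weights), ncol(x$muscle_weights), ncol(x$activations),
    x$carrier_band[1], x$carrier_band[2], x$noise_sd
  ))
  invisible(x)
}

#' Smooth non-negative activation waveforms
#'
#' Builds `R` temporal activation waveforms as sums of Gaussian bumps with
#' distinct, randomly placed centers; each waveform is rescaled to peak
#' value 1. These emulate burst-like muscle recruitment during key presses.
#'
#' @param R number of synergy components (>= 1).
#' @param samples number of time samples (>= 1).
#' @param fs sampling rate in Hz (sets bump widths in seconds).
#' @param seed integer seed.
#' @return Non-negative R x samples matrix with `max == 1` per row.
#' @examples
#' H <- make_activation_waveforms(3, 1200, 400, seed = 2)
#' range(H)
#' @export
make_activation_waveforms <- function(R, samples, fs = 400, seed = 1L) {
  if (!is_count(R)) abort_argument("`R` must be a positive integer")
  if (!is_count(samples)) abort_argument("`samples` must be a positive integer")
  if (!is_number(fs) || fs <= 0) abort_argument("`fs` must be positive")
  dur <- samples / fs
  tt <- (seq_len(samples) - 1) / fs
  withr::with_seed(as.integer(seed), {
    H <- matrix(0, R, samples)
    for (r in seq_len(R)) {
      # key-press-like bursts: short (~0.1-0.2 s) and mostly disjoint
      # across components, so the latent factors stay identifiable
      n_bumps <- max(2L, floor(dur / 1.0))
      grid <- (seq_len(n_bumps) - runif(n_bumps, 0.1, 0.9)) / n_bumps
      centers <- pmin(pmax(grid + (r - 1) / (n_bumps * R), 0.02), 0.98) * dur
      widths <- runif(n_bumps, 0.1, 0.22)
      amps <- runif(n_bumps, 0.5, 1)
      for (b in seq_len(n_bumps)) {
        H[r, ] <- H[r, ] + amps[b] * exp(-(tt - centers[b])^2 / (2 * widths[b]^2))
      }
      H[r, ] <- H[r, ] / max(H[r, ])
    }
    H
  })
}

# Unit-variance Gaussian noise band-passed to `band`; the stochastic
# interference-pattern carrier the activation envelope modulates.
bandlimited_carrier <- function(n, fs, band) {
  x <- rnorm(n)
  ny <- fs / 2
  bf <- signal::butter(4, pmin(band / ny, 0.999), type = "pass")
  y <- signal::filtfilt(bf, x)
  s <- sd(y)
  if (s > 0) y / s else y
}

#' Generate synthetic sEMG from a known synergy structure
#'
#' Channel i is \eqn{\sum_r W_{ir} H_r(t) c_i(t) + \epsilon(t)}: the low-rank
#' non-negative envelope amplitude-modulates a per-channel unit-variance
#' band-limited Gaussian carrier, plus additive Gaussian noise. The envelope
#' matrix \eqn{W H} has rank exactly R when the factors are full rank, so the
#' recording carries a known ground truth for factorization methods.
#'
#' @param truth a [synergy_ground_truth()].
#' @param fs sampling rate in Hz; `truth$carrier_band` must lie inside
#'   (0, fs/2).
#' @param samples number of samples; defaults to the activation length.
#' @return An [emg_recording()].
#' @examples
#' W <- diag(2)
#' H <- make_activation_waveforms(2, 800, 400, seed = 3)
#' rec <- generate_synergy_emg(synergy_ground_truth(W, H, seed = 3), fs = 400)
#' @export
generate_synergy_emg <- function(truth, fs = 400, samples = ncol(truth$activations)) {
  stopifnot(inherits(truth, "synergy_ground_truth"))
  if (truth$carrier_band[2] >= fs / 2) {
    abort_argument("carrier band must lie strictly inside (0, fs/2)")
  }
  if (samples > ncol(truth$activations)) {
    abort_argument("`samples` exceeds the activation waveform length")
  }
  W <- truth$muscle_weights
  H <- truth$activations[, seq_len(samples), drop = FALSE]
  ne <- nrow(W)
  env <- W %*% H
  withr::with_seed(truth$seed, {
    X <- matrix(0, ne, samples)
    for (i in seq_len(ne)) {
      carrier <- bandlimited_carrier(samples, fs, truth$carrier_band)
      X[i, ] <- env[i, ] * carrier
      if (truth$noise_sd > 0) X[i, ] <- X[i, ] + rnorm(samples, 0, truth$noise_sd)
    }
    emg_recording(X, fs = fs, channel_names = default_channel_names(ne))
  })
}

#' Default ground truth used across examples and validation
#'
#' Four-channel, three-synergy structure: each synergy loads dominantly on a
#' different muscle with mild cross-talk, with burst-like activation
#' waveforms. Mirrors the montage (ED, FDS, ECU, FCU) of a piano-playing
#' session.
#'
#' @param channels number of channels (default 4).
#' @param R number of synergies (default 3).
#' @param samples number of time samples (default 1200).
#' @param fs sampling rate (default 400 Hz).
#' @param noise_sd additive noise SD; `NULL` (default) picks 5% of the RMS of
#'   the noiseless envelope signal (a low-noise setting).
#' @param seed integer seed.
#' @return A [synergy_ground_truth()].
#' @export
default_synergy_truth <- function(channels = 4, R = 3, samples = 1200,
                                  fs = 400, noise_sd = NULL, seed = 1L) {
  H <- make_activation_waveforms(R, samples, fs, seed = seed)
  W <- withr::with_seed(as.integer(seed) + 1L, {
    W <- matrix(runif(channels * R, 0.05, 0.3), channels, R)
    for (r in seq_len(R)) {
      W[((r - 1) %% channels) + 1L, r] <- W[((r - 1) %% channels) + 1L, r] + 1
    }
    W
  })
  if (is.null(noise_sd)) {
    Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    env <- Wn %*% H
    noise_sd <- 0.05 * sqrt(mean(env^2))
  }
  synergy_ground_truth(W, H, noise_sd = noise_sd, seed = seed)
}

#' Programmed fatigue session
#'
#' Describes a synthetic fatigue-inducing session: its duration and, per
#' fatigue feature, the (start, end) multiplier of a linear ramp. With
#' multipliers RMS 1 -> 1.5 and MF/PE/FD 1 -> <1 the session emulates a
#' progressively harder 3-minute piano task in which amplitude grows while
#' the spectrum compresses toward low frequencies.
#'
#' @param duration_s session duration in seconds (> 0; default 180 s).
#' @param ramp named list with elements `RMS`, `MF`, `PE`, `FD`, each a
#'   length-2 positive (start, end) multiplier.
#' @param seed integer seed.
#' @return Object of class `fatigue_program`.
#' @export
fatigue_program <- function(duration_s = 180,
                            ramp = list(
                              RMS = c(1, 1.5), MF = c(1, 0.7),
                              PE = c(1, 0.8), FD = c(1, 0.8)
                            ),
                            seed = 1L) {
  if (!is_number(duration_s) || duration_s <= 0) {
    abort_argument("`duration_s` must be positive")
  }
  need <- c("RMS", "MF", "PE", "FD")
  if (!all(need %in% names(ramp))) {
    abort_argument("`ramp` must name RMS, MF, PE and FD")
  }
  for (nm in need) {
    r <- ramp[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0)) {
      abort_argument(sprintf("ramp multipliers for %s must be positive", nm))
    }
  }
  structure(list(duration_s = duration_s, ramp = ramp[need], seed = as.integer(seed)),
    class = "fatigue_program"
  )
}

#' Generate a synthetic fatigue session
#'
#' Produces a multichannel recording whose windowed features drift along the
#' programmed ramps. Mechanism: band-limited Gaussian noise is passed through
#' a time-varying first-order low-pass whose cutoff tracks the MF ramp
#' (compressing the spectrum toward low frequencies so median frequency,
#' permutation entropy and fractal dimension all fall), a slow deterministic
#' oscillation scaled by the PE/FD ramps adds waveform regularity, the local
#' RMS (1 s moving window) is normalized out, and the RMS ramp is applied as
#' an explicit amplitude profile.
#'
#' @param program a [fatigue_program()].
#' @param channels number of channels (>= 1).
#' @param fs sampling rate in Hz.
#' @return List with `recording` (an [emg_recording()]) and `level`, a tibble
#'   `time_s`, `level` giving the programmed fatigue level in [0, 1] per
#'   sample.
#' @examples
#' ses <- generate_fatigue_emg(fatigue_program(duration_s = 10), channels = 2)
#' ses$recording
#' @export
generate_fatigue_emg <- function(program, channels = 4, fs = 400) {
  stopifnot(inherits(program, "fatigue_program"))
  if (!is_count(channels)) abort_argument("`channels` must be a positive integer")
  if (program$duration_s < 2) {
    abort_argument("`duration_s` must cover at least two feature windows (>= 2 s)")
  }
  n <- round(program$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  level <- tt / max(tt)
  mult <- function(nm) {
    r <- program$ramp[[nm]]
    r[1] + (r[2] - r[1]) * level
  }
  m_rms <- mult("RMS")
  m_mf <- mult("MF")
  m_pe <- mult("PE")
  m_fd <- mult("FD")
  # Low-pass cutoff tracking the MF ramp; 140 Hz at multiplier 1 leaves the
  # 20-150 Hz carrier nearly untouched, lower multipliers compress it.
  fc_lp <- 140 * pmax(m_mf, 0.05)^2.5
  a_lp <- exp(-2 * pi * fc_lp / fs)
  det_amp <- 1.2 * (1 - pmin(m_pe, m_fd))
  win <- max(3L, round(fs))
  rec <- withr::with_seed(program$seed, {
    gains <- runif(channels, 0.8, 1.2)
    phases <- runif(channels, 0, 2 * pi)
    X <- matrix(0, channels, n)
    for (i in seq_len(channels)) {
      x <- bandlimited_carrier(n, fs, c(20, min(150, fs / 2 * 0.95)))
      y <- numeric(n)
      acc <- 0
      for (k in seq_len(n)) {
        acc <- a_lp[k] * acc + (1 - a_lp[k]) * x[k]
        y[k] <- acc
      }
      loc <- sqrt(pmax(moving_average(y^2, win), 1e-12))
      y <- y / loc
      y <- y + det_amp * sin(2 * pi * 6 * tt + phases[i])
      loc <- sqrt(pmax(moving_average(y^2, win), 1e-12))
      y <- y / loc
      X[i, ] <- 0.3 * gains[i] * m_rms * y
    }
    emg_recording(X, fs = fs, channel_names = default_channel_names(channels))
  })
  list(
    recording = rec,
    level = tibble::tibble(time_s = tt, level = level)
  )
}
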