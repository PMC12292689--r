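#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a 3-D synergy model
#'
#' @param x a `synergy_model_3d` from [cp_als()].
#' @param ... unused.
#' @return Long tibble with columns `component`, `mode` (frequency /
#'   temporal / spatial), `index`, `axis` (frequency in Hz, time sample, or
#'   channel label) and `value`.
#' @export
tidy.synergy_model_3d <- function(x, ...) {
  freqs <- x$freqs_hz %||% seq_len(nrow(x$F))
  chans <- x$channel_names %||% as.character(seq_len(nrow(x$S)))
  one <- function(M, mode, axis) {
    tibble::tibble(
      component = rep(seq_len(ncol(M)), each = nrow(M)),
      mode = mode,
      index = rep(seq_len(nrow(M)), ncol(M)),
      axis = rep(as.character(axis), ncol(M)),
      value = as.vector(M)
    )
  }
  dplyr::bind_rows(
    one(x$F, "frequency", freqs),
    one(x$T, "temporal", seq_len(nrow(x$T))),
    one(x$S, "spatial", chans)
  )
}

#' @rdname tidy.synergy_model_3d
#' @export
glance.synergy_model_3d <- function(x, ...) {
  tibble::tibble(
    rank = x$rank, fit = x$fit, mean_restart_fit = mean(x$fits),
    n_iter = x$n_iter, converged = x$converged
  )
}

#' Tidy a 2-D synergy model
#'
#' @param x a `synergy_model_2d` from [nmf()].
#' @param ... unused.
#' @return Long tibble with `component`, `mode` (spatial / temporal),
#'   `index`, `value`.
#' @export
tidy.synergy_model_2d <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      component = rep(seq_len(ncol(x$W)), each = nrow(x$W)),
      mode = "spatial",
      index = rep(seq_len(nrow(x$W)), ncol(x$W)),
      value = as.vector(x$W)
    ),
    tibble::tibble(
      component = rep(seq_len(nrow(x$H)), ncol(x$H)),
      mode = "temporal",
      index = rep(seq_len(ncol(x$H)), each = nrow(x$H)),
      value = as.vector(x$H)
    )
  )
}

#' @rdname tidy.synergy_model_2d
#' @export
glance.synergy_model_2d <- function(x, ...) {
  tibble::tibble(
    rank = x$rank, fit = x$fit, n_iter = x$n_iter, converged = x$converged
  )
}

#' Tidy a rank-selection result
#'
#' @param x a [select_rank()] result.
#' @param ... unused.
#' @return The FIT curve tibble with a `selected` flag.
#' @export
tidy.rank_selection <- function(x, ...) {
  out <- x$fit_curve
  out$selected <- out$rank == x$rank
  out
}

#' Tidy a similarity report into (pair, domain, r) rows
#'
#' @param x a [compare_synergies()] result.
#' @param ... unused.
#' @return Tibble with columns `pair`, `domain`, `r`.
#' @export
tidy.similarity_report <- function(x, ...) {
  tibble::as_tibble(x)[c("pair", "spatial_r", "frequency_r", "temporal_r")] |>
    tidyr::pivot_longer(-"pair", names_to = "domain", values_to = "r") |>
    dplyr::mutate(domain = sub("_r$", "", .data$domain))
}

#' @rdname tidy.similarity_report
#' @export
glance.similarity_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    mean_spatial_r = mean(x$spatial_r),
    mean_frequency_r = mean(x$frequency_r),
    mean_temporal_r = mean(x$temporal_r),
    n_subject_synergies = attr(x, "n_subject_synergies"),
    n_reference_synergies = attr(x, "n_reference_synergies")
  )
}

#' Tidy windowed fatigue features into long form
#'
#' @param x a [window_features()] result.
#' @param ... unused.
#' @return Long tibble `window`, `time_s`, `channel`, `feature`, `value`.
#' @export
tidy.feature_windows <- function(x, ...) {
  keep <- intersect(c("rms", "mf", "pe", "fd", "rf", "mf_n", "pf", "ff"), names(x))
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(keep),
      names_to = "feature", values_to = "value"
    )
}

#' @rdname cmfi
#' @param x a `cmfi_series`.
#' @param ... unused.
#' @export
glance.cmfi_series <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    max_cmfi = max(x$cmfi),
    mean_cmfi = mean(x$cmfi),
    prop_rest = if ("rest_flag" %in% names(x)) mean(x$rest_flag) else NA_real_,
    threshold = attr(x, "threshold") %||% NA_real_
  )
}

#' Plot an EMG tensor as per-channel scalograms
#'
#' @param object an [emg_tensor()].
#' @param ... unused.
#' @return A ggplot: time-frequency magnitude rasters faceted by channel.
#' @export
autoplot.emg_tensor <- function(object, ...) {
  d <- dim(object)
  df <- tibble::tibble(
    freq_hz = rep(attr(object, "freqs_hz"), times = d[2] * d[3]),
    t = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    channel = rep(attr(object, "channel_names"), each = d[1] * d[2]),
    value = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$freq_hz, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c(name = "|CWT|") +
    ggplot2::labs(x = "time (samples)", y = "frequency (Hz)")
}

#' Plot the factors of a 3-D synergy model
#'
#' @param object a `synergy_model_3d`.
#' @param ... unused.
#' @return A ggplot faceted by domain (frequency, temporal, spatial) and
#'   component.
#' @export
autoplot.synergy_model_3d <- function(object, ...) {
  df <- tidy(object)
  df$mode <- factor(df$mode, c("frequency", "temporal", "spatial"))
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$value)) +
    ggplot2::geom_col(
      data = ~ dplyr::filter(.x, .data$mode == "spatial"), width = 0.7
    ) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$mode != "spatial")) +
    ggplot2::facet_grid(component ~ mode, scales = "free") +
    ggplot2::labs(x = NULL, y = "loading")
}

#' Plot the FIT curve of a rank selection
#'
#' @param object a [select_rank()] result.
#' @param ... unused.
#' @return A ggplot of mean FIT against rank with the selected rank marked.
#' @export
autoplot.rank_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$mean_fit)) +
    ggplot2::geom_hline(yintercept = object$fit_threshold, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::labs(x = "number of synergies", y = "mean FIT", colour = "selected")
}

#' Plot a CMFI trajectory
#'
#' @param object a `cmfi_series` (ideally monitored, see
#'   [monitor_fatigue()]).
#' @param ... unused.
#' @return A ggplot of CMFI against time with the rest threshold and flagged
#'   windows highlighted.
#' @export
autoplot.cmfi_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$cmfi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "CMFI")
  thr <- attr(object, "threshold")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "red")
  }
  if ("rest_flag" %in% names(df) && any(df$rest_flag)) {
    p <- p + ggplot2::geom_point(
      data = ~ dplyr::filter(.x, .data$rest_flag),
      colour = "red", size = 1.5
    )
  }
  p
}

#' Plot windowed fatigue features
#'
#' @param object a [window_features()] result.
#' @param ... unused.
#' @return A ggplot of each raw feature over time, coloured by channel.
#' @export
autoplot.feature_windows <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$feature %in% c("rms", "mf", "pe", "fd"), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value, colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot a simulated hand trace
#'
#' @param object a [simulate_hand()] result.
#' @param ... unused.
#' @return A ggplot of joint angles, torques and key force over time.
#' @export
autoplot.sim_trace <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"t", names_to = "signal", values_to = "value")
  df$group <- dplyr::case_when(
    grepl("^theta_dot_", df$signal) ~ "joint velocity (rad/s)",
    grepl("^theta_", df$signal) ~ "joint angle (rad)",
    grepl("^tau_", df$signal) ~ "torque (N m)",
    grepl("^Fa_", df$signal) ~ "assistive force (N)",
    TRUE ~ "key force (N)"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value, colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
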