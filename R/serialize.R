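#' Write a synergy model to JSON
#'
#' Serializes the factor matrices and metadata (rank, fit, seed) of a 2-D or
#' 3-D synergy model as nested numeric lists, so models can be exchanged
#' between sessions and subjects.
#'
#' @param model a `synergy_model_3d` or `synergy_model_2d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synergy_model <- function(model, path) {
  if (is_synergy_model_3d(model)) {
    payload <- list(
      type = "synergy_model_3d",
      F = model$F, T = model$T, S = model$S,
      rank = model$rank, fit = model$fit, fits = model$fits,
      n_iter = model$n_iter, converged = model$converged, seed = model$seed,
      freqs_hz = model$freqs_hz, channel_names = model$channel_names
    )
  } else if (inherits(model, "synergy_model_2d")) {
    payload <- list(
      type = "synergy_model_2d",
      W = model$W, H = model$H,
      rank = model$rank, fit = model$fit,
      n_iter = model$n_iter, converged = model$converged, seed = model$seed
    )
  } else {
    abort_argument("`model` must be a synergy model")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a synergy model from JSON
#'
#' @param path a file written by [write_synergy_model()].
#' @return A `synergy_model_3d` or `synergy_model_2d`.
#' @export
read_synergy_model <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$type, "synergy_model_3d")) {
    structure(
      list(
        F = as.matrix(p$F), T = as.matrix(p$T), S = as.matrix(p$S),
        rank = as.integer(p$rank), fit = p$fit, fits = p$fits,
        n_iter = p$n_iter, converged = p$converged, seed = p$seed,
        freqs_hz = p$freqs_hz, channel_names = p$channel_names
      ),
      class = "synergy_model_3d"
    )
  } else if (identical(p$type, "synergy_model_2d")) {
    structure(
      list(
        W = as.matrix(p$W), H = as.matrix(p$H),
        rank = as.integer(p$rank), fit = p$fit,
        n_iter = p$n_iter, converged = p$converged, seed = p$seed
      ),
      class = "synergy_model_2d"
    )
  } else {
    abort_format("unrecognized model file")
  }
}

#' Write an EMG tensor to disk
#'
#' Stores the array in R's serialization format with a JSON header next to
#' it (shape, frequency axis, channels) for interoperability.
#'
#' @param tensor an [emg_tensor()].
#' @param path output path (e.g. `tensor.rds`).
#' @return `path`, invisibly.
#' @export
write_emg_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "emg_tensor"))
  saveRDS(tensor, path)
  jsonlite::write_json(
    list(
      shape = dim(tensor), freqs_hz = attr(tensor, "freqs_hz"),
      channel_names = attr(tensor, "channel_names")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an EMG tensor written by [write_emg_tensor()]
#'
#' @param path path to the stored tensor.
#' @return An [emg_tensor()].
#' @export
read_emg_tensor <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  obj <- readRDS(path)
  if (!inherits(obj, "emg_tensor")) abort_format("file does not hold an EMG tensor")
  obj
}
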