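#' Pearson correlation coefficient
#'
#' Similarity metric used throughout the rehabilitation assessment:
#' \eqn{r = \frac{n\sum x_i y_i - \sum x_i \sum y_i}
#' {\sqrt{n\sum x_i^2 - (\sum x_i)^2}\sqrt{n\sum y_i^2 - (\sum y_i)^2}}}.
#'
#' @param x,y numeric sequences of equal length `n >= 2`, neither constant.
#' @return Correlation in [-1, 1].
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort_argument("`x` and `y` must have equal length")
  if (length(x) < 2) abort_argument("need at least two observations")
  if (sd(x) == 0 || sd(y) == 0) {
    abort(
      "correlation undefined for a constant sequence",
      class = "pianosynergy_undefined_correlation"
    )
  }
  as.numeric(cor(x, y))
}

# Pearson r that degrades to 0 instead of erroring (used only while scoring
# candidate pairings, where a degenerate column should simply never win).
safe_r <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  as.numeric(cor(x, y))
}

#' Match synergy components between two models
#'
#' Factor order out of a factorization is arbitrary, so components are
#' aligned before any comparison: the injective assignment (over the smaller
#' rank) maximizing the summed Pearson correlation of the spatial
#' muscle-weight columns is found by exhaustive search, with ties broken
#' toward the lowest indices.
#'
#' @param subject,reference `synergy_model_3d` objects (or any lists carrying
#'   a spatial factor `S`).
#' @return Tibble with columns `subject`, `reference`, `spatial_r`, one row
#'   per matched pair, with attributes `unpaired_subject` /
#'   `unpaired_reference` listing components left unmatched when ranks
#'   differ.
#' @export
match_components <- function(subject, reference) {
  S_a <- subject$S
  S_b <- reference$S
  if (is.null(S_a) || is.null(S_b) || !ncol(S_a) || !ncol(S_b)) {
    abort_argument("both models must carry a non-empty spatial factor `S`")
  }
  if (nrow(S_a) != nrow(S_b)) abort_argument("models have different channel counts")
  Ra <- ncol(S_a)
  Rb <- ncol(S_b)
  k <- min(Ra, Rb)
  R_full <- outer(seq_len(Ra), seq_len(Rb), Vectorize(function(i, j) {
    safe_r(S_a[, i], S_b[, j])
  }))
  if (Ra <= Rb) {
    cand <- injections(Rb, Ra)
    scores <- apply(cand, 1, function(asg) sum(R_full[cbind(seq_len(Ra), asg)]))
    asg <- cand[which.max(scores), ]
    pairs <- tibble::tibble(subject = seq_len(Ra), reference = as.integer(asg))
  } else {
    cand <- injections(Ra, Rb)
    scores <- apply(cand, 1, function(asg) sum(R_full[cbind(asg, seq_len(Rb))]))
    asg <- cand[which.max(scores), ]
    pairs <- tibble::tibble(subject = as.integer(asg), reference = seq_len(Rb))
  }
  pairs <- pairs[order(pairs$subject), ]
  pairs$spatial_r <- R_full[cbind(pairs$subject, pairs$reference)]
  structure(pairs,
    unpaired_subject = setdiff(seq_len(Ra), pairs$subject),
    unpaired_reference = setdiff(seq_len(Rb), pairs$reference)
  )
}

resample_columns <- function(M, len) {
  if (nrow(M) == len) return(M)
  apply(M, 2, function(col) {
    approx(seq(0, 1, length.out = length(col)), col,
      xout = seq(0, 1, length.out = len)
    )$y
  })
}

#' Compare subject synergies against a reference model
#'
#' Quantifies rehabilitation progress as the similarity between a subject's
#' synergy factors and a reference (e.g. healthy) model in the spatial,
#' frequency and temporal domains. Pairs are fixed once by spatial-factor
#' correlation ([match_components()]) and reused across domains; temporal
#' factors of different lengths are linearly resampled to the reference
#' length. Correlations are reported as-is (not clamped at zero), and are
#' invariant to per-component positive rescaling of either model.
#'
#' @param subject,reference `synergy_model_3d` objects built over the same
#'   channel set and the same wavelet scale set.
#' @return Object of class `similarity_report`: a tibble with columns `pair`,
#'   `subject`, `reference`, `spatial_r`, `frequency_r`, `temporal_r`;
#'   attributes record unpaired components and the two model ranks.
#' @export
compare_synergies <- function(subject, reference) {
  stopifnot(is_synergy_model_3d(subject), is_synergy_model_3d(reference))
  ch_a <- subject$channel_names %||% rownames(subject$S)
  ch_b <- reference$channel_names %||% rownames(reference$S)
  if (!is.null(ch_a) && !is.null(ch_b) && !identical(ch_a, ch_b)) {
    abort_argument("models were built over different channel sets")
  }
  if (nrow(subject$S) != nrow(reference$S)) {
    abort_argument("models have different channel counts")
  }
  if (nrow(subject$F) != nrow(reference$F)) {
    abort_argument("models were built over different scale sets")
  }
  pairs <- match_components(subject, reference)
  T_sub <- resample_columns(subject$T, nrow(reference$T))
  freq_r <- temp_r <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs$subject[p]
    j <- pairs$reference[p]
    freq_r[p] <- safe_r(subject$F[, i], reference$F[, j])
    temp_r[p] <- safe_r(T_sub[, i], reference$T[, j])
  }
  out <- tibble::tibble(
    pair = seq_len(nrow(pairs)),
    subject = pairs$subject, reference = pairs$reference,
    spatial_r = pairs$spatial_r, frequency_r = freq_r, temporal_r = temp_r
  )
  structure(out,
    class = c("similarity_report", class(out)),
    n_subject_synergies = ncol(subject$S),
    n_reference_synergies = ncol(reference$S),
    unpaired_subject = attr(pairs, "unpaired_subject"),
    unpaired_reference = attr(pairs, "unpaired_reference")
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "<similarity_report> %d pair(s); subject R = %d, reference R = %d\n",
    nrow(x), attr(x, "n_subject_synergies"), attr(x, "n_reference_synergies")
  ))
  print(tibble::as_tibble(x), ...)
  if (length(attr(x, "unpaired_subject"))) {
    cat(
      "unpaired subject component(s):",
      paste(attr(x, "unpaired_subject"), collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Write a similarity report to CSV and JSON
#'
#' @param report a [compare_synergies()] result.
#' @param csv_path,json_path output paths (`NULL` skips either).
#' @return `report`, invisibly.
#' @export
write_similarity_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "similarity_report"))
  long <- tidy.similarity_report(report)
  if (!is.null(csv_path)) {
    write.table(long, csv_path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        pairs = tibble::as_tibble(report),
        n_subject_synergies = attr(report, "n_subject_synergies"),
        n_reference_synergies = attr(report, "n_reference_synergies"),
        unpaired_subject = attr(report, "unpaired_subject"),
        unpaired_reference = attr(report, "unpaired_reference")
      ),
      json_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(report)
}
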