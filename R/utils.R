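#' @importFrom rlang abort warn %||% .data
#' @importFrom stats fft rnorm runif sd cor lm coef approx median quantile
#' @importFrom utils read.table write.table head tail
NULL

abort_argument <- function(msg) abort(msg, class = "pianosynergy_argument_error")
abort_format   <- function(msg) abort(msg, class = "pianosynergy_format_error")
abort_data     <- function(msg) abort(msg, class = "pianosynergy_data_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Moving average with shrinking windows at the edges
#'
#' Centered moving average; near the boundaries the window shrinks so the
#' output has the same length as the input and stays inside the data range
#' (no zero-padding bias, preserves non-negativity).
#'
#' @param x numeric vector.
#' @param width integer window width in samples (values < 2 return `x`).
#' @return numeric vector, same length as `x`.
#' @keywords internal
#' @noRd
moving_average <- function(x, width) {
  n <- length(x)
  if (width < 2 || n < 2) return(x)
  width <- min(width, n)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Rows of all permutations of 1:n in lexicographic order.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# All injective assignments (ordered selections) of k targets out of 1:n,
# lexicographic; rows are the images of 1:k.
injections <- function(n, k) {
  if (k == 0L) return(matrix(integer(0), 1L, 0L))
  if (k == 1L) return(matrix(seq_len(n), ncol = 1L))
  out <- NULL
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    sub <- injections(n - 1L, k - 1L)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow = nrow(sub))))
  }
  dimnames(out) <- NULL
  out
}

# Khatri-Rao (column-wise Kronecker) product: (I*J) x R from I x R and J x R.
khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (r in seq_len(ncol(A))) out[, r] <- kronecker(A[, r], B[, r])
  out
}

# Solve V x = b for a small symmetric system, falling back to a
# pseudo-inverse (SVD) when V is singular.
solve_gram <- function(V, B) {
  out <- tryCatch(solve(V, B), error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- svd(V)
  pos <- s$d > max(s$d[1], 0) * 1e-12
  if (!any(pos)) return(matrix(0, nrow(V), ncol(B)))
  s$v[, pos, drop = FALSE] %*% ((t(s$u[, pos, drop = FALSE]) %*% B) / s$d[pos])
}

default_channel_names <- function(n) {
  base <- c("ED", "FDS", "ECU", "FCU")
  if (n <= length(base)) base[seq_len(n)] else sprintf("ch%02d", seq_len(n))
}
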