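#' @rdname cp_als
#' @param x object to test.
#' @export
is_synergy_model_3d <- function(x) inherits(x, "synergy_model_3d")

unfold <- function(X, mode) {
  d <- dim(X)
  switch(mode,
    `1` = matrix(X, d[1], d[2] * d[3]),
    `2` = matrix(aperm(X, c(2, 1, 3)), d[2], d[1] * d[3]),
    `3` = matrix(aperm(X, c(3, 1, 2)), d[3], d[1] * d[2])
  )
}

# Squared Frobenius norm of the CP model and its inner product with the data,
# computed in factor space (no dense reconstruction needed).
cp_model_norms <- function(X1, F, T_, S) {
  G <- (crossprod(F)) * (crossprod(T_)) * (crossprod(S))
  normY2 <- sum(G)
  inner <- sum(F * (X1 %*% khatri_rao(S, T_)))
  c(normY2 = normY2, inner = inner)
}

# One non-negative mode update. The primary move is the unconstrained
# mode-n least-squares solution (normal equations against the Khatri-Rao
# design) with negative entries clipped to zero; the monotonicity safeguard
# rejects that move whenever it raises the residual and substitutes an exact
# column-wise non-negative coordinate-descent pass (which cannot increase
# the residual). Returns the updated factor and its squared residual.
# `M = X(n) %*% KR`, `G` is the Hadamard product of the other Gram matrices.
update_mode_nn <- function(A_cur, M, G, normX2, res_cur) {
  resid_of <- function(A) {
    max(normX2 - 2 * sum(A * M) + sum(G * crossprod(A)), 0)
  }
  A_ls <- pmax(t(solve_gram(G, t(M))), 0)
  res_ls <- resid_of(A_ls)
  if (res_ls <= res_cur * (1 + 1e-12)) {
    return(list(A = A_ls, res = res_ls))
  }
  A <- A_cur
  for (r in seq_len(ncol(A))) {
    if (G[r, r] <= 1e-300) next
    num <- M[, r] - as.numeric(A %*% G[, r]) + A[, r] * G[r, r]
    A[, r] <- pmax(num / G[r, r], 0)
  }
  list(A = A, res = resid_of(A))
}

cp_als_once <- function(X, rank, max_iter, tol, seed) {
  d <- dim(X)
  X1 <- unfold(X, 1)
  X2 <- unfold(X, 2)
  X3 <- unfold(X, 3)
  normX2 <- sum(X^2)
  init <- withr::with_seed(seed, list(
    F = matrix(abs(rnorm(d[1] * rank)), d[1], rank),
    T = matrix(abs(rnorm(d[2] * rank)), d[2], rank),
    S = matrix(abs(rnorm(d[3] * rank)), d[3], rank)
  ))
  F <- init$F
  T_ <- init$T
  S <- init$S
  nm <- cp_model_norms(X1, F, T_, S)
  prev_res <- max(normX2 - 2 * nm[["inner"]] + nm[["normY2"]], 0)
  init_res <- prev_res
  prev_fit <- 1 - prev_res / normX2
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # update order follows the listing S -> F -> T
    up <- update_mode_nn(
      S, X3 %*% khatri_rao(T_, F), crossprod(T_) * crossprod(F),
      normX2, prev_res
    )
    S <- up$A
    prev_res <- up$res
    up <- update_mode_nn(
      F, X1 %*% khatri_rao(S, T_), crossprod(S) * crossprod(T_),
      normX2, prev_res
    )
    F <- up$A
    prev_res <- up$res
    up <- update_mode_nn(
      T_, X2 %*% khatri_rao(S, F), crossprod(S) * crossprod(F),
      normX2, prev_res
    )
    T_ <- up$A
    prev_res <- up$res
    fit <- 1 - prev_res / normX2
    if (abs(fit - prev_fit) < tol) {
      prev_fit <- fit
      converged <- TRUE
      break
    }
    prev_fit <- fit
  }
  list(
    F = F, T = T_, S = S, fit = 1 - prev_res / normX2,
    resid = sqrt(prev_res), init_resid = sqrt(init_res),
    n_iter = it, converged = converged
  )
}

# Unit-normalize the columns of the frequency and spatial factors, absorbing
# the scale into the temporal factor (identification convention).
normalize_cp_factors <- function(F, T_, S) {
  nf <- sqrt(colSums(F^2))
  ns <- sqrt(colSums(S^2))
  nf[nf == 0] <- 1
  ns[ns == 0] <- 1
  list(
    F = sweep(F, 2, nf, "/"),
    T = sweep(T_, 2, nf * ns, "*"),
    S = sweep(S, 2, ns, "/")
  )
}

#' Non-negative CP decomposition of an EMG tensor (CP-ALS)
#'
#' Fits \eqn{E \approx \sum_{r=1}^{R} F_r \circ T_r \circ S_r} with
#' non-negative frequency (`F`), activation-scaling (`T`) and muscle-weight
#' (`S`) factors by alternating least squares over the mode-3/1/2 unfoldings
#' (update order S, F, T), clipping negative entries after each
#' least-squares update. A monotonicity safeguard rejects any sweep that
#' raises the residual, so the returned model never fits worse than its
#' initialization. Several random restarts are run and the best FIT kept.
#' Factors are identified up to per-component scaling and permutation; the
#' frequency and spatial columns are returned unit-norm with the scale
#' absorbed into the temporal factor.
#'
#' @param tensor an [emg_tensor()] or plain non-negative 3-way array.
#' @param rank number of synergies R (>= 1). A rank above the smallest
#'   tensor dimension triggers a warning but is still attempted.
#' @param max_iter maximum ALS sweeps per restart (default 200).
#' @param tol convergence threshold on the FIT change (default 1e-5).
#' @param seed integer seed; restart k uses `seed + k - 1`.
#' @param restarts number of random restarts (default 5).
#' @return Object of class `synergy_model_3d`: list with factors `F`
#'   (f_bins x R), `T` (t_samples x R), `S` (channels x R), `rank`, `fit`
#'   (best FIT), `fits` (per restart), `n_iter`, `converged`, `seed`,
#'   `freqs_hz`, `channel_names`, `fs`.
#' @examples
#' X <- array(abs(rnorm(4 * 6 * 3)), c(4, 6, 3))
#' m <- cp_als(X, rank = 2, restarts = 2, seed = 1)
#' m$fit
#' @export
cp_als <- function(tensor, rank, max_iter = 200, tol = 1e-5, seed = 1L,
                   restarts = 5L) {
  X <- unclass(tensor)
  if (!is.array(X) || length(dim(X)) != 3) abort_argument("`tensor` must be 3-way")
  if (!is_count(rank)) abort_argument("`rank` must be a positive integer")
  if (rank > min(dim(X))) {
    warn(sprintf(
      "rank %d exceeds the smallest tensor dimension (%d); attempting anyway",
      rank, min(dim(X))
    ))
  }
  meta <- list(
    freqs_hz = attr(tensor, "freqs_hz"),
    channel_names = attr(tensor, "channel_names")
  )
  if (all(X == 0)) {
    d <- dim(X)
    out <- list(
      F = matrix(0, d[1], rank), T = matrix(0, d[2], rank),
      S = matrix(0, d[3], rank), rank = as.integer(rank), fit = 1,
      fits = rep(1, restarts), n_iter = 0L, converged = TRUE,
      seed = as.integer(seed)
    )
    return(structure(c(out, meta), class = "synergy_model_3d"))
  }
  runs <- lapply(seq_len(restarts), function(k) {
    cp_als_once(X, rank, max_iter, tol, as.integer(seed) + k - 1L)
  })
  fits <- vapply(runs, `[[`, numeric(1), "fit")
  best <- runs[[which.max(fits)]]
  fac <- normalize_cp_factors(best$F, best$T, best$S)
  out <- list(
    F = fac$F, T = fac$T, S = fac$S, rank = as.integer(rank),
    fit = best$fit, fits = fits, n_iter = best$n_iter,
    converged = best$converged, seed = as.integer(seed)
  )
  structure(c(out, meta), class = "synergy_model_3d")
}

#' @export
print.synergy_model_3d <- function(x, ...) {
  cat(sprintf(
    "<synergy_model_3d> R = %d, FIT = %.4f (%d restart%s), %s\n",
    x$rank, x$fit, length(x$fits), if (length(x$fits) > 1) "s" else "",
    if (isTRUE(x$converged)) "converged" else "not converged"
  ))
  invisible(x)
}

#' Reconstruct the dense tensor from a CP synergy model
#'
#' @param model a `synergy_model_3d` from [cp_als()].
#' @return 3-way array `nrow(F) x nrow(T) x nrow(S)`.
#' @export
reconstruct_tensor <- function(model) {
  stopifnot(is_synergy_model_3d(model))
  array(
    model$F %*% t(khatri_rao(model$S, model$T)),
    c(nrow(model$F), nrow(model$T), nrow(model$S))
  )
}

#' Reconstruction quality (FIT)
#'
#' \eqn{FIT = 1 - \|X - Y\|_F^2 / \|X\|_F^2}: 1 iff the reconstruction is
#' exact, 0 for the null reconstruction, negative when the model is worse
#' than predicting zero. The all-zero tensor reconstructed by zero has FIT 1
#' by convention.
#'
#' @param original,reconstructed arrays of identical shape.
#' @return FIT value (<= 1).
#' @examples
#' fit_metric(array(2, c(1, 1, 1)), array(1, c(1, 1, 1))) # 0.75
#' @export
fit_metric <- function(original, reconstructed) {
  X <- unclass(original)
  Y <- unclass(reconstructed)
  if (!identical(dim(X), dim(Y))) abort_argument("shapes must match")
  nx2 <- sum(X^2)
  if (nx2 == 0) {
    if (sum(Y^2) == 0) return(1)
    abort_data("FIT undefined: zero-norm original with nonzero reconstruction")
  }
  1 - sum((X - Y)^2) / nx2
}

#' Select the number of synergies from the FIT curve
#'
#' Runs [cp_als()] at ranks `1..r_max` and returns the smallest rank whose
#' mean FIT over restarts reaches `fit_threshold` (default 0.90) while the
#' mean-FIT increment to the next rank is at most `increment` (default 0.02).
#' When no rank qualifies the rank with the highest mean FIT is returned with
#' a warning flag.
#'
#' @param tensor an [emg_tensor()] or 3-way array.
#' @param r_max largest rank tried (>= 2); clipped (with a warning) at the
#'   generic CP rank bound, the smallest pairwise product of dimensions.
#' @param restarts restarts per rank (mean FIT is taken over these).
#' @param seed integer seed.
#' @param fit_threshold mean-FIT requirement (default 0.90).
#' @param increment largest admissible FIT gain from one extra synergy
#'   (default 0.02).
#' @param max_iter,tol passed to [cp_als()].
#' @return Object of class `rank_selection`: list with `rank`, `fit_curve`
#'   (tibble `rank`, `mean_fit`, `best_fit`), `selected_by` ("rule" or
#'   "argmax"), `warning` flag, and `models` (one best model per rank).
#' @export
select_rank <- function(tensor, r_max = 6, restarts = 5L, seed = 1L,
                        fit_threshold = 0.90, increment = 0.02,
                        max_iter = 200, tol = 1e-5) {
  if (!is_count(r_max) || r_max < 2) abort_argument("`r_max` must be >= 2")
  d <- dim(unclass(tensor))
  bound <- min(d[1] * d[2], d[1] * d[3], d[2] * d[3])
  if (r_max > bound) {
    warn(sprintf("r_max clipped from %d to the CP rank bound %d", r_max, bound))
    r_max <- bound
  }
  models <- vector("list", r_max)
  mean_fit <- best_fit <- numeric(r_max)
  for (r in seq_len(r_max)) {
    m <- cp_als(tensor, r,
      max_iter = max_iter, tol = tol, seed = seed, restarts = restarts
    )
    models[[r]] <- m
    mean_fit[r] <- mean(m$fits)
    best_fit[r] <- m$fit
  }
  qualifies <- which(
    mean_fit[-r_max] >= fit_threshold & diff(mean_fit) <= increment
  )
  if (length(qualifies)) {
    rank <- qualifies[1]
    selected_by <- "rule"
    flag <- FALSE
  } else {
    rank <- which.max(mean_fit)
    selected_by <- "argmax"
    flag <- TRUE
    warn("no rank satisfied the FIT rule; returning argmax FIT")
  }
  structure(
    list(
      rank = as.integer(rank),
      fit_curve = tibble::tibble(
        rank = seq_len(r_max), mean_fit = mean_fit, best_fit = best_fit
      ),
      selected_by = selected_by, warning = flag, models = models,
      fit_threshold = fit_threshold, increment = increment
    ),
    class = "rank_selection"
  )
}

#' @export
print.rank_selection <- function(x, ...) {
  cat(sprintf(
    "<rank_selection> rank = %d (%s%s); mean FIT at rank: %.4f\n",
    x$rank, x$selected_by, if (x$warning) ", flagged" else "",
    x$fit_curve$mean_fit[x$rank]
  ))
  invisible(x)
}

nmf_once <- function(V, rank, max_iter, tol, seed) {
  eps <- 1e-12
  ne <- nrow(V)
  ns <- ncol(V)
  init <- withr::with_seed(seed, list(
    W = matrix(abs(rnorm(ne * rank)) + 0.1, ne, rank),
    H = matrix(abs(rnorm(ns * rank)) + 0.1, rank, ns)
  ))
  W <- init$W
  H <- init$H
  obj <- numeric(0)
  prev <- sum((V - W %*% H)^2)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    cur <- sum((V - W %*% H)^2)
    obj <- c(obj, cur)
    if (abs(prev - cur) < tol * max(prev, eps)) {
      converged <- TRUE
      prev <- cur
      break
    }
    prev <- cur
  }
  list(W = W, H = H, objective = obj, resid2 = prev, n_iter = it, converged = converged)
}

#' Non-negative matrix factorization of an EMG matrix
#'
#' Factorizes a non-negative channels x samples matrix (rectified or
#' enveloped EMG) as `V ~ W %*% H` under Frobenius loss using the standard
#' multiplicative updates, whose objective is non-increasing at every
#' iteration. `W` holds the muscle weights (columns unit-norm, scale absorbed
#' into `H`), `H` the activation coefficients. Used by the fatigue path with
#' `rank = 2` synergy modes by default (see [cmfi_pipeline()]).
#'
#' @param mat non-negative numeric matrix.
#' @param rank number of synergy modes.
#' @param max_iter,tol stopping rule (relative objective change).
#' @param seed integer seed; restart k uses `seed + k - 1`.
#' @param restarts random restarts, best FIT kept (default 3).
#' @return Object of class `synergy_model_2d`: list with `W`, `H`, `rank`,
#'   `fit`, `objective` (per-iteration trajectory of the kept run),
#'   `n_iter`, `converged`, `seed`.
#' @examples
#' V <- outer(c(1, 2), c(3, 1, 2))
#' nmf(V, 1, seed = 1)$fit
#' @export
nmf <- function(mat, rank, max_iter = 200, tol = 1e-6, seed = 1L, restarts = 3L) {
  V <- as.matrix(mat)
  if (any(V < 0)) {
    abort_data("input has negative entries: rectify or envelope the EMG first")
  }
  if (!is_count(rank)) abort_argument("`rank` must be a positive integer")
  if (all(V == 0)) {
    out <- list(
      W = matrix(0, nrow(V), rank), H = matrix(0, rank, ncol(V)),
      rank = as.integer(rank), fit = 1, objective = numeric(0),
      n_iter = 0L, converged = TRUE, seed = as.integer(seed)
    )
    return(structure(out, class = "synergy_model_2d"))
  }
  runs <- lapply(seq_len(restarts), function(k) {
    nmf_once(V, rank, max_iter, tol, as.integer(seed) + k - 1L)
  })
  res <- vapply(runs, `[[`, numeric(1), "resid2")
  best <- runs[[which.min(res)]]
  nw <- sqrt(colSums(best$W^2))
  nw[nw == 0] <- 1
  W <- sweep(best$W, 2, nw, "/")
  H <- sweep(best$H, 1, nw, "*")
  rownames(W) <- rownames(V)
  structure(
    list(
      W = W, H = H, rank = as.integer(rank),
      fit = 1 - best$resid2 / sum(V^2), objective = best$objective,
      n_iter = best$n_iter, converged = best$converged, seed = as.integer(seed)
    ),
    class = "synergy_model_2d"
  )
}

#' @export
print.synergy_model_2d <- function(x, ...) {
  cat(sprintf(
    "<synergy_model_2d> R = %d, FIT = %.4f, %d muscles x %d samples\n",
    x$rank, x$fit, nrow(x$W), ncol(x$H)
  ))
  invisible(x)
}
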