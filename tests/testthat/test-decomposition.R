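test_that("CP-ALS recovers a noiseless rank-1 tensor", {
  set.seed(10)
  a <- runif(5) + 0.5
  b <- runif(7) + 0.5
  c3 <- runif(3) + 0.5
  X <- outer(outer(a, b), c3)
  m <- cp_als(X, 1, restarts = 3, seed = 1)
  expect_gte(m$fit, 0.999)
  expect_gte(abs(cor(m$F[, 1], a)), 0.999)
  expect_gte(abs(cor(m$T[, 1], b)), 0.999)
  expect_gte(abs(cor(m$S[, 1], c3)), 0.999)
  expect_true(all(m$F >= 0) && all(m$T >= 0) && all(m$S >= 0))
})

test_that("degenerate and invalid inputs are handled per contract", {
  z <- cp_als(array(0, c(3, 4, 2)), 2, seed = 1)
  expect_equal(z$fit, 1)
  expect_true(all(z$S == 0))
  expect_warning(cp_als(array(runif(24), c(3, 4, 2)), 4, restarts = 1, seed = 1))
  expect_error(cp_als(matrix(1, 2, 2), 1), class = "pianosynergy_argument_error")
})

test_that("FIT matches hand-computed values", {
  X <- array(2, c(1, 1, 1))
  expect_equal(fit_metric(X, X), 1)
  expect_equal(fit_metric(X, array(0, c(1, 1, 1))), 0)
  expect_equal(fit_metric(X, array(1, c(1, 1, 1))), 0.75)
  expect_error(fit_metric(X, array(1, c(1, 2, 1))), class = "pianosynergy_argument_error")
  expect_equal(fit_metric(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), 1)
  expect_error(
    fit_metric(array(0, c(1, 1, 1)), array(1, c(1, 1, 1))),
    class = "pianosynergy_data_error"
  )
})

test_that("reconstruction agrees with the factor-space FIT", {
  fx <- synergy_tensor(3)
  m <- cp_als(fx$tensor, 3, restarts = 2, seed = 2)
  expect_equal(fit_metric(fx$tensor, reconstruct_tensor(m)), m$fit, tolerance = 1e-8)
})

test_that("synthetic ground-truth synergies are recovered", {
  fx <- synergy_tensor(3)
  m <- cp_als(fx$tensor, 3, restarts = 5, seed = 1)
  pairs <- match_components(m, list(S = fx$truth$muscle_weights))
  expect_true(all(pairs$spatial_r >= 0.90))
})

test_that("rank selection follows the FIT rule", {
  # exact rank-1 tensor selects 1 (FIT 1, zero increment)
  set.seed(4)
  X <- outer(outer(runif(4) + 0.5, runif(10) + 0.5), runif(3) + 0.5)
  sel <- select_rank(X, r_max = 3, restarts = 2, seed = 1)
  expect_identical(sel$rank, 1L)
  expect_identical(sel$selected_by, "rule")
  expect_false(sel$warning)

  # pure noise cannot satisfy the rule reliably: flagged result
  set.seed(5)
  N <- array(abs(rnorm(4 * 10 * 3)), c(4, 10, 3))
  expect_warning(
    seln <- select_rank(N, r_max = 3, restarts = 2, seed = 1),
    "argmax"
  )
  expect_true(seln$warning)

  expect_error(select_rank(X, r_max = 1), class = "pianosynergy_argument_error")
})

test_that("mean FIT is non-decreasing in rank on a synthetic tensor", {
  fx <- synergy_tensor(2)
  suppressWarnings(sel <- select_rank(fx$tensor, r_max = 4, restarts = 3, seed = 1))
  expect_true(all(diff(sel$fit_curve$mean_fit) >= -1e-3))
})

test_that("CP-ALS matches a dense multi-start oracle on tiny tensors", {
  # oracle: 200 random restarts of box-constrained quasi-Newton on the
  # full factor parameterization
  set.seed(6)
  d <- c(4, 6, 3)
  rank <- 2
  W1 <- matrix(runif(d[1] * rank), d[1])
  W2 <- matrix(runif(d[2] * rank), d[2])
  W3 <- matrix(runif(d[3] * rank), d[3])
  X <- array(W1 %*% t(pianosynergy:::khatri_rao(W3, W2)), d) +
    array(abs(rnorm(prod(d), 0, 0.05)), d)
  obj <- function(par) {
    F <- matrix(par[1:(d[1] * rank)], d[1])
    T_ <- matrix(par[d[1] * rank + 1:(d[2] * rank)], d[2])
    S <- matrix(par[(d[1] + d[2]) * rank + 1:(d[3] * rank)], d[3])
    sum((array(F %*% t(pianosynergy:::khatri_rao(S, T_)), d) - X)^2)
  }
  npar <- sum(d) * rank
  oracle <- min(vapply(1:200, function(k) {
    set.seed(1000 + k)
    optim(runif(npar), obj,
      method = "L-BFGS-B", lower = 0,
      control = list(maxit = 500)
    )$value
  }, numeric(1)))
  m <- cp_als(X, rank, restarts = 10, seed = 3)
  resid_als <- sqrt((1 - m$fit) * sum(X^2))
  expect_lte(resid_als, sqrt(oracle) * 1.01)
})

test_that("NMF factorizes exactly factorizable matrices", {
  V <- outer(c(1, 2, 0.5), c(3, 1, 2, 4))
  m <- nmf(V, 1, seed = 1)
  expect_gte(m$fit, 0.999)
  m2 <- nmf(diag(2), 2, seed = 1, max_iter = 2000, tol = 1e-12)
  expect_gte(m2$fit, 0.999)
  expect_error(nmf(matrix(c(-1, 1, 1, 1), 2), 1), class = "pianosynergy_data_error")
})

test_that("NMF multiplicative updates never increase the objective", {
  set.seed(7)
  V <- matrix(abs(rnorm(40 * 15)), 40)
  m <- nmf(V, 3, seed = 2, restarts = 1, max_iter = 100)
  expect_true(all(diff(m$objective) <= 1e-8 * m$objective[1]))
  expect_true(all(m$W >= 0) && all(m$H >= 0))
  expect_false(anyNA(m$W) || anyNA(m$H))
})

test_that("synergy models survive a JSON round-trip", {
  fx <- synergy_tensor(3)
  m <- cp_als(fx$tensor, 2, restarts = 1, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_synergy_model(m, path)
  back <- read_synergy_model(path)
  expect_equal(back$S, m$S, tolerance = 1e-12)
  expect_equal(back$fit, m$fit, tolerance = 1e-12)
  expect_s3_class(back, "synergy_model_3d")

  V <- matrix(abs(rnorm(12)), 3)
  m2 <- nmf(V, 2, seed = 1)
  write_synergy_model(m2, path)
  back2 <- read_synergy_model(path)
  expect_equal(back2$W, m2$W, tolerance = 1e-12, ignore_attr = TRUE)
})
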