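test_that("activation waveforms are normalized bursts with distinct peaks", {
  H1 <- make_activation_waveforms(1, 100, fs = 400, seed = 1)
  expect_equal(max(H1), 1)
  expect_true(min(H1) >= 0)

  H3 <- make_activation_waveforms(3, 1200, fs = 400, seed = 2)
  expect_identical(dim(H3), c(3L, 1200L))
  peaks <- apply(H3, 1, which.max)
  expect_length(unique(peaks), 3)

  expect_identical(
    make_activation_waveforms(2, 500, seed = 9),
    make_activation_waveforms(2, 500, seed = 9)
  )
  expect_error(make_activation_waveforms(0, 10), class = "pianosynergy_argument_error")
  expect_error(make_activation_waveforms(2, 0), class = "pianosynergy_argument_error")
})

test_that("synergy EMG propagates the latent structure", {
  # zero envelope with no noise gives a silent recording
  W <- diag(2)
  H0 <- matrix(0, 2, 400)
  rec0 <- generate_synergy_emg(synergy_ground_truth(W, H0, seed = 1), fs = 400)
  expect_true(all(rec0 == 0))

  # a channel loaded only on a silent component stays silent
  H <- rbind(make_activation_waveforms(1, 400, seed = 3), rep(0, 400))
  rec <- generate_synergy_emg(synergy_ground_truth(W, H, seed = 4), fs = 400)
  expect_gt(sd(unclass(rec)[1, ]), 0)
  expect_true(all(unclass(rec)[2, ] == 0))

  # determinism and carrier-band validation
  tr <- default_synergy_truth(seed = 5, samples = 600)
  expect_identical(
    unclass(generate_synergy_emg(tr)),
    unclass(generate_synergy_emg(tr))
  )
  bad <- synergy_ground_truth(W, H, carrier_band = c(20, 250), seed = 1)
  expect_error(generate_synergy_emg(bad, fs = 400),
    class = "pianosynergy_argument_error"
  )
})

test_that("channel power matches the envelope prediction (Monte-Carlo oracle)", {
  truth <- default_synergy_truth(seed = 1, noise_sd = 0)
  env <- truth$muscle_weights %*% truth$activations
  predicted <- rowMeans(env^2) # unit-variance carrier
  powers <- matrix(0, 50, nrow(env))
  for (s in 1:50) {
    tr <- synergy_ground_truth(truth$muscle_weights, truth$activations,
      noise_sd = 0, seed = s
    )
    powers[s, ] <- rowMeans(unclass(generate_synergy_emg(tr))^2)
  }
  observed <- colMeans(powers)
  expect_true(all(abs(observed - predicted) / predicted < 0.2))
})

test_that("the latent envelope matrix has rank exactly R", {
  truth <- default_synergy_truth(seed = 2)
  env <- truth$muscle_weights %*% truth$activations
  sv <- svd(env)$d
  expect_identical(sum(sv > 1e-8 * sv[1]), 3L)
})

test_that("fatigue sessions follow the programmed ramps", {
  win_rms <- function(x, fs) {
    starts <- seq(1, length(x) - fs + 1, by = fs %/% 2)
    vapply(starts, function(s) sqrt(mean(x[s:(s + fs - 1)]^2)), numeric(1))
  }
  ratios <- mf_drop <- logical(20)
  rms_ratio <- numeric(20)
  for (s in 1:20) {
    ses <- generate_fatigue_emg(
      fatigue_program(duration_s = 40, seed = s),
      channels = 1, fs = 400
    )
    x <- unclass(ses$recording)[1, ]
    r <- win_rms(x, 400)
    rms_ratio[s] <- tail(r, 1) / r[1]
    mf_drop[s] <- median_frequency(tail(x, 400), 400) <
      median_frequency(head(x, 400), 400)
  }
  expect_true(all(rms_ratio > 1.3 & rms_ratio < 1.7))
  expect_gte(sum(mf_drop), 19)
})

test_that("constant ramps produce no amplitude trend", {
  flat <- list(RMS = c(1, 1), MF = c(1, 1), PE = c(1, 1), FD = c(1, 1))
  drift <- vapply(1:10, function(s) {
    ses <- generate_fatigue_emg(
      fatigue_program(duration_s = 40, ramp = flat, seed = s),
      channels = 1, fs = 400
    )
    x <- unclass(ses$recording)[1, ]
    starts <- seq(1, length(x) - 399, by = 200)
    r <- vapply(starts, function(i) sqrt(mean(x[i:(i + 399)]^2)), numeric(1))
    abs(coef(lm(r ~ seq_along(r)))[2]) * length(r) / mean(r)
  }, numeric(1))
  expect_true(mean(drift < 0.05) >= 0.9)
})

test_that("programmed fatigue level is monotone and spans [0, 1]", {
  ses <- generate_fatigue_emg(fatigue_program(duration_s = 5, seed = 1),
    channels = 2, fs = 400
  )
  expect_true(all(diff(ses$level$level) >= 0))
  expect_equal(range(ses$level$level), c(0, 1))
  expect_identical(nrow(ses$level), ncol(ses$recording))
  expect_error(
    generate_fatigue_emg(fatigue_program(duration_s = 5), channels = 0),
    class = "pianosynergy_argument_error"
  )
})
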