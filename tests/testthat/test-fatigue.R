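test_that("windowed features match closed forms", {
  # constant signal: RMS is the constant, PE degenerates to 0
  recc <- emg_recording(matrix(3, 1, 400), fs = 400, "m1")
  fwc <- window_features(recc)
  expect_equal(fwc$rms, 3)
  expect_equal(fwc$pe, 0)

  # unit 50 Hz sine: RMS = 1/sqrt(2), MF at the tone (within one PSD bin)
  x <- sin(2 * pi * 50 * (0:399) / 400)
  fw <- window_features(emg_recording(matrix(x, 1), fs = 400, "m1"))
  expect_equal(fw$rms, 1 / sqrt(2), tolerance = 0.01)
  expect_lt(abs(fw$mf - 50), 400 / 256) # one Welch bin

  # ordinal degeneracy and waveform dimension
  expect_equal(permutation_entropy(seq_len(200)), 0)
  expect_equal(higuchi_fd(seq(0, 1, length.out = 400)), 1, tolerance = 0.05)

  rec <- emg_recording(matrix(rnorm(800), 1), fs = 400, "m1")
  expect_error(window_features(rec, window_s = 3), class = "pianosynergy_argument_error")
  expect_error(window_features(rec, window_s = 0.1), class = "pianosynergy_argument_error")
  expect_error(
    window_features(rec, window_s = 0.5, step_s = 1),
    class = "pianosynergy_argument_error"
  )
})

test_that("normalization maps to [0, 1] with fatigue-aligned direction", {
  rec <- emg_recording(matrix(c(rnorm(400, sd = 1), rnorm(400, sd = 2)), 1),
    fs = 400, "m1"
  )
  fw <- window_features(rec, window_s = 1, step_s = 1)
  nf <- normalize_features(fw)
  expect_equal(nf$rf, c(0, 1)) # RMS rises -> rf rises
  expect_true(all(nf$rf >= 0 & nf$rf <= 1 & nf$mf_n >= 0 & nf$mf_n <= 1))

  # MF falling from 80 to 60 Hz must invert to (0, 1)
  t <- (0:399) / 400
  two <- emg_recording(
    matrix(c(sin(2 * pi * 80 * t), sin(2 * pi * 60 * t)), 1), 400, "m1"
  )
  nf2 <- normalize_features(window_features(two, window_s = 1, step_s = 1))
  expect_equal(nf2$mf_n, c(0, 1))

  # degenerate zero-range features normalize to 0 with a warning
  recc <- emg_recording(matrix(3, 1, 800), fs = 400, "m1")
  expect_warning(nfc <- normalize_features(window_features(recc, step_s = 1)))
  expect_true(all(nfc$pf == 0))
})

test_that("single-muscle index is the stated convex combination", {
  fw0 <- toy_normalized_fw(0, 0, 0, 0)
  expect_equal(single_muscle_fmi(fw0)$ifmi, 0)
  fw1 <- toy_normalized_fw(1, 1, 1, 1)
  expect_equal(single_muscle_fmi(fw1)$ifmi, 1)
  fwh <- toy_normalized_fw(0.8, 0.6, 0.4, 0.2)
  expect_equal(single_muscle_fmi(fwh)$ifmi, 0.5)
  expect_warning(w <- fatigue_weights(0.5, 0.5, 0.5, 0.5))
  expect_equal(sum(w), 1)
})

test_that("dominant modes follow the max rule with low-index ties", {
  expect_identical(as.integer(dominant_modes(matrix(c(0.9, 0.1), 2, 1))), 1L)
  expect_identical(as.integer(dominant_modes(matrix(c(0.1, 0.9), 2, 1))), 2L)
  expect_identical(as.integer(dominant_modes(matrix(c(0.5, 0.5), 2, 1))), 1L)
  H <- rbind(c(1, 0, 1, 0), c(0, 2, 0, 2))
  expect_identical(as.integer(dominant_modes(H)), c(1L, 2L, 1L, 2L))
})

test_that("the DMWCM stacks and renormalizes dominant-mode weights", {
  W <- cbind(c(0.3, 0.1), c(0.2, 0.6))
  out <- dmwcm(W, rep(1L, 4))
  expect_equal(unname(out), matrix(c(0.75, 0.25), 2, 4), tolerance = 1e-12)
  alt <- dmwcm(W, c(1L, 2L, 1L, 2L))
  expect_equal(alt[, 2], c(0.25, 0.75))
  expect_equal(colSums(alt), rep(1, 4))
  raw <- dmwcm(W, c(1L, 2L), renormalize = FALSE)
  expect_equal(raw[, 1], c(0.3, 0.1))
  expect_error(dmwcm(W, 3L), class = "pianosynergy_internal_error")
})

test_that("CMFI is the DMWCM-weighted sum of muscle indices", {
  one <- cmfi(matrix(1, 1, 3), matrix(0.5, 1, 3))
  expect_equal(one$cmfi, rep(0.5, 3))
  two <- cmfi(matrix(c(0.75, 0.25), 2, 1), matrix(c(0.4, 0.8), 2, 1))
  expect_equal(two$cmfi, 0.5)
  full <- cmfi(matrix(c(0.6, 0.4), 2, 2), matrix(1, 2, 2))
  expect_equal(full$cmfi, c(1, 1))
  expect_error(
    cmfi(matrix(1, 1, 3), matrix(0.5, 1, 4)),
    class = "pianosynergy_argument_error"
  )
})

test_that("relabeling muscles permutes the DMWCM and leaves CMFI unchanged", {
  set.seed(21)
  W <- matrix(runif(8), 4, 2)
  modes <- sample(1:2, 6, replace = TRUE)
  ifmi <- matrix(runif(24), 4, 6)
  perm <- c(3, 1, 4, 2)
  base <- dmwcm(W, modes)
  permuted <- dmwcm(W[perm, ], modes)
  expect_equal(permuted, base[perm, ], tolerance = 1e-12)
  expect_equal(
    cmfi(permuted, ifmi[perm, ])$cmfi,
    cmfi(base, ifmi)$cmfi,
    tolerance = 1e-12
  )
})

test_that("rest prompting applies threshold hysteresis", {
  s <- cmfi(matrix(1, 1, 4), matrix(c(0.2, 0.8, 0.9, 0.5), 1))
  m <- monitor_fatigue(s, threshold = 0.7, resume_below = 0.7)
  expect_identical(m$rest_flag, c(FALSE, TRUE, TRUE, FALSE))

  # hysteresis: once on, stays on until dropping below resume level
  s2 <- cmfi(matrix(1, 1, 5), matrix(c(0.2, 0.8, 0.65, 0.55, 0.65), 1))
  m2 <- monitor_fatigue(s2, threshold = 0.7, resume_below = 0.6)
  expect_identical(m2$rest_flag, c(FALSE, TRUE, TRUE, FALSE, FALSE))

  low <- cmfi(matrix(1, 1, 3), matrix(c(0.1, 0.2, 0.3), 1))
  expect_false(any(monitor_fatigue(low)$rest_flag))
  expect_error(monitor_fatigue(low, threshold = 0), class = "pianosynergy_argument_error")
  expect_error(
    monitor_fatigue(low, threshold = 0.5, resume_below = 0.6),
    class = "pianosynergy_argument_error"
  )
})

test_that("weight calibration recovers generating weights", {
  ses <- generate_fatigue_emg(fatigue_program(duration_s = 20, seed = 31),
    channels = 2, fs = 400
  )
  fw <- normalize_features(window_features(ses$recording))
  means <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(fw), window),
    rf = mean(rf), mf_n = mean(mf_n), pf = mean(pf), ff = mean(ff),
    .groups = "drop"
  )
  w_rf <- calibrate_weights(fw, means$rf)
  expect_equal(as.numeric(w_rf), c(1, 0, 0, 0), tolerance = 1e-6)

  gt_mean <- rowMeans(as.matrix(means[, c("rf", "mf_n", "pf", "ff")]))
  w_eq <- calibrate_weights(fw, gt_mean)
  expect_equal(as.numeric(w_eq), rep(0.25, 4), tolerance = 1e-6)

  set.seed(32)
  expect_warning(calibrate_weights(fw, runif(attr(fw, "n_windows"))))
})

test_that("CMFI tracks programmed fatigue and features trend correctly", {
  rho <- rms_up <- mf_down <- numeric(10)
  for (s in 1:10) {
    ses <- generate_fatigue_emg(fatigue_program(duration_s = 60, seed = s),
      channels = 4, fs = 400
    )
    series <- suppressWarnings(cmfi_pipeline(ses$recording, seed = s))
    lvl <- approx(ses$level$time_s, ses$level$level, xout = series$time_s)$y
    rho[s] <- cor(series$cmfi, lvl, method = "spearman")
    fw <- tibble::as_tibble(attr(series, "features"))
    trend <- dplyr::summarise(
      dplyr::group_by(fw, window),
      rms = mean(rms), mf = mean(mf), .groups = "drop"
    )
    rms_up[s] <- coef(lm(rms ~ window, trend))[2] > 0
    mf_down[s] <- coef(lm(mf ~ window, trend))[2] < 0
  }
  expect_true(all(rho >= 0.8))
  expect_gte(sum(rms_up), 9)
  expect_gte(sum(mf_down), 9)
  expect_true(all(is.finite(rho)))
})

test_that("CMFI stays within [0, 1] under normalized inputs", {
  ses <- generate_fatigue_emg(fatigue_program(duration_s = 20, seed = 41),
    channels = 3, fs = 400
  )
  series <- suppressWarnings(cmfi_pipeline(ses$recording, seed = 41))
  expect_true(all(series$cmfi >= 0 & series$cmfi <= 1))
  expect_s3_class(attr(series, "nmf_model"), "synergy_model_2d")
})
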