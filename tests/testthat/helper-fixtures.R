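# Shared fixtures. Everything is generated in code; heavier objects are
# cached per session so several test files can reuse them.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, fixture_cache)) {
    assign(key, force(expr), fixture_cache)
  }
  get(key, fixture_cache)
}

# Standard low-noise 3-synergy tensor (the validation study conditions):
# 4 channels x 1200 samples at 400 Hz, 30 wavelet scales.
synergy_tensor <- function(seed) {
  cached(paste0("tensor_", seed), {
    truth <- default_synergy_truth(seed = seed)
    rec <- generate_synergy_emg(truth)
    list(
      truth = truth,
      tensor = build_emg_tensor(rec, wavelet_config())
    )
  })
}

# Hand-built 3-D synergy model (for assessment tests).
toy_model_3d <- function(F, T, S, channel_names = NULL) {
  structure(
    list(
      F = F, T = T, S = S, rank = ncol(S), fit = 1, fits = 1,
      n_iter = 0L, converged = TRUE, seed = 0L,
      freqs_hz = NULL, channel_names = channel_names
    ),
    class = "synergy_model_3d"
  )
}

# Minimal normalized feature-windows object with prescribed values.
toy_normalized_fw <- function(rf, mf_n, pf, ff, channel = "m1") {
  n <- length(rf)
  fw <- tibble::tibble(
    window = seq_len(n), time_s = seq_len(n) - 0.5, channel = channel,
    rms = rf, mf = mf_n, pe = pf, fd = ff,
    rf = rf, mf_n = mf_n, pf = pf, ff = ff
  )
  structure(fw,
    class = c("feature_windows", class(fw)),
    fs = 400, window_s = 1, step_s = 1, n_windows = n,
    starts = seq(1, by = 400, length.out = n), window_len = 400L,
    normalized = TRUE
  )
}

# Single-joint test rig: spring-loaded joint with actuator inertia and
# viscous damping, optionally PD-driven. Linear in theta, so trajectories
# are smooth and closed-form intuition applies.
one_joint_rig <- function(Ks = 0.02, Kp = 0, Kd = 0, Ce = 0.01,
                          Me = 1e-4, theta_d = 0, theta0 = 0.3,
                          theta_dot0 = 0) {
  list(
    chain = finger_chain(0.05, theta = theta0, theta_dot = theta_dot0),
    exo = exo_model(
      Kp = diag(Kp, 1), Kd = diag(Kd, 1), Ks = diag(Ks, 1),
      Me = diag(Me, 1), Ce = diag(Ce, 1),
      theta_eq = 0, theta_d = theta_d
    )
  )
}
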