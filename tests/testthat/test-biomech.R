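test_that("key force follows the spring-damper law", {
  key <- key_model(ks = 100, bs = 1)
  expect_equal(key_force(0, 0, key), 0)
  expect_equal(key_force(0.01, 0.05, key), 1.05)
  expect_equal(key_force(0.02, 0.1, key), 2 * key_force(0.01, 0.05, key))
  expect_error(key_model(ks = -1), class = "pianosynergy_argument_error")
})

test_that("fingertip Jacobian matches closed forms and finite differences", {
  one <- finger_chain(lengths = 0.07)
  expect_equal(fingertip_jacobian(one, theta = 0), matrix(c(0, 0.07), 2, 1))

  # random configurations against a finite-difference oracle
  set.seed(51)
  chain <- finger_chain(c(0.045, 0.025, 0.018))
  for (k in 1:5) {
    th <- runif(3, -0.5, 1.2)
    J <- fingertip_jacobian(chain, th)
    h <- 1e-7
    J_fd <- sapply(1:3, function(j) {
      e <- rep(0, 3)
      e[j] <- h
      (fingertip_position(chain, th + e) - fingertip_position(chain, th - e)) / (2 * h)
    })
    expect_lt(max(abs(J - J_fd)), 1e-6)
  }
  expect_equal(as.numeric(t(J) %*% c(0, 0)), rep(0, 3))
})

test_that("Hill torque respects its curve normalizations", {
  m <- muscle_model(Fmax = 50, lmt = function(th) 0.25 - 0.01 * th, l0 = 0.25)
  expect_equal(hill_torque(m, 1, 0, alpha = 0, theta = 0.2), 0)
  # at the operating point torque is Fmax * moment arm
  expect_equal(hill_torque(m, 1, 0, alpha = 1, theta = 0.2), 50 * -0.01,
    tolerance = 1e-9
  )
  # force-length is unimodal about 1
  expect_lt(
    abs(hill_torque(m, 1.6, 0, 1, 0.2)), abs(hill_torque(m, 1, 0, 1, 0.2))
  )
  expect_lt(
    abs(hill_torque(m, 0.5, 0, 1, 0.2)), abs(hill_torque(m, 1, 0, 1, 0.2))
  )
  expect_warning(hill_torque(m, 1, 0, alpha = 1.2, theta = 0))
  # force-velocity: 1 at rest, weaker when shortening, stronger eccentric
  fv <- pianosynergy:::force_velocity
  shape <- list(af = 0.25, flen = 1.4)
  expect_equal(fv(0, shape), 1)
  expect_lt(fv(0.3, shape), 1)
  expect_gt(fv(-0.3, shape), 1)
})

test_that("moment arm differentiates the musculotendon length", {
  expect_equal(moment_arm(function(th) 0.2 + 0.015 * th, 0.4), 0.015, tolerance = 1e-9)
  expect_equal(moment_arm(function(th) 0.2 + 0.01 * sin(th), 0), 0.01, tolerance = 1e-6)
  full <- moment_arm(function(th) 0.2 + 0.01 * sin(th), 0.3, h = 1e-4)
  half <- moment_arm(function(th) 0.2 + 0.01 * sin(th), 0.3, h = 5e-5)
  expect_lt(abs(full - half), 1e-8)
  expect_error(moment_arm(function(th) NaN, 0), class = "pianosynergy_data_error")
})

test_that("torque and assistive force follow the lever relations", {
  out <- joint_torque_and_assist(10, 0.02, 0.02)
  expect_equal(out$tau, 0.2)
  expect_equal(out$Fa, 10)
  zero <- joint_torque_and_assist(0, 0.02, 0.02)
  expect_equal(zero$tau, 0)
  expect_equal(zero$Fa, 0)
  expect_equal(joint_torque_and_assist(10, 0.02, 0.01)$Fa, 2 * out$Fa)
  expect_error(joint_torque_and_assist(1, 0.01, 0), class = "pianosynergy_argument_error")
})

test_that("PD torque is a restoring action toward the desired trajectory", {
  exo <- exo_model(Kp = diag(2, 1), Kd = diag(0.5, 1), theta_d = 0.5, n = 1)
  expect_equal(exo_torque(exo, 0.5, 0), 0)
  expect_equal(exo_torque(exo, 0.4, -0.1), 2 * 0.1 + 0.5 * 0.1)
  expect_lt(exo_torque(exo, 0.6, 0), 0)
  expect_gt(exo_torque(exo, 0.4, 0), 0)
  expect_error(exo_torque(exo, c(1, 2), c(0, 0)), class = "pianosynergy_argument_error")
  expect_error(exo_model(Kp = matrix(c(1, 2, 0, 1), 2), Kd = diag(2)),
    class = "pianosynergy_argument_error"
  )
})

test_that("the PD-driven system settles on the desired posture", {
  chain <- finger_chain(c(0.045, 0.025, 0.018), theta = c(0.3, 0.3, 0.2))
  exo <- exo_model(
    Kp = diag(0.8, 3), Kd = diag(0.05, 3), Ks = diag(0, 3),
    Me = diag(c(2e-4, 1e-4, 5e-5)), Ce = diag(0.02, 3),
    theta_eq = c(0, 0, 0), theta_d = c(0.4, 0.3, 0.2)
  )
  tr <- simulate_hand(chain, exo = exo, duration = 3, dt = 1e-3)
  last <- as.numeric(tail(tr, 1)[paste0("theta_", c("MCP", "PIP", "DIP"))])
  expect_lt(max(abs(last - c(0.4, 0.3, 0.2))), 1e-3)
})

test_that("an unforced chain stays put", {
  chain <- finger_chain(c(0.04, 0.03), theta = c(0.2, 0.1), joint_names = c("a", "b"))
  tr <- simulate_hand(chain, duration = 0.5, dt = 1e-3)
  expect_lt(max(abs(tr$theta_a - 0.2)), 1e-10)
  expect_lt(max(abs(tr$theta_b - 0.1)), 1e-10)
})

test_that("a statically held key press reflects the spring force through J'", {
  # 1-link finger resting on the key plane: tip starts at y = 0 with the
  # contact surface at 0.005 m, i.e. 5 mm of compression
  key <- key_model(ks = 150, bs = 0)
  chain1 <- finger_chain(0.1, theta = 0)
  J <- fingertip_jacobian(chain1)
  expect_equal(key_force(0.005, 0, key), 0.75)
  expect_equal(as.numeric(t(J) %*% c(0, 0.75)), 0.075)

  # the simulator reaches the matching torque balance: at rest
  # Ks * theta = -J(theta)' (0, F_key)
  exo <- exo_model(
    Kp = diag(0, 1), Kd = diag(0, 1), Ks = diag(300, 1),
    Me = diag(1e-3, 1), Ce = diag(0.3, 1), theta_eq = 0
  )
  tr <- simulate_hand(chain1,
    key = key, exo = exo, duration = 0.6, dt = 1e-3,
    contact_height = 0.005
  )
  F_end <- tail(tr$F_key, 1)
  th_end <- tail(tr$theta_MCP, 1)
  tau_spring <- 300 * th_end
  tau_key <- as.numeric(t(fingertip_jacobian(chain1, th_end)) %*% c(0, F_end))
  expect_equal(F_end, 0.75, tolerance = 0.01)
  expect_equal(tau_spring, -tau_key, tolerance = 0.01 * abs(tau_key))
})

test_that("assistive-force paths agree in static equilibrium", {
  # muscle pulling against the exoskeleton spring: at rest the muscle
  # torque equals the spring torque, and Fa = tau / d on both paths
  m <- muscle_model(
    Fmax = 40, lmt = function(th) 0.25 - 0.01 * th, l0 = 0.25,
    vmax = 0.5, alpha = 1
  )
  chain1 <- finger_chain(0.05, theta = 0)
  exo <- exo_model(
    Kp = diag(0, 1), Kd = diag(0, 1), Ks = diag(2, 1),
    Me = diag(1e-3, 1), Ce = diag(0.2, 1), theta_eq = 0
  )
  tr <- simulate_hand(chain1,
    exo = exo, muscles = list(m), duration = 1.5,
    dt = 1e-3, d_joint = 0.02
  )
  th <- tail(tr$theta_MCP, 1)
  tau_m <- tail(tr$tau_m_MCP, 1)
  expect_equal(2 * th, tau_m, tolerance = 0.01 * abs(tau_m)) # torque balance
  # explicit Hill chain reproduces the simulator's muscle torque and Fa
  r <- moment_arm(m$lmt, th)
  Ft <- m$Fmax * pianosynergy:::force_length(m$lmt(th) / m$l0, m$fl_width) *
    pianosynergy:::force_velocity(0, m$fv_shape) * 1
  path <- joint_torque_and_assist(Ft, r, 0.02)
  expect_equal(path$tau, tau_m, tolerance = 1e-6)
  expect_equal(path$Fa, tail(tr$Fa_MCP, 1), tolerance = 1e-6)
})

test_that("passive mechanical energy never increases", {
  chain <- finger_chain(c(0.045, 0.025, 0.018),
    theta = c(0.4, 0.3, 0.2), theta_dot = c(2, -1, 1)
  )
  exo <- exo_model(
    Kp = diag(0, 3), Kd = diag(0, 3), Ks = diag(0.05, 3),
    Me = diag(c(2e-4, 1e-4, 5e-5)), Ce = diag(0.01, 3), theta_eq = c(0, 0, 0)
  )
  tr <- simulate_hand(chain, exo = exo, duration = 1, dt = 5e-4)
  E <- trace_energy(tr, chain, exo = exo)
  expect_true(all(diff(E) <= 1e-8 * E[1]))
})

test_that("halving the step shrinks the end-state error at 4th order", {
  rig <- one_joint_rig(Ks = 0.05, Kp = 0.03, Ce = 0.002, Me = 1e-4, theta_d = 0.1)
  end_state <- function(dt) {
    tr <- simulate_hand(rig$chain, exo = rig$exo, duration = 0.2, dt = dt)
    as.numeric(tail(tr, 1)[c("theta_MCP", "theta_dot_MCP")])
  }
  ref <- end_state(2.5e-5)
  err1 <- sqrt(sum((end_state(1e-3) - ref)^2))
  err2 <- sqrt(sum((end_state(5e-4) - ref)^2))
  expect_gte(err1 / err2, 12)
})

test_that("divergence and bad steps are reported", {
  chain <- finger_chain(0.05, theta = 0.1)
  expect_error(simulate_hand(chain, dt = 0.01), class = "pianosynergy_argument_error")
})

test_that("hand-system configs load from YAML and simulate", {
  path <- system.file("extdata", "hand.yaml", package = "pianosynergy")
  sys <- read_hand_config(path)
  expect_identical(length(sys$chain$lengths), 3L)
  expect_s3_class(sys$key, "key_model")
  expect_s3_class(sys$exo, "exo_model")
  tr <- simulate_hand(sys$chain,
    key = sys$key, exo = sys$exo, muscles = sys$muscles,
    duration = 0.3, dt = 1e-3, contact_height = sys$contact_height,
    d_joint = sys$d_joint
  )
  expect_true(all(is.finite(as.matrix(tr))))
  def <- default_hand_system()
  expect_equal(def$chain$lengths, sys$chain$lengths)
})
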