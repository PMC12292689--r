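#' Piano-key spring-damper model
#'
#' The key is modeled as a linear spring-damper: the feedback force on the
#' fingertip is `F = ks * xk + bs * vk` with `xk` the key compression and
#' `vk` its velocity.
#'
#' @param ks stiffness in N/m (> 0).
#' @param bs damping in N s/m (>= 0).
#' @param travel full key travel in m (informational; default 0.01).
#' @return Object of class `key_model`.
#' @export
key_model <- function(ks, bs = 0, travel = 0.01) {
  if (!is_number(ks) || ks <= 0) abort_argument("`ks` must be > 0")
  if (!is_number(bs) || bs < 0) abort_argument("`bs` must be >= 0")
  structure(list(ks = ks, bs = bs, travel = travel), class = "key_model")
}

#' Key feedback force
#'
#' @param xk key compression in m.
#' @param vk compression velocity in m/s.
#' @param key a [key_model()].
#' @return Force in N (`ks * xk + bs * vk`).
#' @examples
#' key_force(0.01, 0.05, key_model(ks = 100, bs = 1)) # 1.05 N
#' @export
key_force <- function(xk, vk, key) {
  stopifnot(inherits(key, "key_model"))
  key$ks * xk + key$bs * vk
}

#' Planar finger linkage
#'
#' A finger as a planar chain of rigid phalanges moving in the sagittal
#' (flexion-extension) plane. The anatomical models use three links
#' (MCP-PIP-DIP driving PP, MP, DP) for the index, middle, ring and little
#' finger and two (MC, IP) for the thumb, but any chain length >= 1 is
#' accepted for analysis.
#'
#' @param lengths link lengths in m (> 0), proximal to distal.
#' @param masses link masses in kg (> 0), same length; defaults approximate
#'   phalanges as uniform cylinders of 8 mm radius and soft-tissue density.
#' @param joint_names labels; defaults MCP/PIP/DIP style.
#' @param theta joint angles in rad (default 0).
#' @param theta_dot joint angular velocities in rad/s (default 0).
#' @return Object of class `finger_chain`.
#' @export
finger_chain <- function(lengths, masses = NULL, joint_names = NULL,
                         theta = NULL, theta_dot = NULL) {
  if (!length(lengths) || any(lengths <= 0)) {
    abort_argument("`lengths` must be positive")
  }
  n <- length(lengths)
  if (is.null(masses)) masses <- 1100 * pi * 0.008^2 * lengths
  if (length(masses) != n || any(masses <= 0)) {
    abort_argument("`masses` must be positive, one per link")
  }
  joint_names <- joint_names %||%
    (if (n == 2) c("MC", "IP") else c("MCP", "PIP", "DIP")[seq_len(min(n, 3))])
  if (length(joint_names) < n) joint_names <- sprintf("J%d", seq_len(n))
  theta <- theta %||% rep(0, n)
  theta_dot <- theta_dot %||% rep(0, n)
  if (length(theta) != n || length(theta_dot) != n) {
    abort_argument("`theta` and `theta_dot` must have one entry per joint")
  }
  structure(
    list(
      lengths = as.numeric(lengths), masses = as.numeric(masses),
      joint_names = joint_names[seq_len(n)],
      theta = as.numeric(theta), theta_dot = as.numeric(theta_dot)
    ),
    class = "finger_chain"
  )
}

#' Fingertip position of a planar chain
#'
#' @param chain a [finger_chain()].
#' @param theta joint angles (defaults to the chain state).
#' @return Length-2 numeric (x, y) in m.
#' @export
fingertip_position <- function(chain, theta = chain$theta) {
  cum <- cumsum(theta)
  c(sum(chain$lengths * cos(cum)), sum(chain$lengths * sin(cum)))
}

#' Fingertip Jacobian
#'
#' Planar position Jacobian of the fingertip: maps joint velocities to tip
#' velocity; its transpose maps a tip force to joint torques, converting the
#' key feedback force into joint feedback torques.
#'
#' @param chain a [finger_chain()].
#' @param theta joint angles (defaults to the chain state).
#' @return 2 x n matrix (rows x, y).
#' @examples
#' fingertip_jacobian(finger_chain(lengths = 0.05)) # [[0], [0.05]]
#' @export
fingertip_jacobian <- function(chain, theta = chain$theta) {
  n <- length(chain$lengths)
  cum <- cumsum(theta)
  J <- matrix(0, 2, n)
  for (k in seq_len(n)) {
    idx <- k:n
    J[1, k] <- -sum(chain$lengths[idx] * sin(cum[idx]))
    J[2, k] <- sum(chain$lengths[idx] * cos(cum[idx]))
  }
  J
}

# COM Jacobians, inertia matrix from the uniform-rod link approximation:
# M(theta) = sum_l m_l Jv_l' Jv_l + I_l Jw_l' Jw_l.
chain_inertia <- function(chain, theta) {
  n <- length(chain$lengths)
  L <- chain$lengths
  m <- chain$masses
  cum <- cumsum(theta)
  M <- matrix(0, n, n)
  for (l in seq_len(n)) {
    Jv <- matrix(0, 2, n)
    for (k in seq_len(l)) {
      idx <- if (k <= l - 1) k:(l - 1) else integer(0)
      sx <- -sum(L[idx] * sin(cum[idx])) - (L[l] / 2) * sin(cum[l])
      sy <- sum(L[idx] * cos(cum[idx])) + (L[l] / 2) * cos(cum[l])
      Jv[1, k] <- sx
      Jv[2, k] <- sy
    }
    Il <- m[l] * L[l]^2 / 12
    Jw <- matrix(0, 1, n)
    Jw[1, seq_len(l)] <- 1
    M <- M + m[l] * crossprod(Jv) + Il * crossprod(Jw)
  }
  M
}

# Coriolis/centrifugal vector C(theta, theta_dot) %*% theta_dot via
# Christoffel symbols with central-difference dM/dtheta.
chain_coriolis <- function(chain, theta, theta_dot, h = 1e-6) {
  n <- length(theta)
  dM <- array(0, c(n, n, n))
  for (i in seq_len(n)) {
    tp <- theta
    tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    dM[, , i] <- (chain_inertia(chain, tp) - chain_inertia(chain, tm)) / (2 * h)
  }
  cvec <- numeric(n)
  for (k in seq_len(n)) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        gamma <- 0.5 * (dM[k, j, i] + dM[k, i, j] - dM[i, j, k])
        acc <- acc + gamma * theta_dot[i] * theta_dot[j]
      }
    }
    cvec[k] <- acc
  }
  cvec
}

#' Exoskeleton model
#'
#' Passive exoskeleton dynamics (extra inertia `Me`, viscous damping `Ce`,
#' structural stiffness `Ks` about the gravity-compensated equilibrium
#' `theta_eq`) plus the active PD assistance drive
#' `tau_e = Kp (theta_d - theta) + Kd (theta_d_dot - theta_dot)` toward a
#' desired trajectory.
#'
#' @param Kp,Kd proportional/derivative gain matrices (symmetric positive
#'   semidefinite; scalars are expanded to diagonal matrices).
#' @param Ks structural stiffness matrix (default 0).
#' @param Me added inertia matrix (default 0).
#' @param Ce damping matrix (default 0).
#' @param theta_eq equilibrium angles in rad (default 0).
#' @param theta_d desired trajectory: constant vector or function of time
#'   returning a vector.
#' @param theta_d_dot desired velocity: constant vector or function of time;
#'   default zero.
#' @param n number of joints (inferred from `theta_eq` or gain matrices when
#'   omitted).
#' @return Object of class `exo_model`.
#' @export
exo_model <- function(Kp, Kd, Ks = 0, Me = 0, Ce = 0,
                      theta_eq = NULL, theta_d = NULL, theta_d_dot = NULL,
                      n = NULL) {
  dim_of <- function(x) if (is.matrix(x)) nrow(x) else NA_integer_
  n <- n %||% {
    cand <- c(
      dim_of(Kp), dim_of(Kd), dim_of(Ks), dim_of(Me), dim_of(Ce),
      length(theta_eq) %||% NA_integer_
    )
    cand <- cand[!is.na(cand) & cand > 0]
    if (!length(cand)) abort_argument("cannot infer joint count; supply `n`")
    cand[1]
  }
  as_mat <- function(x, nm) {
    if (!is.matrix(x)) x <- diag(rep(x, length.out = n), n)
    if (!all(dim(x) == n)) abort_argument(sprintf("`%s` must be %d x %d", nm, n, n))
    if (max(abs(x - t(x))) > 1e-9) abort_argument(sprintf("`%s` must be symmetric", nm))
    if (min(eigen(x, symmetric = TRUE, only.values = TRUE)$values) < -1e-9) {
      abort_argument(sprintf("`%s` must be positive semidefinite", nm))
    }
    x
  }
  theta_eq <- theta_eq %||% rep(0, n)
  structure(
    list(
      Kp = as_mat(Kp, "Kp"), Kd = as_mat(Kd, "Kd"), Ks = as_mat(Ks, "Ks"),
      Me = as_mat(Me, "Me"), Ce = as_mat(Ce, "Ce"),
      theta_eq = as.numeric(theta_eq),
      theta_d = theta_d %||% theta_eq, theta_d_dot = theta_d_dot,
      n = as.integer(n)
    ),
    class = "exo_model"
  )
}

eval_traj <- function(f, t, n) {
  if (is.null(f)) return(rep(0, n))
  v <- if (is.function(f)) f(t) else f
  rep(as.numeric(v), length.out = n)
}

#' Exoskeleton PD assistance torque
#'
#' @param exo an [exo_model()].
#' @param theta,theta_dot current joint angles and velocities.
#' @param t time in s (used when the desired trajectory is a function).
#' @return Torque vector in N m.
#' @export
exo_torque <- function(exo, theta, theta_dot, t = 0) {
  stopifnot(inherits(exo, "exo_model"))
  if (length(theta) != exo$n || length(theta_dot) != exo$n) {
    abort_argument("state dimension does not match the exoskeleton model")
  }
  td <- eval_traj(exo$theta_d, t, exo$n)
  tdd <- eval_traj(exo$theta_d_dot, t, exo$n)
  as.numeric(exo$Kp %*% (td - theta) + exo$Kd %*% (tdd - theta_dot))
}

#' Hill-type muscle model
#'
#' Phenomenological muscle producing joint torque
#' `tau = Fmax * f_l(l_norm) * f_v(v_norm) * alpha * r_m(theta)` with a
#' Gaussian force-length curve `f_l(l) = exp(-((l - 1)/fl_width)^2)` and a
#' Hill hyperbolic force-velocity curve (concentric branch
#' `(1 - v)/(1 + v/af)` for normalized shortening velocity `v` in [0, 1),
#' eccentric branch saturating at `flen`); both curves equal 1 at their
#' operating point (`l = 1`, `v = 0`).
#'
#' @param Fmax maximum isometric force in N (> 0).
#' @param lmt musculotendon length as a function of joint angle (rad -> m).
#' @param l0 optimal musculotendon length in m (normalizes `lmt`).
#' @param vmax maximum shortening velocity in m/s (normalizes excursion
#'   rate).
#' @param fl_width Gaussian width of the force-length curve (default 0.45).
#' @param fv_shape list with `af` (curvature, default 0.25) and `flen`
#'   (eccentric plateau, default 1.4).
#' @param alpha activation in [0, 1]: constant or function of time.
#' @return Object of class `muscle_model`.
#' @export
muscle_model <- function(Fmax, lmt, l0 = lmt(0), vmax = 10 * l0,
                         fl_width = 0.45, fv_shape = list(af = 0.25, flen = 1.4),
                         alpha = 0) {
  if (!is_number(Fmax) || Fmax <= 0) abort_argument("`Fmax` must be > 0")
  if (!is.function(lmt)) abort_argument("`lmt` must be a function of joint angle")
  structure(
    list(
      Fmax = Fmax, lmt = lmt, l0 = l0, vmax = vmax,
      fl_width = fl_width, fv_shape = fv_shape, alpha = alpha
    ),
    class = "muscle_model"
  )
}

force_length <- function(l_norm, width) exp(-((l_norm - 1) / width)^2)

force_velocity <- function(v_norm, shape) {
  af <- shape$af %||% 0.25
  flen <- shape$flen %||% 1.4
  ifelse(v_norm >= 0,
    pmax(0, (1 - v_norm) / (1 + v_norm / af)),
    flen - (flen - 1) * exp(v_norm / af)
  )
}

clamp_alpha <- function(alpha) {
  if (any(alpha < 0 | alpha > 1)) {
    warn("activation outside [0, 1]; clamping")
    alpha <- pmin(pmax(alpha, 0), 1)
  }
  alpha
}

#' Moment arm by virtual work
#'
#' The moment arm equals the derivative of musculotendon length with respect
#' to joint angle (virtual-work principle), evaluated by central finite
#' difference.
#'
#' @param lmt musculotendon length function (rad -> m).
#' @param theta joint angle in rad.
#' @param h finite-difference step (default 1e-5 rad).
#' @return Moment arm in m.
#' @examples
#' moment_arm(function(th) 0.25 - 0.011 * th, 0.3) # -0.011
#' @export
moment_arm <- function(lmt, theta, h = 1e-5) {
  lp <- lmt(theta + h)
  lm <- lmt(theta - h)
  if (!is.finite(lp) || !is.finite(lm)) {
    abort_data("musculotendon length is not finite near `theta`")
  }
  (lp - lm) / (2 * h)
}

#' Hill muscle joint torque
#'
#' @param m a [muscle_model()].
#' @param l_norm normalized fiber length (1 at optimum).
#' @param v_norm normalized contraction velocity (0 isometric, positive
#'   shortening).
#' @param alpha activation in [0, 1] (clamped with a warning otherwise).
#' @param theta joint angle in rad (for the moment arm).
#' @return Joint torque in N m:
#'   `Fmax * f_l(l_norm) * f_v(v_norm) * alpha * r_m(theta)`.
#' @export
hill_torque <- function(m, l_norm, v_norm, alpha, theta) {
  stopifnot(inherits(m, "muscle_model"))
  alpha <- clamp_alpha(alpha)
  m$Fmax * force_length(l_norm, m$fl_width) *
    force_velocity(v_norm, m$fv_shape) * alpha * moment_arm(m$lmt, theta)
}

#' Joint torque and per-segment assistive force
#'
#' Converts a tendon force to joint torque via the moment arm
#' (`tau = Ft * r_m`) and to the assistive force a rehabilitation robot must
#' apply at its attachment point (`Fa = tau / d_joint`, with `d_joint` the
#' distance from the force application point to the joint's instantaneous
#' center of rotation).
#'
#' @param Ft tendon force in N.
#' @param r_m moment arm in m.
#' @param d_joint application-point distance in m (> 0).
#' @return List with `tau` (N m) and `Fa` (N).
#' @examples
#' joint_torque_and_assist(10, 0.02, 0.02) # tau 0.2, Fa 10
#' @export
joint_torque_and_assist <- function(Ft, r_m, d_joint) {
  if (any(!is.finite(d_joint)) || any(d_joint <= 0)) {
    abort_argument("`d_joint` must be > 0")
  }
  tau <- Ft * r_m
  list(tau = tau, Fa = tau / d_joint)
}

# Key contact state at a configuration: compression, compression velocity,
# force and the joint feedback torque J' (0, F).
key_contact <- function(chain, key, theta, theta_dot, contact_height) {
  tip <- fingertip_position(chain, theta)
  J <- fingertip_jacobian(chain, theta)
  xk <- contact_height - tip[2]
  if (xk <= 0) {
    return(list(xk = 0, vk = 0, F = 0, tau_k = rep(0, length(theta)), J = J))
  }
  vk <- -as.numeric(J[2, ] %*% theta_dot)
  F <- key_force(xk, vk, key)
  list(xk = xk, vk = vk, F = F, tau_k = as.numeric(t(J) %*% c(0, F)), J = J)
}

muscle_joint_torques <- function(muscles, theta, theta_dot, t) {
  n <- length(theta)
  tau <- numeric(n)
  for (j in seq_len(n)) {
    m <- muscles[[j]]
    if (is.null(m)) next
    r <- moment_arm(m$lmt, theta[j])
    l_norm <- m$lmt(theta[j]) / m$l0
    v_norm <- -r * theta_dot[j] / m$vmax
    a <- if (is.function(m$alpha)) m$alpha(t) else m$alpha
    a <- min(max(a, 0), 1)
    tau[j] <- m$Fmax * force_length(l_norm, m$fl_width) *
      force_velocity(v_norm, m$fv_shape) * a * r
  }
  tau
}

#' Forward simulation of the key-finger-exoskeleton system
#'
#' Integrates the coupled dynamics
#' `[Mf + Me] theta'' + [Cf + Ce] theta' + Ks (theta - theta_eq) =
#' tau_m + tau_e - Jk' F_key` with fixed-step 4th-order Runge-Kutta. The
#' finger inertia and Coriolis terms come from the planar uniform-rod link
#' model; the key force engages only while the fingertip lies below the
#' contact height, with compression equal to the penetration depth. With
#' zero activation and no assistance the system is purely dissipative.
#'
#' @param chain a [finger_chain()] (initial state from its `theta`,
#'   `theta_dot`).
#' @param key a [key_model()] or `NULL` for no key.
#' @param exo an [exo_model()] or `NULL` for no exoskeleton.
#' @param muscles list of [muscle_model()] (or `NULL`) per joint.
#' @param duration simulated time in s.
#' @param dt integrator step in s (<= 2e-3).
#' @param contact_height key contact height of the fingertip in m
#'   (default `-Inf`: never in contact).
#' @param d_joint distances from the robot attachment points to the joint
#'   centers in m (for the assistive forces; default half the link lengths).
#' @return Object of class `sim_trace`: tibble with `t`, per-joint `theta_*`,
#'   `theta_dot_*`, `tau_m_*`, `tau_e_*`, `Fa_*`, and `F_key`.
#' @export
simulate_hand <- function(chain, key = NULL, exo = NULL, muscles = NULL,
                          duration = 1, dt = 1e-3, contact_height = -Inf,
                          d_joint = NULL) {
  stopifnot(inherits(chain, "finger_chain"))
  if (!is_number(dt) || dt <= 0 || dt > 2e-3) {
    abort_argument("`dt` must be positive and at most 2 ms")
  }
  n <- length(chain$lengths)
  muscles <- muscles %||% vector("list", n)
  d_joint <- d_joint %||% (chain$lengths / 2)
  if (any(d_joint <= 0)) abort_argument("`d_joint` must be > 0")
  if (!is.null(exo) && exo$n != n) {
    abort_argument("exoskeleton dimension does not match the chain")
  }
  zero <- matrix(0, n, n)
  Me <- if (is.null(exo)) zero else exo$Me
  Ce <- if (is.null(exo)) zero else exo$Ce
  Ks <- if (is.null(exo)) zero else exo$Ks
  theta_eq <- if (is.null(exo)) rep(0, n) else exo$theta_eq

  rhs_terms <- function(t, theta, theta_dot) {
    tau_m <- muscle_joint_torques(muscles, theta, theta_dot, t)
    tau_e <- if (is.null(exo)) rep(0, n) else exo_torque(exo, theta, theta_dot, t)
    kc <- if (is.null(key)) {
      list(F = 0, tau_k = rep(0, n))
    } else {
      key_contact(chain, key, theta, theta_dot, contact_height)
    }
    list(tau_m = tau_m, tau_e = tau_e, F_key = kc$F, tau_k = kc$tau_k)
  }
  deriv <- function(t, y, parms) {
    theta <- y[seq_len(n)]
    theta_dot <- y[n + seq_len(n)]
    tr <- rhs_terms(t, theta, theta_dot)
    M <- chain_inertia(chain, theta) + Me
    cf <- chain_coriolis(chain, theta, theta_dot)
    rhs <- tr$tau_m + tr$tau_e - tr$tau_k -
      cf - as.numeric(Ce %*% theta_dot) - as.numeric(Ks %*% (theta - theta_eq))
    acc <- as.numeric(solve(M, rhs))
    list(c(theta_dot, acc))
  }
  times <- seq(0, duration, by = dt)
  y0 <- c(chain$theta, chain$theta_dot)
  sol <- deSolve::ode(y0, times, deriv, parms = NULL, method = "rk4")
  Y <- unclass(sol)
  bad <- !stats::complete.cases(Y) | apply(Y, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    last_ok <- if (all(bad)) 0 else max(Y[!bad, 1])
    abort(
      sprintf("simulation diverged; last valid time %.4f s", last_ok),
      class = "pianosynergy_simulation_diverged"
    )
  }
  nt <- nrow(Y)
  tau_m_mat <- tau_e_mat <- matrix(0, nt, n)
  F_key <- numeric(nt)
  for (i in seq_len(nt)) {
    tr <- rhs_terms(Y[i, 1], Y[i, 1 + seq_len(n)], Y[i, 1 + n + seq_len(n)])
    tau_m_mat[i, ] <- tr$tau_m
    tau_e_mat[i, ] <- tr$tau_e
    F_key[i] <- tr$F_key
  }
  Fa_mat <- sweep(tau_m_mat, 2, d_joint, "/")
  jn <- chain$joint_names
  out <- tibble::tibble(t = Y[, 1])
  for (j in seq_len(n)) out[[paste0("theta_", jn[j])]] <- Y[, 1 + j]
  for (j in seq_len(n)) out[[paste0("theta_dot_", jn[j])]] <- Y[, 1 + n + j]
  for (j in seq_len(n)) out[[paste0("tau_m_", jn[j])]] <- tau_m_mat[, j]
  for (j in seq_len(n)) out[[paste0("tau_e_", jn[j])]] <- tau_e_mat[, j]
  for (j in seq_len(n)) out[[paste0("Fa_", jn[j])]] <- Fa_mat[, j]
  out$F_key <- F_key
  structure(out,
    class = c("sim_trace", class(out)),
    joint_names = jn, dt = dt, contact_height = contact_height,
    d_joint = d_joint
  )
}

#' Total mechanical energy along a simulated trace
#'
#' Kinetic energy of the linkage plus the elastic energies of the
#' exoskeleton structure and (when engaged) the key spring; used to verify
#' passive dissipation.
#'
#' @param trace a [simulate_hand()] result.
#' @param chain the simulated [finger_chain()].
#' @param exo the [exo_model()] used, or `NULL`.
#' @param key the [key_model()] used, or `NULL`.
#' @param contact_height key contact height (default from the trace).
#' @return Numeric vector of energies in J, one per time step.
#' @export
trace_energy <- function(trace, chain, exo = NULL, key = NULL,
                         contact_height = attr(trace, "contact_height")) {
  jn <- attr(trace, "joint_names")
  n <- length(jn)
  th <- as.matrix(trace[paste0("theta_", jn)])
  thd <- as.matrix(trace[paste0("theta_dot_", jn)])
  Ks <- if (is.null(exo)) matrix(0, n, n) else exo$Ks
  teq <- if (is.null(exo)) rep(0, n) else exo$theta_eq
  vapply(seq_len(nrow(trace)), function(i) {
    M <- chain_inertia(chain, th[i, ]) + if (is.null(exo)) 0 else exo$Me
    e <- 0.5 * as.numeric(t(thd[i, ]) %*% M %*% thd[i, ]) +
      0.5 * as.numeric(t(th[i, ] - teq) %*% Ks %*% (th[i, ] - teq))
    if (!is.null(key)) {
      tip <- fingertip_position(chain, th[i, ])
      xk <- max(contact_height - tip[2], 0)
      e <- e + 0.5 * key$ks * xk^2
    }
    e
  }, numeric(1))
}

#' Default index-finger hand system
#'
#' A ready-to-simulate parameter set: three-phalanx index finger (uniform
#' cylinder inertia), a grand-piano-like key (100 N/m, 0.5 N s/m), a PD
#' exoskeleton with mild structural stiffness, and a flexor muscle per joint
#' with linearly angle-dependent musculotendon length.
#'
#' @return List with elements `chain`, `key`, `exo`, `muscles`,
#'   `contact_height`, `d_joint`.
#' @export
default_hand_system <- function() {
  chain <- finger_chain(
    lengths = c(0.045, 0.025, 0.018),
    theta = c(0.3, 0.3, 0.2)
  )
  n <- 3
  key <- key_model(ks = 100, bs = 0.5, travel = 0.01)
  # Me reflects the push-rod actuator and linkage inertia at each joint;
  # it dominates the tiny phalanx inertias and sets the closed-loop bandwidth
  exo <- exo_model(
    Kp = diag(0.8, n), Kd = diag(0.05, n), Ks = diag(0.1, n),
    Me = diag(c(2e-4, 1e-4, 5e-5)), Ce = diag(0.02, n),
    theta_eq = c(0.3, 0.3, 0.2), theta_d = c(0.6, 0.5, 0.3)
  )
  r0 <- c(0.011, 0.008, 0.005)
  fmax <- c(100, 60, 30)
  muscles <- lapply(1:n, function(j) {
    muscle_model(
      Fmax = fmax[j],
      lmt = local({
        rj <- r0[j]
        function(th) 0.25 - rj * th
      }),
      l0 = 0.25, vmax = 0.5, alpha = 0.1
    )
  })
  list(
    chain = chain, key = key, exo = exo, muscles = muscles,
    contact_height = 0.045, d_joint = chain$lengths / 2
  )
}

#' Read a hand-system configuration from YAML
#'
#' Parses a config with blocks `chain` (lengths, masses, theta, theta_dot),
#' `key` (ks, bs, travel), `exo` (kp, kd, ks, ce, me as scalars or vectors
#' expanded to diagonal matrices; theta_eq, theta_d), `muscles` (per joint:
#' fmax, l0, r0, vmax, alpha with `lmt(theta) = l0 - r0 * theta`), and
#' scalars `contact_height`, `d_joint`.
#'
#' @param path YAML file path.
#' @return List like [default_hand_system()].
#' @export
read_hand_config <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chain$lengths)) abort_format("config must provide chain$lengths")
  chain <- finger_chain(
    lengths = as.numeric(cfg$chain$lengths),
    masses = if (!is.null(cfg$chain$masses)) as.numeric(cfg$chain$masses),
    theta = if (!is.null(cfg$chain$theta)) as.numeric(cfg$chain$theta),
    theta_dot = if (!is.null(cfg$chain$theta_dot)) as.numeric(cfg$chain$theta_dot)
  )
  n <- length(chain$lengths)
  key <- if (!is.null(cfg$key)) {
    key_model(cfg$key$ks, cfg$key$bs %||% 0, cfg$key$travel %||% 0.01)
  }
  as_diag <- function(x, default = 0) {
    if (is.null(x)) return(diag(default, n))
    diag(rep(as.numeric(x), length.out = n), n)
  }
  exo <- if (!is.null(cfg$exo)) {
    exo_model(
      Kp = as_diag(cfg$exo$kp), Kd = as_diag(cfg$exo$kd),
      Ks = as_diag(cfg$exo$ks), Me = as_diag(cfg$exo$me),
      Ce = as_diag(cfg$exo$ce),
      theta_eq = if (!is.null(cfg$exo$theta_eq)) as.numeric(cfg$exo$theta_eq),
      theta_d = if (!is.null(cfg$exo$theta_d)) as.numeric(cfg$exo$theta_d),
      n = n
    )
  }
  muscles <- if (!is.null(cfg$muscles)) {
    lapply(cfg$muscles, function(mc) {
      muscle_model(
        Fmax = mc$fmax,
        lmt = local({
          l0 <- mc$l0 %||% 0.25
          r0 <- mc$r0 %||% 0.01
          function(th) l0 - r0 * th
        }),
        l0 = mc$l0 %||% 0.25, vmax = mc$vmax %||% 0.5,
        alpha = mc$alpha %||% 0
      )
    })
  }
  list(
    chain = chain, key = key, exo = exo, muscles = muscles,
    contact_height = cfg$contact_height %||% -Inf,
    d_joint = if (!is.null(cfg$d_joint)) {
      rep(as.numeric(cfg$d_joint), length.out = n)
    } else {
      chain$lengths / 2
    }
  )
}
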