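#' Computed-muscle-control gains
#'
#' @param k_p position feedback gain (s^-2).
#' @param k_v velocity feedback gain (s^-1); the default pair is critically
#'   damped (k_v^2 = 4 k_p).
#' @param k_u excitation feedback gain (dimensionless). Values well above 1
#'   compensate the first-order activation lag: with window w and time
#'   constant tau, u = a* + k_u (a* - a) reaches a* within one window when
#'   k_u = exp(-w/tau) / (1 - exp(-w/tau)); the default over-drives
#'   slightly (excitations clamp to [0, 1]).
#' @param window_s control update interval / lookahead window (s).
#' @return list of class `cmc_gains`.
#' @export
cmc_gains <- function(k_p = 900, k_v = 60, k_u = 5, window_s = 0.005) {
  stopifnot(k_p >= 0, k_v >= 0, k_u >= 0, window_s > 0)
  structure(list(k_p = k_p, k_v = k_v, k_u = k_u, window_s = window_s),
            class = "cmc_gains")
}

#' Stage 1: desired accelerations
#'
#' qdd* = qdd_exp + k_v (qd_exp - qd) + k_p (q_exp - q), with the reference
#' evaluated ahead of the current state by the control window.
#'
#' @param state list with `q` (deg) and `qd` (deg/s).
#' @param reference list with `angles`, `velocities`, `accelerations`
#'   evaluated at the lookahead time (single row, deg units).
#' @param gains [cmc_gains()].
#' @return desired accelerations (deg/s^2).
#' @export
desired_accelerations <- function(state, reference, gains = cmc_gains()) {
  as.numeric(reference$accelerations) +
    gains$k_v * (as.numeric(reference$velocities) - as.numeric(state$qd)) +
    gains$k_p * (as.numeric(reference$angles) - as.numeric(state$q))
}

#' Stage 2: static optimization of muscle activities
#'
#' Finds steady-state activities a* in [0, 1] minimizing sum(a^2) subject
#' (softly) to the equations of motion reproducing the desired
#' accelerations, with per-muscle forces linearized in activity at the
#' current state. Infeasibility is absorbed by heavily penalized reserve
#' generalized forces; their usage is reported so callers can assert they
#' stay near zero.
#'
#' @param model `wing_model`.
#' @param state list with `q`, `qd` (deg, deg/s).
#' @param qdd_star desired accelerations (deg/s^2).
#' @param reserve_weight penalty weight on the acceleration residual
#'   relative to sum(a^2) (default 1e4).
#' @param F_ext generalized external forces (N m).
#' @param cache optional [eom_cache()].
#' @return list with `activations` (named), `forces_N` (at a*),
#'   `reserve_norm` (residual acceleration, deg/s^2), `converged`.
#' @export
static_optimization <- function(model, state, qdd_star, reserve_weight = 1e4,
                                F_ext = 0, cache = NULL) {
  stopifnot(all(is.finite(qdd_star)))
  muscles <- model$muscles
  nm <- length(muscles)
  if (nm == 0) stop("model has no muscles")
  if (is.null(cache)) cache <- eom_cache(model)
  dofs <- model_dofs(model)
  q <- stats::setNames(as.numeric(state$q), dofs$label)
  tr <- forward_kinematics(model, q)
  Lmt <- vapply(muscles, function(m) path_length(model, m, transforms = tr), 0)
  Rm <- moment_arm_matrix(model, q)
  vmt <- as.numeric(-t(Rm) %*% (as.numeric(state$qd) * pi / 180))  # mm/s
  f0 <- fslope <- numeric(nm)
  for (i in seq_len(nm)) {
    p <- muscles[[i]]$params
    f0[i] <- steady_state_force(p, 0, Lmt[i], vmt[i])$force
    f1 <- steady_state_force(p, 1, Lmt[i], vmt[i])$force
    fslope[i] <- max(f1 - f0[i], 0)
  }
  base <- equations_of_motion(model, state, stats::setNames(f0, names(muscles)),
                              F_ext, cache)
  J <- matrix(0, length(base), nm)
  for (i in seq_len(nm)) {
    fi <- f0; fi[i] <- fi[i] + fslope[i]
    J[, i] <- equations_of_motion(model, state, stats::setNames(fi, names(muscles)),
                                  F_ext, cache) - base
  }
  d <- as.numeric(qdd_star) - base
  scl <- sqrt(mean(J^2) + 1e-12)
  w <- reserve_weight / scl^2
  obj <- function(a) sum(a^2) + w * sum((J %*% a - d)^2)
  grd <- function(a) 2 * a + 2 * w * as.numeric(t(J) %*% (J %*% a - d))
  res <- stats::optim(rep(0, nm), obj, grd, method = "L-BFGS-B",
                      lower = 0, upper = 1,
                      control = list(maxit = 500, factr = 1e4))
  a <- stats::setNames(res$par, names(muscles))
  list(activations = a,
       forces_N = stats::setNames(f0 + fslope * a, names(muscles)),
       reserve_norm = sqrt(sum((J %*% a - d)^2)),
       converged = res$convergence == 0)
}

#' Stage 3: excitation feedback controller
#'
#' u = a* + k_u (a* - a), clamped to [0, 1].
#'
#' @param a_star target activities from stage 2.
#' @param a current activities.
#' @param k_u feedback gain.
#' @return excitations in [0, 1].
#' @export
excitation_controller <- function(a_star, a, k_u = 0.5) {
  stopifnot(all(a_star >= 0 & a_star <= 1), all(a >= 0 & a <= 1))
  pmin(1, pmax(0, a_star + k_u * (a_star - a)))
}

#' Run the computed-muscle-control loop
#'
#' Tracks a reference Fourier motion with the muscle-actuated forward
#' dynamic model by looping the four stages per control window: (1)
#' desired accelerations from the reference at t + window, (2) static
#' optimization of activities, (3) excitation feedback, (4) forward
#' integration of the coupled activation (exact exponential update) and
#' rigid-body dynamics over the window (adaptive Runge-Kutta via deSolve).
#'
#' @param model `wing_model` with muscles actuating every dof direction.
#' @param reference `fourier_motion` whose dof names match the model dof
#'   labels.
#' @param gains [cmc_gains()].
#' @param duration simulated time (s), default one cycle.
#' @param dt integrator step bound within each control window (s).
#' @param F_ext generalized external forces (N m), default 0.
#' @param rigid_tendon use the rigid-tendon force model in the dynamics
#'   (default TRUE; the elastic-tendon equilibrium is used in stage 2
#'   linearization either way when FALSE).
#' @return object of class `cmc_result`: time grid, tracked `q`, `qd`,
#'   per-muscle `activations`, `excitations`, `forces_N`, the reference
#'   angles, per-dof RMS tracking error (deg) and mean reserve usage.
#' @export
cmc_simulate <- function(model, reference, gains = cmc_gains(),
                         duration = NULL, dt = 1e-3, F_ext = 0,
                         rigid_tendon = TRUE) {
  dofs <- model_dofs(model)
  n <- nrow(dofs)
  if (is.null(duration)) duration <- reference$period_s
  if (!all(dofs$label %in% motion_dofs(reference)))
    stop("reference motion must provide every model dof")
  muscles <- model$muscles
  nm <- length(muscles)
  if (nm == 0) stop("model has no muscles")
  cache <- eom_cache(model)
  mnames <- names(muscles)
  ref0 <- evaluate_motion(reference, 0, dofs$label)
  q <- as.numeric(ref0$angles); qd <- as.numeric(ref0$velocities)
  a <- rep(0.02, nm)
  win <- gains$window_s
  n_win <- max(1L, round(duration / win))
  times <- numeric(0); Q <- QD <- matrix(0, 0, n)
  ACT <- EXC <- FRC <- matrix(0, 0, nm)
  reserve <- numeric(0)

  deriv <- function(t, y, parms) {
    qv <- y[1:n]; qdv <- y[n + 1:n]; av <- pmin(1, pmax(0, y[2 * n + 1:nm]))
    qn <- stats::setNames(qv, dofs$label)
    tr <- forward_kinematics(model, qn)
    Rm <- moment_arm_matrix(model, qv)
    Lmt <- vapply(muscles, function(m) path_length(model, m, transforms = tr), 0)
    vmt <- as.numeric(-t(Rm) %*% (qdv * pi / 180))
    fm <- vapply(seq_len(nm), function(i)
      steady_state_force(muscles[[i]]$params, av[i], Lmt[i], vmt[i],
                         rigid_tendon = rigid_tendon)$force, 0)
    qdd <- equations_of_motion(model, list(q = qv, qd = qdv),
                               stats::setNames(fm, mnames), F_ext, cache)
    u <- parms$u
    tau <- ifelse(u > av, parms$tact, parms$tdeact)
    dadt <- (u - av) / tau
    list(c(qdv, qdd, dadt))
  }
  tact <- vapply(muscles, function(m) m$params$tau_act, 0)
  tdeact <- vapply(muscles, function(m) m$params$tau_deact, 0)

  for (k in seq_len(n_win)) {
    t0 <- (k - 1) * win
    refk <- evaluate_motion(reference, t0 + win, dofs$label)
    qdd_star <- desired_accelerations(list(q = q, qd = qd), refk, gains)
    so <- static_optimization(model, list(q = q, qd = qd), qdd_star,
                              F_ext = F_ext, cache = cache)
    u <- excitation_controller(so$activations, a, gains$k_u)
    y0 <- c(q, qd, a)
    sol <- deSolve::ode(y0, c(t0, t0 + win), deriv,
                        parms = list(u = u, tact = tact, tdeact = tdeact),
                        method = "ode45", hini = dt, hmax = dt,
                        rtol = 1e-6, atol = 1e-8)
    if (anyNA(sol[nrow(sol), ]) || nrow(sol) < 2)
      stop(sprintf("integration failed in window %d (t = %.3f s); state: %s",
                   k, t0, paste(signif(y0, 4), collapse = ", ")))
    yend <- sol[nrow(sol), -1]
    q <- as.numeric(yend[1:n]); qd <- as.numeric(yend[n + 1:n])
    a <- pmin(1, pmax(0, as.numeric(yend[2 * n + 1:nm])))
    if (any(abs(q) > 1e4))
      stop(sprintf("integration blow-up in window %d; state: %s",
                   k, paste(signif(c(q, qd), 4), collapse = ", ")))
    times <- c(times, t0 + win)
    Q <- rbind(Q, q); QD <- rbind(QD, qd)
    ACT <- rbind(ACT, a); EXC <- rbind(EXC, u)
    FRC <- rbind(FRC, as.numeric(so$forces_N))
    reserve <- c(reserve, so$reserve_norm)
  }
  colnames(Q) <- colnames(QD) <- dofs$label
  colnames(ACT) <- colnames(EXC) <- colnames(FRC) <- mnames
  ref_tab <- evaluate_motion(reference, times, dofs$label)$angles
  structure(list(time = times, q = Q, qd = QD,
                 activations = ACT, excitations = EXC, forces_N = FRC,
                 reference = ref_tab,
                 tracking_rms_deg = sqrt(colMeans((Q - ref_tab)^2)),
                 reserve_rms = sqrt(mean(reserve^2)),
                 gains = gains),
            class = "cmc_result")
}

#' @export
print.cmc_result <- function(x, ...) {
  cat(sprintf("<cmc_result> %d control steps, %.3f s\n",
              length(x$time), max(x$time)))
  cat("tracking RMS (deg):",
      paste(sprintf("%s=%.3g", colnames(x$q), x$tracking_rms_deg), collapse = ", "),
      "\n")
  invisible(x)
}

#' Single-dof antagonist-pair benchmark model
#'
#' A minimal muscle-driven system for exercising the control loop: one rod
#' segment on a revolute (flap) joint, actuated by an antagonist muscle
#' pair with equal, opposite moment arms. Joint damping dominates inertia
#' at flapping frequencies, so muscle work is dissipative and activity
#' bursts align with muscle shortening.
#'
#' @param mass_g segment mass (g).
#' @param length_mm segment length (mm).
#' @param moment_arm_mm magnitude of each muscle's moment arm (mm).
#' @param F_max maximum isometric force of each muscle (N).
#' @param damping joint viscous damping (N m s rad^-1).
#' @param gravity gravity vector (m s^-2), default zero.
#' @return `wing_model` with dof `flex` and muscles "agonist"/"antagonist".
#' @export
make_antagonist_benchmark <- function(mass_g = 20, length_mm = 150,
                                      moment_arm_mm = 15, F_max = 40,
                                      damping = 0.01, gravity = c(0, 0, 0)) {
  O <- c(0, 0, 0)
  tipref <- c(0, length_mm, 0)
  bones <- list(
    wing_bone("ground", 0L, 100, bone_frame(c(0, -40, 0)), bone_frame(O), 4),
    wing_bone("arm", 1L, mass_g, bone_frame(O), bone_frame(tipref), 3)
  )
  joints <- list(joint_spec("hinge", "revolute", "ground", "arm", O,
                            axes = diag(3), dof_labels = "flex"))
  h <- moment_arm_mm
  mk <- function(name, sgn) {
    pts <- list(list(bone = "ground", pos = c(0, -40, sgn * h)),
                list(bone = "arm", pos = c(0, 60, sgn * h)))
    wing_muscle(muscle_path(name, pts),
                muscle_params(l_om = 35, alpha_deg = 0, L_ts = 65,
                              F_max = F_max))
  }
  muscles <- list(agonist = mk("agonist", 1), antagonist = mk("antagonist", -1))
  wing_model(bones, joints, muscles, gravity = gravity, joint_damping = damping)
}
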