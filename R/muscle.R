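#' Wrap object
#'
#' An analytic surface (sphere, cylinder or ellipsoid) attached to a bone
#' that deflects any muscle segment that would otherwise pass through it.
#' Center/axis are given in the reference-posture global frame and move
#' with the bone.
#'
#' @param shape "sphere", "cylinder" or "ellipsoid".
#' @param bone bone label the object is attached to.
#' @param center center in reference-posture global coordinates (mm).
#' @param radii numeric: length 1 for sphere/cylinder, 3 for ellipsoid (mm).
#' @param axis cylinder axis direction (reference frame), ignored otherwise.
#' @return object of class `wrap_object`.
#' @export
wrap_object <- function(shape, bone, center, radii, axis = c(0, 0, 1)) {
  shape <- match.arg(shape, c("sphere", "cylinder", "ellipsoid"))
  if (any(radii <= 0)) stop("wrap radii must be positive")
  if (shape == "ellipsoid" && length(radii) != 3)
    stop("ellipsoid needs 3 radii")
  structure(list(shape = shape, bone = bone, center = as.numeric(center),
                 radii = as.numeric(radii), axis = normalize(axis)),
            class = "wrap_object")
}

#' Muscle path
#'
#' Ordered attachment points (origin, optional via points, insertion), each
#' bound to a bone and given in reference-posture global coordinates, plus
#' the wrap objects the path may engage. Engagement is automatic: a wrap is
#' applied to a segment whenever the straight segment would intersect it.
#'
#' @param name muscle name.
#' @param points list of `list(bone = <label>, pos = <3-vector mm>)`, in
#'   origin-to-insertion order (at least 2 points).
#' @param wraps list of [wrap_object()]s associated with this muscle.
#' @return object of class `muscle_path`.
#' @export
muscle_path <- function(name, points, wraps = list()) {
  if (length(points) < 2) stop("muscle path needs at least 2 points")
  for (p in points) stopifnot(!is.null(p$bone), length(p$pos) == 3)
  structure(list(name = name, points = points, wraps = wraps),
            class = "muscle_path")
}

#' Hill-type muscle parameters
#'
#' @param l_om optimal fiber length (mm).
#' @param alpha_deg pennation angle (deg, 0..45).
#' @param L_ts tendon slack length (mm).
#' @param F_max maximum isometric force (N).
#' @param tau_act,tau_deact activation/deactivation time constants (s).
#' @return object of class `muscle_params`.
#' @export
muscle_params <- function(l_om, alpha_deg = 0, L_ts = 1, F_max = 10,
                          tau_act = 0.010, tau_deact = 0.040) {
  stopifnot(l_om > 0, L_ts > 0, F_max > 0, tau_act > 0, tau_deact > 0,
            alpha_deg >= 0, alpha_deg <= 45)
  structure(list(l_om = l_om, alpha_deg = alpha_deg, L_ts = L_ts,
                 F_max = F_max, tau_act = tau_act, tau_deact = tau_deact),
            class = "muscle_params")
}

#' Muscle-tendon actuator (path + parameters)
#' @param path [muscle_path()].
#' @param params [muscle_params()].
#' @return object of class `wing_muscle`.
#' @export
wing_muscle <- function(path, params) {
  structure(list(name = path$name, path = path, params = params),
            class = "wing_muscle")
}

# --- path geometry ------------------------------------------------------

posed_point <- function(transforms, bone, pos) {
  apply_transform(transforms[[bone]], pos)
}

#' Muscle-tendon path length
#'
#' Total length of the muscle path in a given pose: straight segments
#' between consecutive attachment points, with any segment that intersects
#' a wrap object replaced by the shortest tangent-arc-tangent path around
#' it (closed form for spheres, unwrapped-plane construction for cylinders,
#' node relaxation for ellipsoids).
#'
#' @param model `wing_model`.
#' @param path `muscle_path` (or `wing_muscle`).
#' @param angles joint angles as accepted by [forward_kinematics()].
#' @param transforms optional precomputed fk transforms (overrides angles).
#' @return length L_mt in mm.
#' @export
path_length <- function(model, path, angles = list(), transforms = NULL) {
  if (inherits(path, "wing_muscle")) path <- path$path
  if (is.null(transforms)) transforms <- forward_kinematics(model, angles)
  pts <- lapply(path$points, function(p) posed_point(transforms, p$bone, p$pos))
  wraps <- lapply(path$wraps, function(w) pose_wrap(w, transforms))
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    total <- total + segment_length_wrapped(pts[[i]], pts[[i + 1]], wraps)
  }
  total
}

pose_wrap <- function(w, transforms) {
  Tb <- transforms[[w$bone]]
  w$center <- apply_transform(Tb, w$center)
  w$axis <- as.numeric(Tb$R %*% w$axis)
  w
}

segment_length_wrapped <- function(p1, p2, wraps) {
  for (w in wraps) {
    if (wrap_engaged(p1, p2, w)) return(wrap_length(p1, p2, w))
  }
  sqrt(sum((p2 - p1)^2))
}

inside_wrap <- function(p, w) {
  d <- p - w$center
  switch(w$shape,
         sphere = sqrt(sum(d^2)) < w$radii[1],
         cylinder = {
           dp <- d - sum(d * w$axis) * w$axis
           sqrt(sum(dp^2)) < w$radii[1]
         },
         ellipsoid = sum((d / w$radii)^2) < 1)
}

wrap_engaged <- function(p1, p2, w) {
  if (inside_wrap(p1, w) || inside_wrap(p2, w))
    stop(sprintf("muscle attachment point inside wrap object on bone '%s'", w$bone))
  # closest approach of the straight segment to the (scaled) center
  scl <- if (w$shape == "ellipsoid") w$radii else rep(w$radii[1], 3)
  if (w$shape == "cylinder") {
    a1 <- p1 - w$center; a2 <- p2 - w$center
    a1 <- a1 - sum(a1 * w$axis) * w$axis
    a2 <- a2 - sum(a2 * w$axis) * w$axis
    return(seg_point_dist(a1, a2, c(0, 0, 0)) < w$radii[1])
  }
  u1 <- (p1 - w$center) / scl; u2 <- (p2 - w$center) / scl
  seg_point_dist(u1, u2, c(0, 0, 0)) < 1
}

seg_point_dist <- function(a, b, p) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(1, max(0, t))
  sqrt(sum((a + t * ab - p)^2))
}

# closed-form shortest tangent-arc-tangent path around a sphere; the path
# lies in the plane through p1, p2 and the center
sphere_wrap_length <- function(p1, p2, center, r) {
  v1 <- p1 - center; v2 <- p2 - center
  d1 <- sqrt(sum(v1^2)); d2 <- sqrt(sum(v2^2))
  theta <- acos(min(1, max(-1, sum(v1 * v2) / (d1 * d2))))
  arc <- theta - acos(min(1, r / d1)) - acos(min(1, r / d2))
  if (arc <= 0) return(sqrt(sum((p2 - p1)^2)))  # tangents clear the sphere
  sqrt(d1^2 - r^2) + sqrt(d2^2 - r^2) + r * arc
}

# cylinder wrap via the unwrapped-plane construction: solve the circular
# wrap in the cross-section plane, then restore the axial component (the
# geodesic unrolls to a straight line, so L = sqrt(L_planar^2 + dz^2))
cylinder_wrap_length <- function(p1, p2, center, r, axis) {
  z1 <- sum((p1 - center) * axis); z2 <- sum((p2 - center) * axis)
  a1 <- (p1 - center) - z1 * axis; a2 <- (p2 - center) - z2 * axis
  d1 <- sqrt(sum(a1^2)); d2 <- sqrt(sum(a2^2))
  theta <- acos(min(1, max(-1, sum(a1 * a2) / (d1 * d2))))
  arc <- theta - acos(min(1, r / d1)) - acos(min(1, r / d2))
  if (arc <= 0) return(sqrt(sum((p2 - p1)^2)))
  planar <- sqrt(d1^2 - r^2) + sqrt(d2^2 - r^2) + r * arc
  sqrt(planar^2 + (z2 - z1)^2)
}

# ellipsoid wrap by shortest-path node relaxation: midpoint smoothing of an
# n-node polyline with radial projection of interior nodes onto the surface
ellipsoid_wrap_length <- function(p1, p2, center, radii, n_nodes = 50,
                                  iters = 400) {
  tgrid <- seq(0, 1, length.out = n_nodes)
  nodes <- outer(1 - tgrid, p1) + outer(tgrid, p2)
  proj <- function(x) {
    u <- (x - center) / radii
    s <- sqrt(sum(u^2))
    if (s < 1) center + radii * (u / s) else x
  }
  for (it in seq_len(iters)) {
    for (i in 2:(n_nodes - 1)) {
      nodes[i, ] <- proj((nodes[i - 1, ] + nodes[i + 1, ]) / 2)
    }
  }
  sum(sqrt(rowSums((nodes[-1, , drop = FALSE] - nodes[-n_nodes, , drop = FALSE])^2)))
}

wrap_length <- function(p1, p2, w) {
  switch(w$shape,
         sphere = sphere_wrap_length(p1, p2, w$center, w$radii[1]),
         cylinder = cylinder_wrap_length(p1, p2, w$center, w$radii[1], w$axis),
         ellipsoid = ellipsoid_wrap_length(p1, p2, w$center, w$radii))
}

# --- moment arms --------------------------------------------------------

# does the path cross the joint owning this dof? true when the joint's
# distal subtree contains some but not all of the attachment bones
path_crosses_joint <- function(model, path, joint_name) {
  j <- model$joints[[joint_name]]
  subtree <- j$child
  repeat {
    kids <- vapply(model$joints, function(x) x$parent %in% subtree && !(x$child %in% subtree), TRUE)
    if (!any(kids)) break
    subtree <- c(subtree, vapply(model$joints[kids], `[[`, "", "child"))
  }
  bones <- vapply(path$points, `[[`, "", "bone")
  any(bones %in% subtree) && !all(bones %in% subtree)
}

#' Muscle moment arm (tendon excursion)
#'
#' Moment arm of a muscle about one degree of freedom, computed as the
#' tendon-excursion derivative -dL_mt/dq by central finite difference
#' (default step 1e-4 rad). Returns exactly 0 for a dof whose joint the
#' path does not cross.
#'
#' @param model `wing_model`.
#' @param path `muscle_path` or `wing_muscle`.
#' @param angles pose (named dof-label vector or per-joint list, degrees).
#' @param dof dof label.
#' @param step_rad finite-difference step (rad).
#' @return moment arm in mm (per radian of the dof).
#' @export
moment_arm <- function(model, path, angles, dof, step_rad = 1e-4) {
  if (inherits(path, "wing_muscle")) path <- path$path
  dofs <- model_dofs(model)
  if (!(dof %in% dofs$label)) stop("unknown dof: ", dof)
  jname <- dofs$joint[dofs$label == dof]
  if (!path_crosses_joint(model, path, jname)) return(0)
  flat <- flatten_angles(model, angles)
  step_deg <- step_rad * 180 / pi
  up <- flat; up[dof] <- up[dof] + step_deg
  dn <- flat; dn[dof] <- dn[dof] - step_deg
  -(path_length(model, path, up) - path_length(model, path, dn)) / (2 * step_rad)
}

# named flat dof vector (degrees) from either input form
flatten_angles <- function(model, angles) {
  dofs <- model_dofs(model)
  if (is.numeric(angles) && !is.null(names(angles))) {
    out <- stats::setNames(rep(0, nrow(dofs)), dofs$label)
    out[intersect(names(angles), dofs$label)] <-
      angles[intersect(names(angles), dofs$label)]
    return(out)
  }
  out <- stats::setNames(rep(0, nrow(dofs)), dofs$label)
  for (j in model$joints) {
    if (!is.null(angles[[j$name]])) out[j$dof_labels] <- angles[[j$name]]
  }
  out
}

# --- activation & contraction dynamics ---------------------------------

#' One step of first-order activation dynamics
#'
#' da/dt = (u - a)/tau with tau = tau_act while excitation exceeds activity
#' and tau_deact otherwise, integrated exactly over `dt` (exponential
#' update); the result is clamped to [0, 1].
#'
#' @param a current activity in [0, 1].
#' @param u excitation in [0, 1].
#' @param dt time step (s, > 0).
#' @param tau_act,tau_deact time constants (s, > 0).
#' @return updated activity.
#' @export
activation_step <- function(a, u, dt, tau_act = 0.010, tau_deact = 0.040) {
  if (tau_act <= 0 || tau_deact <= 0) stop("time constants must be positive")
  stopifnot(dt > 0)
  tau <- ifelse(u > a, tau_act, tau_deact)
  a_new <- u + (a - u) * exp(-dt / tau)
  pmin(1, pmax(0, a_new))
}

# normalized Hill curves (documented in the methods vignette)
fl_active <- function(lnorm) exp(-(lnorm - 1)^2 / 0.45)
fp_passive <- function(lnorm, kpe = 4, e0 = 0.6) {
  ifelse(lnorm > 1, (exp(kpe * (lnorm - 1) / e0) - 1) / (exp(kpe) - 1), 0)
}
# vnorm: fiber velocity / (vmax), vmax = 10 optimal lengths/s; negative =
# shortening. Hyperbolic concentric limb, saturating eccentric limb.
fv_hill <- function(vnorm) {
  ifelse(vnorm < 0,
         pmax(0, (1 + vnorm) / (1 - 4 * vnorm)),
         1 + 0.8 * vnorm / (vnorm + 0.25))
}
tendon_force_norm <- function(strain, strain_at_fmax = 0.033) {
  ifelse(strain > 0, strain / strain_at_fmax, 0)
}

#' Steady-state Hill-type muscle force
#'
#' Lumped-parameter muscle-tendon force at a given activity, muscle-tendon
#' length and lengthening velocity. The fiber/tendon partition is solved
#' from elastic-tendon equilibrium (tendon force = fiber force along the
#' tendon) by root bracketing; `rigid_tendon = TRUE` pins the tendon at its
#' slack length instead. Fiber force combines the active force-length and
#' force-velocity curves with the passive exponential, scaled by cos of the
#' pennation angle.
#'
#' @param params [muscle_params()].
#' @param a activity in [0, 1].
#' @param L_mt muscle-tendon length (mm).
#' @param v_mt lengthening velocity (mm/s, positive = lengthening).
#' @param rigid_tendon logical.
#' @return list with `force` (N, tendon force), `fiber_lnorm` (normalized
#'   fiber length), `equilibrium_residual` (N), `rigid_fallback` (logical).
#' @export
steady_state_force <- function(params, a, L_mt, v_mt = 0, rigid_tendon = FALSE) {
  stopifnot(a >= 0, a <= 1)
  p <- params
  cosa <- cos(p$alpha_deg * pi / 180)
  vmax <- 10 * p$l_om                       # mm/s
  vnorm <- (v_mt / cosa) / vmax             # rigid-tendon velocity partition
  fiber_force_norm <- function(lnorm)
    (a * fl_active(lnorm) * fv_hill(vnorm) + fp_passive(lnorm)) * cosa
  if (rigid_tendon) {
    lnorm <- (L_mt - p$L_ts) / (p$l_om * cosa)
    if (lnorm <= 0) return(list(force = 0, fiber_lnorm = 0,
                                equilibrium_residual = 0, rigid_fallback = FALSE))
    f <- p$F_max * fiber_force_norm(lnorm)
    return(list(force = max(0, f), fiber_lnorm = lnorm,
                equilibrium_residual = 0, rigid_fallback = FALSE))
  }
  bal <- function(lnorm) {
    strain <- (L_mt - lnorm * p$l_om * cosa - p$L_ts) / p$L_ts
    tendon_force_norm(strain) - fiber_force_norm(lnorm)
  }
  lo <- 1e-6; hi <- max(2.5, (L_mt - p$L_ts) / (p$l_om * cosa) + 0.5)
  if (bal(lo) <= 0) {
    # tendon slack even at zero fiber length: no force
    if (bal(hi) <= 0 || L_mt <= p$L_ts)
      return(list(force = 0, fiber_lnorm = max(0, (L_mt - p$L_ts) / (p$l_om * cosa)),
                  equilibrium_residual = 0, rigid_fallback = FALSE))
  }
  if (sign(bal(lo)) == sign(bal(hi))) {
    # no equilibrium in bracket: rigid-tendon fallback, reported
    res <- steady_state_force(params, a, L_mt, v_mt, rigid_tendon = TRUE)
    res$rigid_fallback <- TRUE
    return(res)
  }
  root <- stats::uniroot(bal, c(lo, hi), tol = 1e-12)$root
  strain <- (L_mt - root * p$l_om * cosa - p$L_ts) / p$L_ts
  force <- p$F_max * tendon_force_norm(strain)
  list(force = force, fiber_lnorm = root,
       equilibrium_residual = p$F_max * abs(bal(root)),
       rigid_fallback = FALSE)
}

#' Estimate tendon slack length from length extremes
#'
#' Solves the two-point system
#' L_mt = L_ts (1 + eps) + lnorm l_om cos(alpha)
#' at the motion's minimum and maximum muscle-tendon lengths. With `l_om`
#' supplied, only the minimum-length equation is used. With `l_om = NULL`
#' both equations are solved as a 2x2 linear system for (L_ts, l_om).
#'
#' The default strains are zero (rigid-tendon estimate): measured
#' muscle-tendon excursions are of the same order as peak tendon strain, so
#' attributing a strain ramp to the tendon across the stroke makes the
#' two-point system infeasible for low-excursion muscles. Non-zero strains
#' can be supplied for muscles where the excursion supports them.
#'
#' @param L_mt_min,L_mt_max extreme muscle-tendon lengths over the motion
#'   (mm, max > min > 0).
#' @param alpha_deg pennation angle (deg).
#' @param lnorm_min,lnorm_max normalized fiber lengths assumed at the two
#'   extremes (defaults 0.85 and 1.05).
#' @param eps_min,eps_max tendon strains assumed at the two extremes
#'   (default 0, see Details).
#' @param l_om optional known optimal fiber length (mm).
#' @return list with `L_ts` and `l_om` (mm).
#' @export
estimate_tendon_slack <- function(L_mt_min, L_mt_max, alpha_deg = 0,
                                  lnorm_min = 0.85, lnorm_max = 1.05,
                                  eps_min = 0, eps_max = 0, l_om = NULL) {
  if (!(L_mt_max > L_mt_min) || L_mt_min <= 0)
    stop("need L_mt_max > L_mt_min > 0")
  cosa <- cos(alpha_deg * pi / 180)
  if (!is.null(l_om)) {
    L_ts <- (L_mt_min - lnorm_min * l_om * cosa) / (1 + eps_min)
    if (L_ts <= 0 || L_ts >= L_mt_min)
      stop("inconsistent inputs: no positive tendon slack length")
    return(list(L_ts = L_ts, l_om = l_om))
  }
  M <- rbind(c(1 + eps_min, lnorm_min * cosa),
             c(1 + eps_max, lnorm_max * cosa))
  sol <- solve(M, c(L_mt_min, L_mt_max))
  L_ts <- sol[1]; l_om_hat <- sol[2]
  if (L_ts <= 0 || l_om_hat <= 0 || L_ts >= L_mt_min)
    stop("inconsistent inputs: no positive solution for (L_ts, l_om)")
  list(L_ts = L_ts, l_om = l_om_hat)
}

# --- trajectories -------------------------------------------------------

#' Muscle-tendon length trajectory over one motion cycle
#'
#' @param model `wing_model`.
#' @param path `muscle_path` or `wing_muscle`.
#' @param motion `fourier_motion` whose dof names match model dof labels.
#' @param samples number of samples over the cycle (>= 2); sample i is at
#'   cycle fraction (i-1)/samples.
#' @return data.frame with `fraction` (0..1) and `length_mm`.
#' @export
length_trajectory <- function(model, path, motion, samples = 200) {
  stopifnot(samples >= 2)
  if (inherits(path, "wing_muscle")) path <- path$path
  frac <- (seq_len(samples) - 1) / samples
  ang <- evaluate_motion(motion, frac * motion$period_s)$angles
  L <- vapply(seq_len(samples), function(i) {
    q <- stats::setNames(as.numeric(ang[i, ]), colnames(ang))
    path_length(model, path, flatten_angles(model, q))
  }, 0)
  data.frame(fraction = frac, length_mm = L)
}

#' Contraction periods of a length trajectory
#'
#' Intervals of the flapping cycle in which the (smoothed) muscle-tendon
#' length is strictly decreasing -- the periods in which the muscle
#' shortens and is taken to be generating force. The sampled trajectory is
#' smoothed by a Fourier refit (order 6 by default) and interval boundaries
#' are the analytic derivative roots, reported to 0.5% cycle resolution.
#'
#' @param trajectory data.frame from [length_trajectory()] (>= 10 samples
#'   per cycle).
#' @param smooth_order Fourier order of the smoothing refit.
#' @param resolution_pct boundary rounding, percent of cycle (default 0.5).
#' @return 2-column matrix of start/end cycle percentages (possibly 0 rows).
#' @export
contraction_periods <- function(trajectory, smooth_order = 6,
                                resolution_pct = 0.5) {
  stopifnot(nrow(trajectory) >= 10)
  fit <- fit_fourier(trajectory$fraction, trajectory$length_mm,
                     K = smooth_order, period_s = 1)
  ph <- phase_analysis(fit$motion)[[1]]
  if (ph$no_stroke) return(matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("start_pct", "end_pct"))))
  m <- ph$decreasing
  m <- round(m / resolution_pct) * resolution_pct
  # normalize to wrap the cycle boundary: report within [0, 100]
  normalize_intervals_pct(m)
}

# split intervals that run past 100% into wrapped pieces and sort
normalize_intervals_pct <- function(m) {
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(m))) {
    s <- m[i, 1]; e <- m[i, 2]
    if (e <= 100) out <- rbind(out, c(s, e))
    else out <- rbind(out, c(s, 100), c(0, e - 100))
  }
  out <- out[out[, 1] != out[, 2], , drop = FALSE]
  out <- out[order(out[, 1]), , drop = FALSE]
  # an interval ending at 100 is NOT merged with one starting at 0:
  # reports keep wrapped pieces separate, matching how contraction
  # periods are conventionally tabulated
  colnames(out) <- c("start_pct", "end_pct")
  out
}
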