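# Rigid-body dynamics of the actuated chain: recursive Newton-Euler
# inverse dynamics over the model's ordered dofs, from which the mass
# matrix and bias forces are extracted numerically. Internally SI units
# (m, kg, s, rad); the package interface stays in mm / g / deg.

# links: one per dof; bones attach to the last dof that moves them, fused
# with everything connected by fixed joints downstream of it
build_links <- function(model) {
  dofs <- model_dofs(model)
  n <- nrow(dofs)
  if (n == 0) stop("model has no degrees of freedom")
  # which dofs move each bone (in chain order)
  bone_last_dof <- integer(0)
  for (b in names(model$bones)[-1]) {
    moving <- integer(0)
    cur <- b
    repeat {
      j <- NULL
      for (jj in model$joints) if (jj$child == cur) { j <- jj; break }
      if (is.null(j)) break
      if (joint_dof_count(j$kind) > 0)
        moving <- c(moving, which(dofs$joint == j$name))
      cur <- j$parent
      if (cur == names(model$bones)[1]) break
    }
    bone_last_dof[b] <- if (length(moving)) max(moving) else 0L
  }
  links <- vector("list", n)
  for (i in seq_len(n)) {
    bones <- names(bone_last_dof)[bone_last_dof == i]
    if (length(bones) == 0) {
      links[[i]] <- list(mass = 0, com = dofs$center[[i]] * 1e-3,
                         inertia = matrix(0, 3, 3), bones = character())
      next
    }
    props <- lapply(bones, function(b) bone_inertial(model$bones[[b]]))
    mass <- sum(vapply(props, `[[`, 0, "mass"))
    if (mass <= 0) {
      links[[i]] <- list(mass = 0, com = dofs$center[[i]] * 1e-3,
                         inertia = matrix(0, 3, 3), bones = character())
      next
    }
    com <- Reduce(`+`, lapply(props, function(p) p$mass * p$com)) / mass
    inertia <- Reduce(`+`, lapply(props, function(p) {
      d <- p$com - com
      p$inertia + p$mass * (sum(d^2) * diag(3) - outer(d, d))
    }))
    links[[i]] <- list(mass = mass, com = com, inertia = inertia, bones = bones)
  }
  links
}

# mass (kg), COM (m) and inertia about COM (kg m^2) of one bone, modeled
# as a solid cylinder between its proximal and distal frame origins
bone_inertial <- function(bone) {
  m <- bone$mass_g * 1e-3
  p0 <- bone$proximal$origin * 1e-3; p1 <- bone$distal$origin * 1e-3
  r <- bone$radius_mm * 1e-3
  L <- sqrt(sum((p1 - p0)^2))
  com <- (p0 + p1) / 2
  if (L < 1e-12) {
    inertia <- diag(2 / 5 * m * r^2, 3)   # degenerate: sphere
  } else {
    u <- (p1 - p0) / L
    B <- triad_from_z(u)
    Iax <- m * r^2 / 2
    Iperp <- m * (3 * r^2 + L^2) / 12
    inertia <- B %*% diag(c(Iperp, Iperp, Iax)) %*% t(B)
  }
  list(mass = m, com = com, inertia = inertia)
}

# posed dof axes (unit, global) and origins (m) for configuration q (deg)
posed_dof_frames <- function(model, q_deg, transforms = NULL) {
  dofs <- model_dofs(model)
  if (is.null(transforms))
    transforms <- forward_kinematics(model, stats::setNames(q_deg, dofs$label))
  axes <- vector("list", nrow(dofs)); origins <- vector("list", nrow(dofs))
  for (i in seq_len(nrow(dofs))) {
    j <- model$joints[[dofs$joint[i]]]
    k <- match(dofs$label[i], j$dof_labels)
    Rpar <- transforms[[j$parent]]$R
    # preceding dofs of the same joint rotate this dof's axis
    Racc <- diag(3)
    if (k > 1) for (kk in seq_len(k - 1))
      Racc <- Racc %*% rod_R(j$axes[, kk], q_deg[dofs$label == j$dof_labels[kk]])
    axes[[i]] <- as.numeric(Rpar %*% Racc %*% j$axes[, k])
    origins[[i]] <- apply_transform(transforms[[j$parent]], j$center) * 1e-3
  }
  list(axes = axes, origins = origins, transforms = transforms)
}

# recursive Newton-Euler inverse dynamics: generalized forces (N m) that
# realize qdd at (q, qd); gravity enters through the base acceleration
rnea <- function(model, q_deg, qd_rad, qdd_rad, links = NULL, frames = NULL,
                 gravity = model$gravity) {
  dofs <- model_dofs(model)
  n <- nrow(dofs)
  if (is.null(links)) links <- build_links(model)
  if (is.null(frames)) frames <- posed_dof_frames(model, q_deg)
  # posed link COM / inertia
  com <- vector("list", n); inert <- vector("list", n)
  for (i in seq_len(n)) {
    l <- links[[i]]
    if (l$mass == 0) { com[[i]] <- frames$origins[[i]]; inert[[i]] <- matrix(0, 3, 3); next }
    bone1 <- l$bones[1]
    T_ <- frames$transforms[[bone1]]
    com[[i]] <- apply_transform(T_, l$com * 1e3) * 1e-3
    inert[[i]] <- T_$R %*% l$inertia %*% t(T_$R)
  }
  w <- a_ang <- a_lin <- vector("list", n)
  w_prev <- c(0, 0, 0); al_prev <- c(0, 0, 0); acc_prev <- -gravity
  o_prev <- frames$origins[[1]]
  for (i in seq_len(n)) {
    o <- frames$origins[[i]]; u <- frames$axes[[i]]
    d <- o - o_prev
    acc_o <- acc_prev + cross3(al_prev, d) + cross3(w_prev, cross3(w_prev, d))
    w[[i]] <- w_prev + u * qd_rad[i]
    a_ang[[i]] <- al_prev + u * qdd_rad[i] + cross3(w_prev, u) * qd_rad[i]
    a_lin[[i]] <- acc_o
    w_prev <- w[[i]]; al_prev <- a_ang[[i]]; acc_prev <- acc_o; o_prev <- o
  }
  # COM accelerations and link wrenches
  F <- N <- vector("list", n)
  for (i in seq_len(n)) {
    dc <- com[[i]] - frames$origins[[i]]
    a_c <- a_lin[[i]] + cross3(a_ang[[i]], dc) + cross3(w[[i]], cross3(w[[i]], dc))
    F[[i]] <- links[[i]]$mass * a_c
    N[[i]] <- inert[[i]] %*% a_ang[[i]] + cross3(w[[i]], as.numeric(inert[[i]] %*% w[[i]]))
  }
  tau <- numeric(n)
  f_next <- c(0, 0, 0); n_next <- c(0, 0, 0); o_next <- NULL
  for (i in rev(seq_len(n))) {
    o <- frames$origins[[i]]
    f_i <- F[[i]] + f_next
    n_i <- as.numeric(N[[i]]) + cross3(com[[i]] - o, F[[i]]) + n_next
    if (!is.null(o_next)) n_i <- n_i + cross3(o_next - o, f_next)
    tau[i] <- sum(frames$axes[[i]] * n_i)
    f_next <- f_i; n_next <- n_i; o_next <- o
  }
  tau
}

#' Equations of motion of the wing chain
#'
#' Computes generalized accelerations from the current state and applied
#' forces: qdd = M(q)^-1 (G(q) + C(q, qd) + R(q) f_m + F_ext), with the
#' mass matrix and bias terms assembled by recursive Newton-Euler over the
#' chain. Joint viscous damping (model$joint_damping) is included as a
#' generalized force -c qd.
#'
#' @param model `wing_model`.
#' @param state list with `q` (deg) and `qd` (deg/s), in [model_dofs()]
#'   order (named vectors allowed).
#' @param muscle_forces named vector of muscle-tendon forces (N), names
#'   matching model muscles (may be empty).
#' @param F_ext generalized external forces per dof (N m), default 0.
#' @param cache optional precomputed [eom_cache()].
#' @return generalized accelerations qdd (deg/s^2).
#' @export
equations_of_motion <- function(model, state, muscle_forces = numeric(0),
                                F_ext = 0, cache = NULL) {
  dofs <- model_dofs(model)
  n <- nrow(dofs)
  q <- as.numeric(state$q); qd <- as.numeric(state$qd)
  stopifnot(length(q) == n, length(qd) == n)
  if (is.null(cache)) cache <- eom_cache(model)
  frames <- posed_dof_frames(model, q)
  qd_r <- qd * pi / 180
  Mb <- mass_matrix_bias(model, q, qd_r, cache$links, frames)
  tau <- rep_len(as.numeric(F_ext), n) - model$joint_damping * qd_r
  if (length(muscle_forces)) {
    Rm <- moment_arm_matrix(model, q, names(muscle_forces))
    tau <- tau + as.numeric(Rm %*% muscle_forces) * 1e-3   # mm -> m
  }
  qdd_r <- solve(Mb$M, tau - Mb$bias)
  as.numeric(qdd_r) * 180 / pi
}

#' Precompute dynamics quantities reused across calls
#' @param model `wing_model`.
#' @return list with link inertial properties.
#' @export
eom_cache <- function(model) {
  links <- build_links(model)
  M0 <- mass_matrix_bias(model, rep(0, length(links)),
                         rep(0, length(links)), links,
                         posed_dof_frames(model, rep(0, length(links))))$M
  ev <- eigen(M0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop("singular mass matrix: a degree of freedom carries no inertia")
  list(links = links)
}

mass_matrix_bias <- function(model, q, qd_r, links, frames) {
  n <- length(q)
  bias <- rnea(model, q, qd_r, rep(0, n), links, frames)
  M <- matrix(0, n, n)
  zero_g <- c(0, 0, 0)
  tau0 <- rnea(model, q, rep(0, n), rep(0, n), links, frames, gravity = zero_g)
  for (i in seq_len(n)) {
    e <- rep(0, n); e[i] <- 1
    M[, i] <- rnea(model, q, rep(0, n), e, links, frames, gravity = zero_g) - tau0
  }
  M <- (M + t(M)) / 2
  list(M = M, bias = bias)
}

#' Moment-arm matrix of the model's muscles
#'
#' @param model `wing_model`.
#' @param q_deg configuration (deg, dof order).
#' @param muscles muscle name subset (default all).
#' @return ndof x nmuscle matrix of moment arms (mm per rad).
#' @export
moment_arm_matrix <- function(model, q_deg, muscles = names(model$muscles),
                              step_rad = 1e-4) {
  dofs <- model_dofs(model)
  qn <- stats::setNames(as.numeric(q_deg), dofs$label)
  out <- matrix(0, nrow(dofs), length(muscles),
                dimnames = list(dofs$label, muscles))
  step_deg <- step_rad * 180 / pi
  crosses <- vapply(muscles, function(m)
    vapply(dofs$label, function(d)
      path_crosses_joint(model, model$muscles[[m]]$path,
                         dofs$joint[dofs$label == d]), TRUE),
    logical(nrow(dofs)))
  crosses <- matrix(crosses, nrow = nrow(dofs),
                    dimnames = list(dofs$label, muscles))
  for (d in dofs$label) {
    if (!any(crosses[d, ])) next
    up <- qn; up[d] <- up[d] + step_deg
    dn <- qn; dn[d] <- dn[d] - step_deg
    tr_up <- forward_kinematics(model, up)
    tr_dn <- forward_kinematics(model, dn)
    for (m in muscles[crosses[d, ]]) {
      p <- model$muscles[[m]]$path
      out[d, m] <- -(path_length(model, p, transforms = tr_up) -
                       path_length(model, p, transforms = tr_dn)) / (2 * step_rad)
    }
  }
  out
}
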