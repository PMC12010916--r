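#' Registration residual between two point clouds
#'
#' The mean Euclidean distance between the transformed initial cloud and
#' the current cloud. With matched clouds (same size and point order, the
#' default) distances are taken pairwise; `match = "nearest"` uses the
#' nearest-neighbor distance from each transformed point instead, for
#' clouds without correspondence.
#'
#' @param init,curr Nx3 matrices or `posture_cloud` objects (mm).
#' @param transform `rigid_transform` applied to `init`.
#' @param match "paired" (default) or "nearest".
#' @return mean distance in mm.
#' @export
cloud_residual <- function(init, curr, transform = rt_identity(),
                           match = c("paired", "nearest")) {
  match <- match.arg(match)
  A <- if (inherits(init, "posture_cloud")) init$points else as.matrix(init)
  B <- if (inherits(curr, "posture_cloud")) curr$points else as.matrix(curr)
  TA <- apply_transform(transform, A)
  if (match == "paired") {
    if (nrow(A) != nrow(B)) stop("paired residual needs clouds of equal size")
    return(mean(sqrt(rowSums((TA - B)^2))))
  }
  d2 <- outer(rowSums(TA^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(TA)), rowSums(B^2)) - 2 * TA %*% t(B)
  mean(sqrt(pmax(0, apply(d2, 1, min))))
}

# Kabsch closed-form rigid registration of matched clouds (A -> B)
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cb - as.numeric(R %*% ca), check = FALSE)
}

# rotation vector (axis * angle, radians) from a rotation matrix
rotvec_from_matrix <- function(R) {
  ang <- rotation_angle(R) * pi / 180
  if (ang < 1e-12) return(c(0, 0, 0))
  if (ang > pi - 1e-4) {
    # near 180 deg: sin(ang) is ill-conditioned; take the axis as the
    # dominant column of R + I and fix its sign from the skew part
    M <- R + diag(3)
    u <- normalize(M[, which.max(colSums(M^2))])
    skew <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (sum(u * skew) < 0) u <- -u
    return(u * ang)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  ax * ang
}

matrix_from_rotvec <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-300) return(diag(3))
  rotation_about_axis(v / ang, ang * 180 / pi)$R
}

#' Kinematic constraint residual of a joint
#'
#' Evaluates the translational and vector constraint equations for a joint
#' connecting a parent and a child body, given the rigid transforms of both
#' bodies from the reference posture. The joint geometry fixes an
#' attachment point (shared in the reference posture) and reference axis
#' triads on both bodies. Residual components: translational separation of
#' the two attachment points (mm); rotational terms by kind --
#' fixed: the relative rotation vector (should be zero);
#' revolute: orthogonality of the parent x/y axes to the child z axis
#' (z axes must stay aligned, rotation about z free);
#' universal: orthogonality of the parent x axis to the child z axis
#' (two free angles);
#' spherical: no rotational constraint;
#' spiral: as revolute, but translation along z must equal
#' pitch * rotation/360 (the coupling term replaces that translation
#' component).
#'
#' @param kind joint kind.
#' @param parent_T,child_T `rigid_transform` of parent and child bodies.
#' @param geometry list with `point` (shared attachment point, reference
#'   frame, mm) and optionally `axes` (3x3 reference triad, default
#'   identity) and `pitch_mm_per_rev` for spiral joints.
#' @return named numeric vector of residuals (translational in mm,
#'   vector terms dimensionless).
#' @export
joint_constraint_residual <- function(kind, parent_T, child_T, geometry) {
  kind <- match.arg(kind, c("fixed", "revolute", "universal", "spherical", "spiral"))
  p <- geometry$point
  axes <- if (is.null(geometry$axes)) diag(3) else geometry$axes
  pm <- apply_transform(parent_T, p)
  pn <- apply_transform(child_T, p)
  Ap <- parent_T$R %*% axes   # posed parent triad
  Ac <- child_T$R %*% axes    # posed child triad
  trans <- pm - pn
  names(trans) <- c("tx", "ty", "tz")
  Rrel <- t(parent_T$R) %*% child_T$R
  switch(kind,
         fixed = {
           rv <- rotvec_from_matrix(Rrel)
           c(trans, rx = rv[1], ry = rv[2], rz = rv[3])
         },
         revolute = c(trans,
                      xz = sum(Ap[, 1] * Ac[, 3]),
                      yz = sum(Ap[, 2] * Ac[, 3])),
         universal = c(trans, xz = sum(Ap[, 1] * Ac[, 3])),
         spherical = trans,
         spiral = {
           z <- Ap[, 3]
           gamma <- rotation_angle(Rrel)  # deg about the shared axis
           pitch <- if (is.null(geometry$pitch_mm_per_rev)) 0 else geometry$pitch_mm_per_rev
           slide <- sum((pn - pm) * z)
           perp <- trans - sum(trans * z) * z
           c(t_perp1 = perp[1], t_perp2 = perp[2], t_perp3 = perp[3],
             xz = sum(Ap[, 1] * Ac[, 3]), yz = sum(Ap[, 2] * Ac[, 3]),
             coupling = slide - pitch * gamma / 360)
         })
}

#' Optimizer configuration for skeletal motion fitting
#'
#' @param n_starts number of random multi-starts (an informed start derived
#'   from per-bone closed-form registration is always added).
#' @param seed RNG seed for start generation.
#' @param max_iter iteration cap per start.
#' @param reltol relative objective-change convergence tolerance (mm).
#' @param center_spread_mm random start spread of joint centers around the
#'   child-bone centroid (mm).
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20, seed = 1L, max_iter = 200,
                       reltol = 1e-12, center_spread_mm = 40) {
  structure(list(n_starts = n_starts, seed = as.integer(seed),
                 max_iter = max_iter, reltol = reltol,
                 center_spread_mm = center_spread_mm), class = "fit_config")
}

# --- internal: chain parameterization ----------------------------------

# number of parameters for a joint kind with P postures (P-1 non-reference)
joint_par_count <- function(kind, n_free) {
  as.integer(switch(kind,
                    revolute = 3 + 2 + n_free,
                    universal = 3 + 3 + 2 * n_free,
                    spherical = 3 + 3 * n_free,
                    fixed = 0,
                    stop("unsupported joint kind in fit: ", kind)))
}

axis_from_sph <- function(phi, psi) {
  c(sin(phi) * cos(psi), sin(phi) * sin(psi), cos(phi))
}

# plain (R, t) pair helpers for the optimizer hot path (no S3 overhead)
rod_R <- function(u, th_deg) {
  th <- th_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
rt_fast <- function(R, cen) list(R = R, t = cen - as.numeric(R %*% cen))
compose_fast <- function(a, b) list(R = a$R %*% b$R,
                                    t = as.numeric(a$R %*% b$t) + a$t)

# joint transform for posture index k (1..n_free) from packed parameters
joint_transform_from_par <- function(kind, par, k) {
  if (kind == "fixed") return(list(R = diag(3), t = c(0, 0, 0)))
  cen <- par[1:3]
  if (kind == "revolute") {
    u <- axis_from_sph(par[4], par[5])
    rt_fast(rod_R(u, par[5 + k]), cen)
  } else if (kind == "universal") {
    Tr <- matrix_from_rotvec(par[4:6])
    th1 <- par[6 + 2 * (k - 1) + 1]; th2 <- par[6 + 2 * (k - 1) + 2]
    rt_fast(rod_R(Tr[, 1], th1) %*% rod_R(Tr[, 2], th2), cen)
  } else { # spherical
    rv <- par[3 + (3 * (k - 1) + 1):(3 * (k - 1) + 3)]
    rt_fast(matrix_from_rotvec(rv * pi / 180), cen)
  }
}

# organize posture clouds: list(ref = list(bone -> pts), obs = list(posture -> bone -> pts))
organize_clouds <- function(clouds, reference_posture = 1L) {
  if (!is.null(clouds$clouds)) clouds <- clouds$clouds
  postures <- sort(unique(vapply(clouds, `[[`, 0L, "posture")))
  if (length(postures) < 2) stop("need at least 2 postures")
  ref <- list(); obs <- list()
  for (cl in clouds) {
    if (nrow(cl$points) < 3) stop("posture cloud needs at least 3 points")
    if (!all(is.finite(cl$points))) stop("non-finite cloud coordinates")
    if (cl$posture == reference_posture) ref[[cl$bone]] <- cl$points
    else {
      key <- as.character(cl$posture)
      if (is.null(obs[[key]])) obs[[key]] <- list()
      obs[[key]][[cl$bone]] <- cl$points
    }
  }
  list(ref = ref, obs = obs, free_postures = setdiff(postures, reference_posture))
}

#' Fit skeletal motion to multi-posture point clouds
#'
#' Recovers joint centers, axes and per-posture rotation angles by
#' minimizing the summed registration residual of all moving bones across
#' postures. Transforms are parameterized directly on the joint-constraint
#' manifold (rotations about optimized centers and axes composed down the
#' chain), so the kind-specific constraint equations are satisfied exactly
#' by construction; [joint_constraint_residual()] is evaluated on the
#' result as a diagnostic. Multi-start local optimization: `n_starts`
#' random starts plus one informed start from per-bone closed-form
#' (Kabsch) registration. The best start's optimum is returned.
#'
#' @param clouds result of [make_posture_clouds()] or a plain list of
#'   `posture_cloud`s covering >= 2 postures (posture 1 = reference).
#' @param joints named list describing the chain, outer-joint first: each
#'   element `list(kind = <joint kind>, moves = <bone names moved>)`.
#'   Default: the two-bar wing with a revolute shoulder and universal
#'   wrist.
#' @param config [fit_config()].
#' @param extra_starts optional list of packed parameter vectors used as
#'   additional starts (used by [compare_joint_types()] for warm starting).
#' @return `fit_result`: per-joint center/axes/angles, per-bone-per-posture
#'   transforms, residual (mm, mean point distance), constraint
#'   diagnostics, and optimizer metadata.
#' @export
fit_skeleton_motion <- function(clouds,
                                joints = list(
                                  shoulder = list(kind = "revolute",
                                                  moves = c("humerus", "ulna", "metacarpus")),
                                  wrist = list(kind = "universal",
                                               moves = "metacarpus")),
                                config = fit_config(),
                                extra_starts = list()) {
  org <- organize_clouds(clouds)
  n_free <- length(org$free_postures)
  jn <- names(joints)
  # joints ordered by number of moved bones (root joint first)
  jn <- jn[order(-vapply(jn, function(n) length(joints[[n]]$moves), 0L))]
  npar <- vapply(jn, function(n) joint_par_count(joints[[n]]$kind, n_free), 0L)
  offs <- cumsum(c(0, npar))
  moving_bones <- unique(unlist(lapply(joints, `[[`, "moves")))
  moving_bones <- intersect(names(org$ref), moving_bones)

  bone_transforms <- function(par, k) {
    Ts <- lapply(seq_along(jn), function(i)
      joint_transform_from_par(joints[[jn[i]]]$kind,
                               par[(offs[i] + 1):offs[i + 1]], k))
    names(Ts) <- jn
    out <- list()
    for (b in moving_bones) {
      Tb <- NULL
      for (i in seq_along(jn)) if (b %in% joints[[jn[i]]]$moves)
        Tb <- if (is.null(Tb)) Ts[[jn[i]]] else compose_fast(Tb, Ts[[jn[i]]])
      out[[b]] <- if (is.null(Tb)) list(R = diag(3), t = c(0, 0, 0)) else Tb
    }
    out
  }

  # flat list of (ref, obs, posture k, bone) pairs for the hot loop
  pairs <- list()
  for (k in seq_len(n_free)) {
    okey <- as.character(org$free_postures[k])
    for (b in moving_bones) {
      B <- org$obs[[okey]][[b]]
      if (is.null(B)) next
      pairs[[length(pairs) + 1L]] <- list(A = org$ref[[b]], B = B, k = k, b = b)
    }
  }
  # the optimized objective IS the reported residual (mean point distance
  # averaged over bone/posture pairs), so the warm-start guarantee in
  # compare_joint_types carries over to the reported values; the tiny
  # epsilon keeps the gradient finite at exactly-zero distances
  objective <- function(par) {
    Ts <- lapply(seq_len(n_free), function(k) bone_transforms(par, k))
    tot <- 0
    for (pr in pairs) {
      T_ <- Ts[[pr$k]][[pr$b]]
      D <- pr$A %*% t(T_$R)
      D[, 1] <- D[, 1] + T_$t[1] - pr$B[, 1]
      D[, 2] <- D[, 2] + T_$t[2] - pr$B[, 2]
      D[, 3] <- D[, 3] + T_$t[3] - pr$B[, 3]
      tot <- tot + mean(sqrt(D[, 1]^2 + D[, 2]^2 + D[, 3]^2 + 1e-24))
    }
    tot / length(pairs)
  }

  starts <- c(list(informed_start(org, joints, jn, n_free)),
              extra_starts)
  with_seed(config$seed, {
    for (s in seq_len(config$n_starts)) {
      starts[[length(starts) + 1L]] <- random_start(org, joints, jn, n_free,
                                                    config$center_spread_mm)
    }
  })
  best <- NULL; meta <- list(n_starts = length(starts))
  perfect <- 1e-9    # mm: numerically exact fit, further starts cannot improve
  for (si in seq_along(starts)) {
    st <- starts[[si]]
    # candidate 1: the raw start (guarantees warm starts never regress)
    v0 <- objective(st)
    if (is.null(best) || v0 < best$value) best <- list(par = st, value = v0, start = si, iters = 0)
    if (best$value < perfect) break
    res <- try(stats::optim(st, objective, method = "BFGS",
                            control = list(maxit = config$max_iter,
                                           reltol = config$reltol)), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (res$value > perfect) {
      # polish with a finer finite-difference step
      res2 <- try(stats::optim(res$par, objective, method = "BFGS",
                               control = list(maxit = config$max_iter,
                                              reltol = config$reltol,
                                              ndeps = rep(1e-6, length(res$par)))),
                  silent = TRUE)
      if (!inherits(res2, "try-error") && res2$value < res$value) res <- res2
    }
    if (res$value < best$value)
      best <- list(par = st * 0 + res$par, value = res$value, start = si,
                   iters = res$counts[["function"]])
    if (best$value < perfect) break
  }
  if (is.null(best)) stop("optimizer failed for all starts")
  assemble_fit_result(best, org, joints, jn, offs, n_free, moving_bones,
                      bone_transforms, meta)
}

informed_start <- function(org, joints, jn, n_free) {
  par <- numeric(0)
  # closed-form per-bone transforms for each free posture
  kab <- lapply(seq_len(n_free), function(k) {
    okey <- as.character(org$free_postures[k])
    out <- list()
    for (b in names(org$ref)) {
      B <- org$obs[[okey]][[b]]
      if (!is.null(B) && nrow(B) == nrow(org$ref[[b]]))
        out[[b]] <- kabsch(org$ref[[b]], B)
    }
    out
  })
  for (i in seq_along(jn)) {
    j <- joints[[jn[i]]]
    bones_here <- j$moves
    deeper <- unlist(lapply(joints[seq_along(joints)][-match(jn[i], names(joints))],
                            function(x) if (all(x$moves %in% bones_here) &&
                                            length(x$moves) < length(bones_here)) x$moves))
    proximal <- setdiff(bones_here, deeper)
    bone <- proximal[1]
    # relative transform at this joint per posture (parent chain removed)
    rel <- lapply(seq_len(n_free), function(k) {
      Tb <- kab[[k]][[bone]]
      if (is.null(Tb)) return(rt_identity())
      # divide out transforms of joints closer to the root that move this bone
      for (ii in seq_along(jn)) {
        if (ii >= i) break
        if (bone %in% joints[[jn[ii]]]$moves) {
          pb <- setdiff(joints[[jn[ii]]]$moves,
                        unlist(lapply(joints[-match(jn[ii], names(joints))], `[[`, "moves")))
          Tp <- kab[[k]][[pb[1]]]
          if (!is.null(Tp)) Tb <- rt_compose(rt_inverse(Tp), Tb)
        }
      }
      Tb
    })
    # center: least-squares solve of (I - R_k) c = t_k over postures
    Amat <- do.call(rbind, lapply(rel, function(T_) diag(3) - T_$R))
    bvec <- unlist(lapply(rel, function(T_) T_$t))
    cen <- tryCatch({
      sv <- svd(Amat)
      dpos <- sv$d > 1e-6 * max(sv$d, 1e-12)
      as.numeric(sv$v[, dpos, drop = FALSE] %*%
                   ((t(sv$u[, dpos, drop = FALSE]) %*% bvec) / sv$d[dpos]))
    }, error = function(e) colMeans(org$ref[[bone]]))
    rotvecs <- lapply(rel, function(T_) rotvec_from_matrix(T_$R))
    mags <- vapply(rotvecs, function(v) sqrt(sum(v^2)), 0)
    main_axis <- if (max(mags) > 1e-9) normalize(rotvecs[[which.max(mags)]]) else c(0, 0, 1)
    par <- c(par, switch(j$kind,
      revolute = {
        phi <- acos(min(1, max(-1, main_axis[3]))); psi <- atan2(main_axis[2], main_axis[1])
        angs <- vapply(seq_len(n_free), function(k)
          sum(rotvecs[[k]] * main_axis) * 180 / pi, 0)
        c(cen, phi, psi, angs)
      },
      universal = {
        dec <- universal_axes_from_rotations(lapply(rel, `[[`, "R"), main_axis)
        c(cen, rotvec_from_matrix(dec$triad), as.numeric(t(dec$angles_deg)))
      },
      spherical = c(cen, unlist(lapply(rotvecs, function(v) v * 180 / pi))),
      numeric(0)))
  }
  par
}

# estimate the fixed axis pair (a1, a2) of a universal joint from relative
# rotations R_p = R(a1, th1p) R(a2, th2p): for all p, a1' R_p a2 = 0 and
# a1'a2 = 0. Solved by alternating smallest-singular-vector updates, then
# angles by two-axis Euler decomposition in the (a1, a2, a1 x a2) basis.
universal_axes_from_rotations <- function(Rs, a1_init) {
  alternate <- function(a1) {
    a1 <- normalize(a1)
    a2 <- NULL
    for (it in 1:30) {
      A2 <- rbind(do.call(rbind, lapply(Rs, function(R) as.numeric(t(R) %*% a1))), a1)
      a2_new <- svd(A2)$v[, 3]
      if (!is.null(a2) && sum(a2_new * a2) < 0) a2_new <- -a2_new
      a2 <- a2_new
      A1 <- rbind(do.call(rbind, lapply(Rs, function(R) as.numeric(R %*% a2))), a2)
      a1_new <- svd(A1)$v[, 3]
      if (sum(a1_new * a1) < 0) a1_new <- -a1_new
      a1 <- a1_new
    }
    # score by how well the two-axis decomposition reconstructs the
    # rotations (the bilinear constraint alone admits spurious pairs)
    a2o <- normalize(a2 - sum(a2 * a1) * a1)
    A <- cbind(a1, a2o, cross3(a1, a2o))
    err <- sum(vapply(Rs, function(R) {
      Rp <- t(A) %*% R %*% A
      th2 <- atan2(Rp[1, 3], Rp[1, 1]); th1 <- atan2(Rp[3, 2], Rp[2, 2])
      sum((rod_R(c(1, 0, 0), th1 * 180 / pi) %*%
             rod_R(c(0, 1, 0), th2 * 180 / pi) - Rp)^2)
    }, 0))
    list(a1 = a1, a2 = a2, err = err)
  }
  # the bilinear system has spurious stationary pairs and the alternation
  # basin is narrow: seed it densely over a deterministic sphere grid
  # (Fibonacci spiral) plus the rotation axes, and keep the best
  nf <- 120
  golden <- pi * (3 - sqrt(5))
  fib <- lapply(seq_len(nf), function(i) {
    z <- 1 - 2 * (i - 0.5) / nf
    r <- sqrt(max(0, 1 - z^2)); th <- golden * (i - 1)
    c(r * cos(th), r * sin(th), z)
  })
  inits <- c(list(a1_init),
             lapply(Rs, function(R) {
               rv <- rotvec_from_matrix(R)
               if (sqrt(sum(rv^2)) > 1e-9) normalize(rv) else c(1, 0, 0)
             }),
             fib)
  cands <- lapply(inits, alternate)
  best <- cands[[which.min(vapply(cands, `[[`, 0, "err"))]]
  a1 <- best$a1; a2 <- best$a2
  a2 <- normalize(a2 - sum(a2 * a1) * a1)
  a3 <- cross3(a1, a2)
  A <- cbind(a1, a2, a3)
  angles <- t(vapply(Rs, function(R) {
    Rp <- t(A) %*% R %*% A     # R(e1, th1) R(e2, th2) in this basis
    th2 <- atan2(Rp[1, 3], Rp[1, 1])
    th1 <- atan2(Rp[3, 2], Rp[2, 2])
    c(th1, th2) * 180 / pi
  }, c(0, 0)))
  list(triad = A, angles_deg = angles)
}

random_start <- function(org, joints, jn, n_free, spread) {
  par <- numeric(0)
  for (nm in jn) {
    j <- joints[[nm]]
    bone <- j$moves[length(j$moves)]
    cen <- colMeans(org$ref[[bone]]) + stats::runif(3, -spread, spread)
    par <- c(par, switch(j$kind,
      revolute = c(cen, acos(stats::runif(1, -1, 1)), stats::runif(1, -pi, pi),
                   stats::runif(n_free, -45, 45)),
      universal = c(cen, stats::rnorm(3, 0, 1),
                    stats::runif(2 * n_free, -45, 45)),
      spherical = c(cen, stats::runif(3 * n_free, -45, 45)),
      numeric(0)))
  }
  par
}

assemble_fit_result <- function(best, org, joints, jn, offs, n_free,
                                moving_bones, bone_transforms, meta) {
  par <- best$par
  joints_out <- list()
  for (i in seq_along(jn)) {
    j <- joints[[jn[i]]]
    p <- par[(offs[i] + 1):offs[i + 1]]
    ji <- list(kind = j$kind)
    if (j$kind != "fixed") ji$center <- p[1:3]
    if (j$kind == "revolute") {
      u <- axis_from_sph(p[4], p[5]); angs <- p[-(1:5)]
      # sign convention: axis z-component (then y, then x) non-negative
      flip <- (u[3] < 0) || (u[3] == 0 && (u[2] < 0 || (u[2] == 0 && u[1] < 0)))
      if (flip) { u <- -u; angs <- -angs }
      ji$axis <- u
      ji$angles_deg <- matrix(wrap_angle_deg(angs), ncol = 1,
                              dimnames = list(NULL, "q1"))
    } else if (j$kind == "universal") {
      Tr <- matrix_from_rotvec(p[4:6])
      ji$axes <- Tr
      ji$angles_deg <- matrix(wrap_angle_deg(p[-(1:6)]), ncol = 2, byrow = TRUE,
                              dimnames = list(NULL, c("q1", "q2")))
    } else if (j$kind == "spherical") {
      ji$angles_deg <- matrix(p[-(1:3)], ncol = 3, byrow = TRUE,
                              dimnames = list(NULL, c("rx", "ry", "rz")))
    }
    joints_out[[jn[i]]] <- ji
  }
  transforms <- lapply(seq_len(n_free), function(k)
    lapply(bone_transforms(par, k), function(T_)
      rigid_transform(T_$R, T_$t, check = FALSE)))
  names(transforms) <- paste0("posture", org$free_postures)
  # per-bone mean-distance residuals + constraint diagnostics
  per_bone <- list(); tot <- 0; n <- 0L
  for (k in seq_len(n_free)) {
    okey <- as.character(org$free_postures[k])
    for (b in moving_bones) {
      B <- org$obs[[okey]][[b]]
      if (is.null(B)) next
      r <- cloud_residual(org$ref[[b]], B, transforms[[k]][[b]])
      per_bone[[paste(b, okey, sep = ".")]] <- r
      tot <- tot + r; n <- n + 1L
    }
  }
  structure(list(joints = joints_out, transforms = transforms,
                 residual_mm = tot / n,
                 per_bone_residual_mm = unlist(per_bone),
                 objective_mm = best$value,
                 optimizer = list(n_starts = meta$n_starts,
                                  best_start = best$start,
                                  iterations = best$iters),
                 par = par),
            class = "fit_result")
}

#' Wrap angles to (-180, 180] degrees
#' @param a angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle_deg <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> residual %.4g mm (best start %d)\n",
              x$residual_mm, x$optimizer$best_start))
  for (nm in names(x$joints)) {
    j <- x$joints[[nm]]
    cat(sprintf("  %s: %s", nm, j$kind))
    if (!is.null(j$center)) cat(sprintf("  center (%.2f, %.2f, %.2f)",
                                        j$center[1], j$center[2], j$center[3]))
    cat("\n")
  }
  invisible(x)
}

# --- joint-type comparison ---------------------------------------------

kind_rank <- c(revolute = 1L, universal = 2L, spherical = 3L)

# embed the packed parameters of a fitted joint into a higher-dof kind
embed_joint_par <- function(from_kind, to_kind, p, n_free) {
  if (from_kind == to_kind) return(p)
  if (from_kind == "revolute" && to_kind == "universal") {
    u <- axis_from_sph(p[4], p[5])
    Tr <- triad_from_z(u)[, c(3, 1, 2)]
    angs <- as.numeric(rbind(p[-(1:5)], 0))
    return(c(p[1:3], rotvec_from_matrix(Tr), angs))
  }
  if (from_kind == "universal" && to_kind == "spherical") {
    Tr <- matrix_from_rotvec(p[4:6])
    th <- matrix(p[-(1:6)], ncol = 2, byrow = TRUE)
    rv <- t(vapply(seq_len(n_free), function(k) {
      R <- rotation_about_axis(Tr[, 1], th[k, 1])$R %*%
        rotation_about_axis(Tr[, 2], th[k, 2])$R
      rotvec_from_matrix(R) * 180 / pi
    }, numeric(3)))
    return(c(p[1:3], as.numeric(t(rv))))
  }
  if (from_kind == "revolute" && to_kind == "spherical") {
    return(embed_joint_par("universal", "spherical",
                           embed_joint_par("revolute", "universal", p, n_free),
                           n_free))
  }
  stop("no embedding from ", from_kind, " to ", to_kind)
}

# split a packed parameter vector into per-joint pieces
split_par <- function(par, kinds, n_free) {
  npar <- vapply(kinds, joint_par_count, 0L, n_free = n_free)
  offs <- cumsum(c(0, npar))
  lapply(seq_along(kinds), function(i) par[(offs[i] + 1):offs[i + 1]])
}

#' Compare candidate joint-type pairs by fit residual
#'
#' Fits the skeletal motion for every candidate (shoulder kind, wrist kind)
#' pair and tabulates the registration residuals. Fits are warm-started
#' from the optima of lower-dof pairs (a revolute optimum embeds exactly
#' into the universal parameterization, and universal into spherical), so
#' on the same data the residual is non-increasing as either joint's dof
#' count grows.
#'
#' @param clouds as in [fit_skeleton_motion()].
#' @param candidates data.frame with columns `shoulder` and `wrist`
#'   (default: all pairs of spherical/universal/revolute).
#' @param config [fit_config()].
#' @param moves named list giving the bones moved by each joint (defaults
#'   to the two-bar wing chain).
#' @return list with `table` (data.frame shoulder, wrist, residual_mm) and
#'   `fits` (named list of `fit_result`s, names "shoulder-wrist").
#' @export
compare_joint_types <- function(clouds,
                                candidates = expand.grid(
                                  shoulder = c("revolute", "universal", "spherical"),
                                  wrist = c("revolute", "universal", "spherical"),
                                  stringsAsFactors = FALSE),
                                config = fit_config(),
                                moves = list(shoulder = c("humerus", "ulna", "metacarpus"),
                                             wrist = "metacarpus")) {
  if (nrow(candidates) == 0) stop("candidate list is empty")
  org <- organize_clouds(clouds)
  n_free <- length(org$free_postures)
  ord <- order(kind_rank[candidates$shoulder] + kind_rank[candidates$wrist])
  candidates <- candidates[ord, , drop = FALSE]
  fits <- list(); rows <- list()
  for (i in seq_len(nrow(candidates))) {
    sk <- candidates$shoulder[i]; wk <- candidates$wrist[i]
    key <- paste(sk, wk, sep = "-")
    warm <- list()
    for (k2 in names(fits)) {
      parts <- strsplit(k2, "-")[[1]]
      if (kind_rank[parts[1]] <= kind_rank[sk] && kind_rank[parts[2]] <= kind_rank[wk]) {
        prev <- fits[[k2]]
        pieces <- split_par(prev$par, c(parts[1], parts[2]), n_free)
        warm[[length(warm) + 1L]] <- c(
          embed_joint_par(parts[1], sk, pieces[[1]], n_free),
          embed_joint_par(parts[2], wk, pieces[[2]], n_free))
      }
    }
    res <- tryCatch(
      fit_skeleton_motion(clouds,
                          joints = list(shoulder = list(kind = sk, moves = moves$shoulder),
                                        wrist = list(kind = wk, moves = moves$wrist)),
                          config = config, extra_starts = warm),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[key]] <- data.frame(shoulder = sk, wrist = wk, residual_mm = NA_real_,
                                error = conditionMessage(res))
    } else {
      fits[[key]] <- res
      rows[[key]] <- data.frame(shoulder = sk, wrist = wk,
                                residual_mm = res$residual_mm, error = NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
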