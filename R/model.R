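#' Bone of the wing skeleton
#'
#' A rigid body of the two-bar wing chain. Positions are millimetres in the
#' global (reference posture) frame. The proximal frame sits at the joint
#' connecting the bone to its parent; the distal frame at the far end.
#'
#' @param name bone label.
#' @param index integer bone index (ground = 0, humerus = 1, ulna = 2,
#'   metacarpus = 3).
#' @param mass_g bone mass in grams (> 0).
#' @param proximal,distal frame lists with elements `origin` (3-vector, mm)
#'   and `axes` (3x3 orthonormal triad, columns are the frame axes).
#' @param radius_mm capsule radius used for the synthetic bone surface.
#' @param surface optional reference point cloud (Nx3, mm).
#' @return object of class `wing_bone`.
#' @export
wing_bone <- function(name, index, mass_g, proximal, distal,
                      radius_mm = 2.5, surface = NULL) {
  stopifnot(is.character(name), mass_g > 0)
  frame_check <- function(f) {
    stopifnot(length(f$origin) == 3, is_rotation_matrix(f$axes, tol = 1e-6))
    f
  }
  proximal <- frame_check(proximal); distal <- frame_check(distal)
  structure(list(name = name, index = as.integer(index), mass_g = mass_g,
                 proximal = proximal, distal = distal,
                 radius_mm = radius_mm, surface = surface),
            class = "wing_bone")
}

bone_frame <- function(origin, axes = diag(3)) list(origin = as.numeric(origin), axes = axes)

#' Joint specification
#'
#' Connects a parent bone to a child bone. `kind` fixes the number of
#' rotational degrees of freedom: fixed = 0, revolute = 1, universal = 2,
#' spherical = 3, spiral = 1 (rotation with coupled translation along the
#' axis). Degree-of-freedom `k` rotates about column `k` of `axes`, applied
#' in the order of `dof_labels`.
#'
#' @param name joint label.
#' @param kind one of "fixed", "revolute", "universal", "spherical", "spiral".
#' @param parent,child bone labels.
#' @param center joint center, global frame (mm).
#' @param axes 3x3 orthonormal triad; column k is the axis of dof k.
#' @param dof_labels character vector naming the angles, length = dof count.
#' @param pitch_mm_per_rev translation per revolution for spiral joints (mm).
#' @return object of class `joint_spec`.
#' @export
joint_spec <- function(name, kind, parent, child, center, axes = diag(3),
                       dof_labels = character(), pitch_mm_per_rev = 0) {
  kind <- match.arg(kind, c("fixed", "revolute", "universal", "spherical", "spiral"))
  ndof <- joint_dof_count(kind)
  if (length(dof_labels) == 0 && ndof > 0)
    dof_labels <- paste0(name, "_q", seq_len(ndof))
  if (length(dof_labels) != ndof)
    stop(sprintf("joint '%s' (%s) needs %d dof labels, got %d",
                 name, kind, ndof, length(dof_labels)))
  if (!is_rotation_matrix(axes, tol = 1e-6)) stop("joint axes must be orthonormal")
  dimnames(axes) <- NULL
  structure(list(name = name, kind = kind, parent = parent, child = child,
                 center = as.numeric(center), axes = axes,
                 dof_labels = dof_labels, pitch_mm_per_rev = pitch_mm_per_rev),
            class = "joint_spec")
}

#' Degrees of freedom of a joint kind
#' @param kind joint kind string.
#' @return integer dof count.
#' @export
joint_dof_count <- function(kind) {
  switch(kind, fixed = 0L, revolute = 1L, universal = 2L,
         spherical = 3L, spiral = 1L,
         stop("unknown joint kind: ", kind))
}

#' Wing model
#'
#' The two-bar musculoskeletal wing: an ordered set of bones forming a
#' kinematic tree rooted at the ground body (fused scapula + coracoid), the
#' joints connecting them, and the muscle-tendon actuators.
#'
#' @param bones list of `wing_bone`, first one is the ground body.
#' @param joints list of `joint_spec`.
#' @param muscles list of muscle definitions (see [muscle_path()]).
#' @param gravity gravity vector, m s^-2 (default -z).
#' @param joint_damping generalized viscous damping per dof, N m s rad^-1.
#' @return object of class `wing_model`.
#' @export
wing_model <- function(bones, joints, muscles = list(),
                       gravity = c(0, 0, -9.81), joint_damping = 0) {
  names(bones) <- vapply(bones, `[[`, "", "name")
  names(joints) <- vapply(joints, `[[`, "", "name")
  model <- structure(list(bones = bones, joints = joints, muscles = muscles,
                          gravity = as.numeric(gravity),
                          joint_damping = joint_damping),
                     class = "wing_model")
  validate_wing_model(model)
  model
}

#' Validate a wing model
#'
#' Checks that joint parent/child labels resolve to bones, that the chain is
#' a tree rooted at the ground body, and that per-bone invariants hold.
#'
#' @param model `wing_model`.
#' @return the model, invisibly; stops on violation.
#' @export
validate_wing_model <- function(model) {
  bn <- names(model$bones)
  for (j in model$joints) {
    if (!(j$parent %in% bn) || !(j$child %in% bn))
      stop(sprintf("joint '%s': parent/child must name bones", j$name))
  }
  children <- vapply(model$joints, `[[`, "", "child")
  if (anyDuplicated(children)) stop("each bone may be the child of one joint only")
  ground <- bn[1]
  if (ground %in% children) stop("ground bone cannot be a joint child")
  # every non-ground bone reachable from ground
  parent_of <- stats::setNames(vapply(model$joints, `[[`, "", "parent"), children)
  for (b in setdiff(bn, ground)) {
    seen <- character(); cur <- b
    while (cur != ground) {
      if (!(cur %in% names(parent_of)) || cur %in% seen)
        stop(sprintf("bone '%s' is not connected to the ground body", b))
      seen <- c(seen, cur); cur <- parent_of[[cur]]
    }
  }
  invisible(model)
}

#' Ordered degrees of freedom of a model
#'
#' @param model `wing_model`.
#' @return data.frame with columns joint, label, axis (list of 3-vectors),
#'   center (list), in chain order.
#' @export
model_dofs <- function(model) {
  rows <- list()
  for (j in model$joints) {
    nd <- joint_dof_count(j$kind)
    if (nd == 0) next
    for (k in seq_len(nd)) {
      rows[[length(rows) + 1L]] <- list(joint = j$name, label = j$dof_labels[k],
                                        axis = j$axes[, k], center = j$center)
    }
  }
  labels <- vapply(rows, `[[`, "", "label")
  structure(list(joint = vapply(rows, `[[`, "", "joint"), label = labels,
                 axis = lapply(rows, `[[`, "axis"),
                 center = lapply(rows, `[[`, "center")),
            class = "data.frame", row.names = labels)
}

# joints sorted so parents come before children (ground-out order)
ordered_joints <- function(model) {
  bn <- names(model$bones)
  depth <- stats::setNames(rep(NA_integer_, length(bn)), bn)
  depth[bn[1]] <- 0L
  js <- model$joints
  repeat {
    progressed <- FALSE
    for (j in js) {
      if (is.na(depth[j$child]) && !is.na(depth[j$parent])) {
        depth[j$child] <- depth[j$parent] + 1L; progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  js[order(vapply(js, function(j) depth[j$child], 0L))]
}

#' Forward kinematics
#'
#' Computes, for a set of joint angles, the rigid transform carrying each
#' bone from the reference posture to the posed posture, composed down the
#' kinematic chain. The ground bone transform is always the identity. Joint
#' rotations are taken about the joint's reference-posture center and axes
#' (product-of-exponentials with the reference configuration), dof order as
#' in `dof_labels`.
#'
#' @param model `wing_model`.
#' @param angles named list: one numeric vector of angles (degrees) per
#'   joint with dofs, names matching joint names; or a single named numeric
#'   vector keyed by dof label.
#' @return named list of `rigid_transform`, one per bone.
#' @export
forward_kinematics <- function(model, angles = list()) {
  # accept flat named vector keyed by dof label
  if (is.numeric(angles)) {
    flat <- angles; angles <- list()
    extra <- setdiff(names(flat), unlist(lapply(model$joints, `[[`, "dof_labels")))
    if (length(extra)) stop("unknown dof label(s): ", paste(extra, collapse = ", "))
    for (j in model$joints) {
      nd <- joint_dof_count(j$kind)
      if (nd == 0) next
      if (!all(j$dof_labels %in% names(flat)))
        stop(sprintf("missing dof value(s) for joint '%s'", j$name))
      angles[[j$name]] <- as.numeric(flat[j$dof_labels])
    }
  }
  transforms <- stats::setNames(vector("list", length(model$bones)), names(model$bones))
  transforms[[1]] <- rt_identity()
  for (j in ordered_joints(model)) {
    nd <- joint_dof_count(j$kind)
    q <- angles[[j$name]]
    if (nd == 0) {
      if (!is.null(q) && length(q) > 0 && any(q != 0))
        stop(sprintf("angles supplied for fixed joint '%s'", j$name))
      Tj <- rt_identity()
    } else {
      if (is.null(q)) stop(sprintf("missing dof value(s) for joint '%s'", j$name))
      if (length(q) != nd)
        stop(sprintf("joint '%s' needs %d angle(s), got %d", j$name, nd, length(q)))
      Tj <- rt_identity()
      for (k in seq_len(nd)) {
        Tj <- rt_compose(Tj, rotation_about_axis(j$axes[, k], q[k], j$center))
      }
      if (j$kind == "spiral") {
        slide <- j$pitch_mm_per_rev * q[1] / 360
        ax <- normalize(j$axes[, 1])
        Tj <- rt_compose(rigid_transform(diag(3), ax * slide, check = FALSE), Tj)
      }
    }
    transforms[[j$child]] <- rt_compose(transforms[[j$parent]], Tj)
  }
  transforms
}

#' Bone length (proximal to distal frame origin distance)
#' @param bone `wing_bone`.
#' @return length in mm.
#' @export
bone_length <- function(bone) {
  sqrt(sum((bone$distal$origin - bone$proximal$origin)^2))
}

#' @export
print.wing_model <- function(x, ...) {
  cat(sprintf("<wing_model> %d bones, %d joints, %d muscles\n",
              length(x$bones), length(x$joints), length(x$muscles)))
  for (j in x$joints)
    cat(sprintf("  joint %-10s %-9s %s -> %s  dofs: %s\n", j$name, j$kind,
                j$parent, j$child,
                if (length(j$dof_labels)) paste(j$dof_labels, collapse = ", ") else "-"))
  invisible(x)
}
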