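#' Write a wing model to JSON
#'
#' Serializes bones (frames, masses, capsule radii), joints, wrap objects
#' and muscles (paths, Hill parameters) to a single JSON file. Bone
#' surface clouds, when present, are written as ascii PLY files named
#' `<model>_<bone>.ply` next to the JSON and referenced from it.
#'
#' @param model `wing_model`.
#' @param path output JSON path.
#' @param write_surfaces write referenced PLY surface clouds (default TRUE).
#' @return `path`, invisibly.
#' @export
write_wing_model <- function(model, path, write_surfaces = TRUE) {
  stem <- sub("\\.json$", "", basename(path))
  dir <- dirname(path)
  bones <- lapply(model$bones, function(b) {
    surf_ref <- NULL
    if (write_surfaces && !is.null(b$surface)) {
      surf_ref <- paste0(stem, "_", b$name, ".ply")
      write_point_cloud(b$surface, file.path(dir, surf_ref))
    }
    list(name = b$name, index = b$index, mass_g = b$mass_g,
         proximal = list(origin = b$proximal$origin, axes = b$proximal$axes),
         distal = list(origin = b$distal$origin, axes = b$distal$axes),
         radius_mm = b$radius_mm, surface_ply = surf_ref)
  })
  joints <- lapply(model$joints, function(j)
    list(name = j$name, kind = j$kind, parent = j$parent, child = j$child,
         center = j$center, axes = j$axes, dof_labels = j$dof_labels,
         pitch_mm_per_rev = j$pitch_mm_per_rev))
  muscles <- lapply(model$muscles, function(m)
    list(name = m$name,
         points = lapply(m$path$points, function(p)
           list(bone = p$bone, pos = p$pos)),
         wraps = lapply(m$path$wraps, function(w)
           list(shape = w$shape, bone = w$bone, center = w$center,
                radii = w$radii, axis = w$axis)),
         params = unclass(m$params)))
  jsonlite::write_json(
    list(format = "wingflap-model", version = 1,
         units = list(length = "mm", mass = "g", angle = "deg"),
         gravity_m_s2 = model$gravity, joint_damping = model$joint_damping,
         bones = bones, joints = joints, muscles = muscles),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a wing model from JSON
#'
#' @param path JSON file written by [write_wing_model()].
#' @return `wing_model`.
#' @export
read_wing_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                           simplifyDataFrame = FALSE)
  if (is.null(x$format) || x$format != "wingflap-model")
    stop("not a wingflap model file: ", path)
  dir <- dirname(path)
  bones <- lapply(x$bones, function(b) {
    surf <- NULL
    if (!is.null(b$surface_ply) && file.exists(file.path(dir, b$surface_ply)))
      surf <- read_point_cloud(file.path(dir, b$surface_ply))
    wing_bone(b$name, b$index, b$mass_g,
              bone_frame(b$proximal$origin, as.matrix(b$proximal$axes)),
              bone_frame(b$distal$origin, as.matrix(b$distal$axes)),
              b$radius_mm, surf)
  })
  joints <- lapply(x$joints, function(j)
    joint_spec(j$name, j$kind, j$parent, j$child, j$center,
               as.matrix(j$axes), unlist(j$dof_labels),
               if (is.null(j$pitch_mm_per_rev)) 0 else j$pitch_mm_per_rev))
  muscles <- lapply(x$muscles, function(m) {
    wraps <- lapply(m$wraps, function(w)
      wrap_object(w$shape, w$bone, w$center, w$radii, w$axis))
    pts <- lapply(m$points, function(p) list(bone = p$bone, pos = p$pos))
    wing_muscle(muscle_path(m$name, pts, wraps),
                do.call(muscle_params, m$params[c("l_om", "alpha_deg", "L_ts",
                                                  "F_max", "tau_act", "tau_deact")]))
  })
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  wing_model(bones, joints, muscles, gravity = x$gravity_m_s2,
             joint_damping = if (is.null(x$joint_damping)) 0 else x$joint_damping)
}
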