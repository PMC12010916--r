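#' Rigid transform
#'
#' A proper rigid-body transform in 3D: a rotation (3x3 proper-orthonormal
#' matrix) followed by a translation (3-vector, mm). Applied to a point p as
#' p' = R p + t.
#'
#' @param rotation 3x3 proper-orthonormal matrix.
#' @param translation numeric 3-vector (mm).
#' @param check validate orthonormality (default TRUE).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            check = TRUE) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rigid_transform needs a 3x3 rotation and a length-3 translation")
  if (check && !is_rotation_matrix(rotation))
    stop("rotation must be proper-orthonormal (R'R = I, det = +1)")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' Test for a proper rotation matrix
#'
#' @param R matrix to test.
#' @param tol orthonormality tolerance (default 1e-9).
#' @return logical
#' @export
is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n"); print(signif(x$R, 6))
  cat("translation (mm):", signif(x$t, 6), "\n")
  invisible(x)
}

#' Identity transform
#' @return `rigid_transform` identity.
#' @export
rt_identity <- function() rigid_transform(check = FALSE)

#' Compose rigid transforms
#'
#' `rt_compose(a, b)` is the transform "first b, then a":
#' (a o b)(p) = a(b(p)).
#'
#' @param a,b `rigid_transform` objects.
#' @return `rigid_transform`
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t, check = FALSE)
}

#' Invert a rigid transform
#' @param a `rigid_transform`.
#' @return `rigid_transform` with a o a^-1 = identity.
#' @export
rt_inverse <- function(a) {
  rigid_transform(t(a$R), as.numeric(-t(a$R) %*% a$t), check = FALSE)
}

#' Apply a rigid transform to points
#'
#' Maps each point p to R p + t.
#'
#' @param transform `rigid_transform`.
#' @param points numeric Nx3 matrix or length-3 vector (mm).
#' @return transformed points, same shape as input.
#' @export
apply_transform <- function(transform, points) {
  if (!inherits(transform, "rigid_transform"))
    stop("transform must be a rigid_transform")
  if (!is_rotation_matrix(transform$R))
    stop("rotation must be proper-orthonormal (R'R = I, det = +1)")
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, ncol = 3) else as.matrix(points)
  if (ncol(pts) != 3L) stop("points must be Nx3")
  if (!all(is.finite(pts))) stop("points must be finite")
  out <- pts %*% t(transform$R)
  out <- sweep(out, 2, transform$t, "+")
  dimnames(out) <- dimnames(pts)
  if (vec) as.numeric(out) else out
}

#' Rotation about an axis through a point
#'
#' Builds the rigid transform rotating by `angle_deg` degrees about the axis
#' `axis` passing through `center` (Rodrigues formula).
#'
#' @param axis direction 3-vector (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @param center point on the axis (mm), default origin.
#' @return `rigid_transform`
#' @export
rotation_about_axis <- function(axis, angle_deg, center = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, as.numeric(center - R %*% center), check = FALSE)
}

#' Rotation angle of a rigid transform
#'
#' The magnitude of the axis-angle representation of the rotation part, in
#' degrees (range 0..180).
#'
#' @param transform `rigid_transform` or 3x3 rotation matrix.
#' @return angle in degrees.
#' @export
rotation_angle <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$R else transform
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

# Unit vector helper
normalize <- function(v) v / sqrt(sum(v^2))

# Build an orthonormal triad whose 3rd column is z (deterministic completion)
triad_from_z <- function(z) {
  z <- normalize(z)
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- normalize(ref - sum(ref * z) * z)
  y <- cross3(z, x)
  cbind(x, y, z)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
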