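# shared fixtures, built once per test run
.fixtures <- new.env()

small_wing <- function() {
  if (is.null(.fixtures$wing))
    .fixtures$wing <- make_synthetic_wing(synth_config(points_per_bone = 60))
  .fixtures$wing
}

default_motion <- function() {
  if (is.null(.fixtures$motion)) .fixtures$motion <- make_default_motion()
  .fixtures$motion
}

# single-revolute test model: a rod on a hinge at the origin, flap about x
hinge_rod_model <- function(length_mm = 100, mass_g = 20, muscles = list()) {
  bones <- list(
    wing_bone("ground", 0L, 10, bone_frame(c(0, -30, 0)), bone_frame(c(0, 0, 0)), 3),
    wing_bone("rod", 1L, mass_g, bone_frame(c(0, 0, 0)),
              bone_frame(c(0, length_mm, 0)), 2))
  joints <- list(joint_spec("hinge", "revolute", "ground", "rod", c(0, 0, 0),
                            axes = diag(3), dof_labels = "swing"))
  wing_model(bones, joints, muscles, gravity = c(0, 0, 0))
}

random_rigid_transform <- function() {
  v <- stats::rnorm(3)
  rt_compose(rotation_about_axis(v / sqrt(sum(v^2)), stats::runif(1, -170, 170)),
             rigid_transform(diag(3), stats::rnorm(3, 0, 20), check = FALSE))
}

expect_equal_tol <- function(a, b, tol) expect_lt(max(abs(a - b)), tol)

# named dof-angle vector of a motion at a cycle fraction
flatten_pose <- function(model, motion, fraction) {
  ang <- evaluate_motion(motion, fraction * motion$period_s)$angles
  stats::setNames(as.numeric(ang), colnames(ang))
}
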