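test_that("cloud residual: trivial and oracle cases", {
  set.seed(2)
  A <- matrix(rnorm(60, 0, 10), 20, 3)
  expect_equal(cloud_residual(A, A, rt_identity()), 0)
  B <- sweep(A, 2, c(5, 0, 0), "+")
  expect_equal(cloud_residual(A, B, rt_identity()), 5)
  tr <- random_rigid_transform()
  C <- matrix(rnorm(60, 0, 10), 20, 3)
  # direct per-point loop oracle
  TA <- t(apply(A, 1, function(p) as.numeric(tr$R %*% p) + tr$t))
  oracle <- mean(sapply(1:20, function(i) sqrt(sum((TA[i, ] - C[i, ])^2))))
  expect_equal(cloud_residual(A, C, tr), oracle, tolerance = 1e-12)
  expect_error(cloud_residual(A, C[1:5, ], tr), "equal size")
})

test_that("joint constraint residuals vanish exactly on constraint-consistent
           motion and detect violations", {
  geom <- list(point = c(2, 1, 0), axes = diag(3))
  expect_lt(max(abs(joint_constraint_residual("fixed", rt_identity(),
                                              rt_identity(), geom))), 1e-12)
  # pure rotation about the shared z axis through the attachment point
  rot <- rotation_about_axis(c(0, 0, 1), 40, geom$point)
  r_rev <- joint_constraint_residual("revolute", rt_identity(), rot, geom)
  expect_lt(max(abs(r_rev)), 1e-12)
  # the same motion violates a fixed joint: rotational residual equals the
  # quaternion/axis-angle oracle (40 deg about z)
  r_fix <- joint_constraint_residual("fixed", rt_identity(), rot, geom)
  expect_lt(max(abs(r_fix[c("tx", "ty", "tz")])), 1e-12)
  expect_equal(as.numeric(r_fix[c("rx", "ry", "rz")]),
               c(0, 0, 40 * pi / 180), tolerance = 1e-9)
  # universal tolerates a second rotation about the moving x axis
  rot2 <- rt_compose(rotation_about_axis(c(1, 0, 0), 25, geom$point), rot)
  expect_lt(max(abs(joint_constraint_residual("universal", rt_identity(),
                                              rot2, geom))), 1e-12)
  expect_gt(max(abs(joint_constraint_residual("revolute", rt_identity(),
                                              rot2, geom))), 0.1)
  expect_error(joint_constraint_residual("hinge", rt_identity(), rot, geom))
})

test_that("spiral constraint couples translation to rotation", {
  geom <- list(point = c(0, 0, 0), axes = diag(3), pitch_mm_per_rev = 10)
  rot <- rotation_about_axis(c(0, 0, 1), 90)
  slide <- rigid_transform(diag(3), c(0, 0, 2.5))
  ok <- joint_constraint_residual("spiral", rt_identity(),
                                  rt_compose(slide, rot), geom)
  expect_lt(max(abs(ok)), 1e-12)
  bad <- joint_constraint_residual("spiral", rt_identity(), rot, geom)
  expect_equal(as.numeric(bad["coupling"]), -2.5, tolerance = 1e-9)
})

# orthonormal triad with given z axis (test-local helper mirroring the
# package's deterministic completion)
triad_from_z_export <- function(z) {
  z <- z / sqrt(sum(z^2))
  ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- ref - sum(ref * z) * z; x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

make_fit_clouds <- function(noise = 0, seed = 2, points = 60) {
  model <- make_synthetic_wing(synth_config(points_per_bone = points))
  posts <- c(default_postures(),
             list(folded = list(shoulder = 10, wrist = c(5, -40))))
  list(model = model,
       pc = make_posture_clouds(model, posts, noise_sigma = noise, seed = seed))
}

test_that("noiseless recovery: angles within 0.1 deg, centers within 0.1 mm,
           residual at the exact-model limit", {
  fx <- make_fit_clouds()
  fit <- fit_skeleton_motion(fx$pc, config = fit_config(n_starts = 3, seed = 4))
  expect_lt(fit$residual_mm, 1e-6)
  sh <- fit$joints$shoulder
  expect_lt(max(abs(sh$angles_deg[, 1] - c(30, -30, 10))), 0.1)
  # revolute center is identifiable up to sliding along the axis
  S <- fx$model$joints$shoulder$center
  perp <- sh$center - S - sum((sh$center - S) * c(1, 0, 0)) * c(1, 0, 0)
  expect_lt(sqrt(sum(perp^2)), 0.1)
  expect_lt(max(abs(sh$axis - c(1, 0, 0))), 1e-3)
  wr <- fit$joints$wrist
  expect_lt(max(abs(wr$center - fx$model$joints$wrist$center)), 0.1)
  # per-posture wrist rotations match truth (axis-sign equivalences aside)
  for (k in 1:3) {
    truth <- list(c(15, 0), c(-15, -20), c(5, -40))[[k]]
    Rt <- rotation_about_axis(c(1, 0, 0), truth[1])$R %*%
      rotation_about_axis(c(0, 0, 1), truth[2])$R
    Rr <- rotation_about_axis(wr$axes[, 1], wr$angles_deg[k, 1])$R %*%
      rotation_about_axis(wr$axes[, 2], wr$angles_deg[k, 2])$R
    expect_lt(rotation_angle(t(Rr) %*% Rt), 0.1)
  }
  # constraint diagnostics: recovered transforms satisfy the revolute
  # constraint equations at the recovered center
  geom <- list(point = sh$center, axes = triad_from_z_export(sh$axis))
  for (k in 1:3) {
    r <- joint_constraint_residual("revolute", rt_identity(),
                                   fit$transforms[[k]]$humerus, geom)
    expect_lt(max(abs(r)), 1e-5)
  }
})

test_that("objective is invariant to a global rigid transform of all clouds", {
  fx <- make_fit_clouds(noise = 0.3, seed = 9, points = 40)
  cfg <- fit_config(n_starts = 2, seed = 5, max_iter = 120)
  f1 <- fit_skeleton_motion(fx$pc, config = cfg)
  G <- rotation_about_axis(c(0.3, 0.8, 0.52), 35, c(40, -20, 10))
  moved <- fx$pc
  moved$clouds <- lapply(moved$clouds, function(cl) {
    cl$points <- apply_transform(G, cl$points); cl
  })
  f2 <- fit_skeleton_motion(moved, config = cfg)
  expect_equal(f2$residual_mm, f1$residual_mm, tolerance = 0.02)
})

test_that("fit residual under noise matches the Gaussian-norm expectation", {
  # noise on the observed postures only, so the expected optimum residual
  # is the closed-form mean norm of one isotropic 3D Gaussian
  sigma <- 0.5
  fx <- make_fit_clouds(noise = 0, seed = 12, points = 150)
  set.seed(41)
  fx$pc$clouds <- lapply(fx$pc$clouds, function(cl) {
    if (cl$posture > 1)
      cl$points <- cl$points + matrix(rnorm(length(cl$points), 0, sigma),
                                      nrow(cl$points), 3)
    cl
  })
  fit <- fit_skeleton_motion(fx$pc, config = fit_config(n_starts = 2, seed = 3,
                                                        max_iter = 150))
  expected <- sigma * sqrt(8 / pi)
  expect_lt(abs(fit$residual_mm - expected) / expected, 0.2)
})

test_that("more multi-starts never worsen the best objective", {
  fx <- make_fit_clouds(noise = 0.4, seed = 6, points = 30)
  cfg1 <- fit_config(n_starts = 1, seed = 11, max_iter = 60)
  cfg5 <- fit_config(n_starts = 4, seed = 11, max_iter = 60)
  f1 <- fit_skeleton_motion(fx$pc, config = cfg1)
  f5 <- fit_skeleton_motion(fx$pc, config = cfg5)
  expect_lte(f5$objective_mm, f1$objective_mm + 1e-12)
})
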