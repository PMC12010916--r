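straight_muscle_model <- function(origin, insertion, wraps = list()) {
  m <- hinge_rod_model()
  path <- muscle_path("m", list(list(bone = "ground", pos = origin),
                                list(bone = "rod", pos = insertion)), wraps)
  m$muscles <- list(m = wing_muscle(path, muscle_params(l_om = 30, L_ts = 50)))
  m
}

test_that("path length: straight segments and collinear via points", {
  m <- straight_muscle_model(c(0, -5, 0), c(0, 5, 0))
  expect_equal(path_length(m, m$muscles$m, c(swing = 0)), 10)
  # collinear via point does not change the length
  p3 <- muscle_path("v", list(list(bone = "ground", pos = c(0, -5, 0)),
                              list(bone = "ground", pos = c(0, 0, 0)),
                              list(bone = "rod", pos = c(0, 5, 0))))
  expect_equal(path_length(m, p3, c(swing = 0)), 10, tolerance = 1e-12)
})

test_that("sphere wrapping matches the closed-form tangent-arc oracle", {
  r <- 5; d <- 20
  w <- wrap_object("sphere", "ground", c(0, 0, 0), r)
  m <- straight_muscle_model(c(0, -d, 0), c(0, d, 0), list(w))
  L <- path_length(m, m$muscles$m, c(swing = 0))
  # independent closed form: two tangents plus the wrapped arc
  oracle <- 2 * sqrt(d^2 - r^2) + r * (pi - 2 * acos(r / d))
  expect_equal(L, oracle, tolerance = 1e-9)
  expect_gt(L, 2 * d)   # wrapped path exceeds the straight chord
  # a segment that misses the sphere is unchanged
  m2 <- straight_muscle_model(c(0, -d, 10), c(0, d, 10), list(w))
  expect_equal(path_length(m2, m2$muscles$m, c(swing = 0)), 2 * d,
               tolerance = 1e-12)
  # attachment inside the wrap is an error
  m3 <- straight_muscle_model(c(0, -2, 0), c(0, d, 0), list(w))
  expect_error(path_length(m3, m3$muscles$m, c(swing = 0)), "inside wrap")
})

test_that("cylinder wrapping reduces to the planar circle case and adds the
           axial component pythagoreanly", {
  r <- 4; d <- 15
  w <- wrap_object("cylinder", "ground", c(0, 0, 0), r, axis = c(0, 0, 1))
  m <- straight_muscle_model(c(-d, 0, 0), c(d, 0, 0), list(w))
  planar <- 2 * sqrt(d^2 - r^2) + r * (pi - 2 * acos(r / d))
  expect_equal(path_length(m, m$muscles$m, c(swing = 0)), planar,
               tolerance = 1e-9)
  dz <- 12
  m2 <- straight_muscle_model(c(-d, 0, -dz / 2), c(d, 0, dz / 2), list(w))
  expect_equal(path_length(m2, m2$muscles$m, c(swing = 0)),
               sqrt(planar^2 + dz^2), tolerance = 1e-9)
})

test_that("ellipsoid wrapping with equal radii approximates the sphere form", {
  r <- 5; d <- 20
  w <- wrap_object("ellipsoid", "ground", c(0, 0, 0), c(r, r, r))
  m <- straight_muscle_model(c(0, -d, 0), c(0, d, 0), list(w))
  oracle <- 2 * sqrt(d^2 - r^2) + r * (pi - 2 * acos(r / d))
  expect_equal(path_length(m, m$muscles$m, c(swing = 0)), oracle,
               tolerance = 0.01 * oracle)
})

test_that("wrap length never drops below the straight-line distance", {
  set.seed(19)
  for (i in 1:15) {
    shape <- sample(c("sphere", "cylinder", "ellipsoid"), 1)
    radii <- if (shape == "ellipsoid") runif(3, 2, 6) else runif(1, 2, 6)
    w <- wrap_object(shape, "ground", rnorm(3, 0, 2), radii, axis = rnorm(3))
    p1 <- rnorm(3, 0, 3) + c(0, -25, 0); p2 <- rnorm(3, 0, 3) + c(0, 25, 0)
    m <- straight_muscle_model(p1, p2, list(w))
    L <- tryCatch(path_length(m, m$muscles$m, c(swing = 0)), error = function(e) NA)
    if (is.na(L)) next   # attachment landed inside the object
    expect_gte(L, sqrt(sum((p2 - p1)^2)) - 1e-9)
  }
})

test_that("tendon-excursion moment arm equals the geometric perpendicular
           distance for a straight path over a revolute joint", {
  for (d in c(5, 12)) {
    m <- straight_muscle_model(c(0, -40, d), c(0, 60, d))
    r <- moment_arm(m, m$muscles$m, c(swing = 0), "swing")
    expect_equal(abs(r), d, tolerance = 0.01 * d)
    # Richardson check: halving the step changes the result negligibly
    r2 <- moment_arm(m, m$muscles$m, c(swing = 0), "swing", step_rad = 5e-5)
    expect_lt(abs(r - r2), 1e-6)
  }
  # a path that does not cross the joint has exactly zero moment arm
  m <- hinge_rod_model()
  p <- muscle_path("local", list(list(bone = "rod", pos = c(0, 10, 0)),
                                 list(bone = "rod", pos = c(0, 60, 5))))
  expect_identical(moment_arm(m, p, c(swing = 15), "swing"), 0)
})

test_that("activation dynamics follow the exact exponential solution", {
  expect_equal(activation_step(0.4, 0.4, 0.05), 0.4)
  expect_equal(activation_step(0, 1, 0.010, tau_act = 0.010),
               1 - exp(-1), tolerance = 1e-12)
  # long horizon converges to the excitation
  a <- 0.9
  for (i in 1:200) a <- activation_step(a, 0.2, 0.01)
  expect_equal(a, 0.2, tolerance = 1e-6)
  # monotone in u
  us <- seq(0, 1, 0.1)
  as_ <- vapply(us, function(u) activation_step(0.5, u, 0.02), 0)
  expect_true(all(diff(as_) >= 0))
  expect_error(activation_step(0, 1, 0.01, tau_act = 0), "positive")
})

test_that("steady-state force: normalization, slack and equilibrium", {
  p <- muscle_params(l_om = 30, alpha_deg = 0, L_ts = 50, F_max = 100)
  # rigid tendon, optimal fiber, full activation, isometric -> F_max
  res <- steady_state_force(p, 1, 50 + 30, 0, rigid_tendon = TRUE)
  expect_equal(res$force, 100, tolerance = 1e-9)
  # zero activation with fiber at/below optimal and slack tendon -> 0
  expect_equal(steady_state_force(p, 0, 60, 0)$force, 0)
  # elastic tendon: equilibrium residual is tiny over random states
  set.seed(23)
  for (i in 1:25) {
    pp <- muscle_params(l_om = runif(1, 15, 50), alpha_deg = runif(1, 0, 25),
                        L_ts = runif(1, 30, 90), F_max = 100)
    Lmt <- runif(1, 0.9, 1.3) * (pp$L_ts + pp$l_om)
    r <- steady_state_force(pp, runif(1), Lmt, runif(1, -50, 50))
    if (!r$rigid_fallback && r$force > 0)
      expect_lt(r$equilibrium_residual, 1e-8 * pp$F_max)
  }
})

test_that("tendon slack estimation: algebraic limit, measured-range oracle
           and homogeneity", {
  # rigid-tendon limit with known fiber length
  est <- estimate_tendon_slack(100, 110, alpha_deg = 0, lnorm_min = 1,
                               l_om = 20)
  expect_equal(est$L_ts, 100 - 20, tolerance = 1e-12)
  # measured range of the wrist flexor: independent 2x2 linear solve
  cosa <- 1
  M <- rbind(c(1, 0.85 * cosa), c(1, 1.05 * cosa))
  oracle <- solve(M, c(103.2, 105.9))
  est2 <- estimate_tendon_slack(103.2, 105.9, alpha_deg = 0)
  expect_equal(est2$L_ts, oracle[1], tolerance = 1e-9)
  expect_equal(est2$l_om, oracle[2], tolerance = 1e-9)
  # homogeneity: scaling all lengths by 2 scales the solution by 2
  est3 <- estimate_tendon_slack(2 * 103.2, 2 * 105.9, alpha_deg = 0)
  expect_equal(est3$L_ts, 2 * est2$L_ts, tolerance = 1e-9)
  expect_error(estimate_tendon_slack(50, 40), "L_mt_max > L_mt_min")
  expect_error(estimate_tendon_slack(10, 10.1, l_om = 50), "inconsistent")
})

test_that("length trajectories: periodicity, recomputation oracle and
           independence from Hill parameters", {
  model <- small_wing()
  motion <- default_motion()
  mus <- model$muscles[["M. extensor metacarpi radialis"]]
  tr <- length_trajectory(model, mus, motion, samples = 60)
  # periodic: fraction 0 equals a fresh evaluation at fraction 1
  L1 <- path_length(model, mus,
                    flatten_pose(model, motion, 1.0))
  expect_equal(tr$length_mm[1], L1, tolerance = 1e-9)
  # per-sample recomputation oracle
  for (i in c(4, 23, 51)) {
    Li <- path_length(model, mus, flatten_pose(model, motion, tr$fraction[i]))
    expect_equal(tr$length_mm[i], Li, tolerance = 1e-12)
  }
  # geometry does not see l_om / L_ts
  model2 <- model
  model2$muscles[[mus$name]]$params$l_om <- mus$params$l_om * 0.4
  model2$muscles[[mus$name]]$params$L_ts <- mus$params$L_ts * 1.6
  tr2 <- length_trajectory(model2, model2$muscles[[mus$name]], motion, samples = 60)
  expect_identical(tr$length_mm, tr2$length_mm)
  # a muscle entirely on one bone has a constant trajectory
  p <- muscle_path("local", list(list(bone = "humerus", pos = c(0, 20, 3)),
                                 list(bone = "humerus", pos = c(0, 60, -2))))
  tr3 <- length_trajectory(model, p, motion, samples = 30)
  expect_lt(diff(range(tr3$length_mm)), 1e-9)
})

test_that("contraction periods: symmetric and asymmetric oracles", {
  # pure cosine length: contracting on exactly [0, 50]%
  tr <- data.frame(fraction = (0:199) / 200,
                   length_mm = 100 + 5 * cos(2 * pi * (0:199) / 200))
  per <- contraction_periods(tr)
  expect_equal(as.numeric(per), c(0, 50))
  # constant trajectory: no contraction intervals
  flat <- data.frame(fraction = (0:49) / 50, length_mm = rep(80, 50))
  expect_equal(nrow(contraction_periods(flat)), 0)
  # synthetic wrist flexor: boundaries equal the derivative-root oracle of
  # a Fourier refit within the reporting resolution
  model <- small_wing()
  trw <- length_trajectory(model, model$muscles[["M. flexor carpi ulnaris"]],
                           default_motion(), samples = 200)
  per2 <- contraction_periods(trw)
  refit <- fit_fourier(trw$fraction, trw$length_mm, K = 6, period_s = 1)
  ph <- phase_analysis(refit$motion)[[1]]
  oracle <- sort(ph$turning_points)
  got <- sort(unique(as.numeric(per2[per2 > 0 & per2 < 100])))
  expect_equal(got, round(oracle / 0.5) * 0.5, tolerance = 0.51)
})
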