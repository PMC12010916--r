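test_that("generators are deterministic in the seed", {
  cfg <- synth_config(seed = 99, points_per_bone = 50)
  m1 <- make_synthetic_wing(cfg); m2 <- make_synthetic_wing(cfg)
  expect_identical(m1$bones$humerus$surface, m2$bones$humerus$surface)
  s1 <- make_noisy_angle_series(default_motion(), cfg)
  s2 <- make_noisy_angle_series(default_motion(), cfg)
  expect_identical(s1, s2)
  m3 <- make_synthetic_wing(synth_config(seed = 100, points_per_bone = 50))
  expect_false(identical(m1$bones$humerus$surface, m3$bones$humerus$surface))
})

test_that("the synthetic wing satisfies the model invariants", {
  model <- small_wing()
  expect_silent(validate_wing_model(model))
  expect_length(model$muscles, 6)
  expect_named(model$joints, c("shoulder", "elbow", "wrist"))
  expect_identical(model$joints$elbow$kind, "fixed")
  expect_identical(model$joints$shoulder$kind, "revolute")
  expect_identical(model$joints$wrist$kind, "universal")
  expect_equal(model$joints$shoulder$center, c(-11.2, 0.1, 0.1))
})

test_that("muscle length ranges over the default motion match the measured
           ranges within 15%", {
  model <- small_wing()
  targets <- list("M. subscapularis" = c(13.7, 14.6),
                  "M. scapulotriceps" = c(73.4, 74.9),
                  "M. extensor digitorum communis" = c(136.7, 139.0),
                  "M. flexor carpi ulnaris" = c(103.2, 105.9),
                  "M. extensor metacarpi radialis" = c(89.9, 97.9),
                  "M. extensor carpi ulnaris" = c(100.3, 105.3))
  for (mn in names(targets)) {
    tr <- length_trajectory(model, model$muscles[[mn]], default_motion(), 200)
    tgt <- targets[[mn]]
    expect_gt(min(tr$length_mm), 0.85 * tgt[1])
    expect_lt(min(tr$length_mm), 1.15 * tgt[1])
    expect_gt(max(tr$length_mm), 0.85 * tgt[2])
    expect_lt(max(tr$length_mm), 1.15 * tgt[2])
  }
})

test_that("posture clouds are exact fk copies at zero noise", {
  model <- small_wing()
  pc <- make_posture_clouds(model, postures = list(ref = list(shoulder = 0, wrist = c(0, 0)),
                                                   same = list(shoulder = 0, wrist = c(0, 0))),
                            noise_sigma = 0, seed = 5)
  ref_h <- model$bones$humerus$surface
  cl <- Filter(function(x) x$bone == "humerus" & x$posture == 2, pc$clouds)[[1]]
  expect_equal(cl$points, ref_h)

  pc2 <- make_posture_clouds(model,
                             postures = list(ref = list(shoulder = 0, wrist = c(0, 0)),
                                             up = list(shoulder = 30, wrist = c(0, 0))),
                             noise_sigma = 0, seed = 5)
  cl2 <- Filter(function(x) x$bone == "humerus" & x$posture == 2, pc2$clouds)[[1]]
  manual <- apply_transform(rotation_about_axis(c(1, 0, 0), 30,
                                                model$joints$shoulder$center), ref_h)
  expect_lt(max(abs(cl2$points - manual)), 1e-9)
})

test_that("cloud noise magnitude matches the 3D Gaussian norm expectation", {
  cfg <- synth_config(seed = 21, points_per_bone = 2500)
  model <- make_synthetic_wing(cfg)
  sigma <- 0.5
  pc <- make_posture_clouds(model, noise_sigma = sigma, seed = 77)
  clean <- make_posture_clouds(model, noise_sigma = 0, seed = 77)
  disp <- unlist(lapply(seq_along(pc$clouds), function(i)
    sqrt(rowSums((pc$clouds[[i]]$points - clean$clouds[[i]]$points)^2))))
  expect_equal(mean(disp), sigma * sqrt(8 / pi), tolerance = 0.05)
})

test_that("noisy angle series: zero noise is exact and flags cycles 2..n-1", {
  motion <- default_motion()
  cfg <- synth_config(seed = 4, angle_noise_sigma = 0, n_cycles = 8,
                      samples_per_cycle = 50)
  s <- make_noisy_angle_series(motion, cfg)
  expect_equal(nrow(s), 400)
  exact <- evaluate_motion(motion, s$time_s)$angles
  expect_lt(max(abs(s$xl_shoulder_deg - exact[, "xl_shoulder"])), 1e-12)
  expect_identical(unique(s$cycle[s$selected]), 2:7)
})

test_that("Fourier refit of a noisy series recovers the amplitude within 2 deg", {
  motion <- default_motion()
  cfg <- synth_config(seed = 8, angle_noise_sigma = 2, n_cycles = 8,
                      samples_per_cycle = 100)
  s <- make_noisy_angle_series(motion, cfg)
  sel <- s[s$selected, ]
  fit <- fit_fourier(sel$time_s, cbind(xl_shoulder = sel$xl_shoulder_deg),
                     K = 4, period_s = motion$period_s)
  amp <- phase_analysis(fit$motion)$xl_shoulder$amplitude_deg
  expect_lt(abs(amp - 64), 2)
})

test_that("degenerate generator inputs are rejected", {
  expect_error(synth_config(points_per_bone = 0))
  expect_error(synth_config(bone_lengths = c(humerus = 0, ulna = 1, metacarpus = 1)))
  model <- small_wing()
  m2 <- model; m2$bones$humerus$surface <- matrix(numeric(0), 0, 3)
  expect_error(make_posture_clouds(m2, noise_sigma = 0, seed = 1), "empty reference cloud")
  expect_error(make_posture_clouds(model, postures = default_postures()[1]),
               "at least 2 postures")
})
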