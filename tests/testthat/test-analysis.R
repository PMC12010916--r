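test_that("rms: closed forms, loop oracle and homogeneity", {
  expect_equal(rms(rep(-3, 10)), 3)
  t <- seq(0, 2, length.out = 2001)[-2001]
  expect_equal(rms(sin(2 * pi * t)), 1 / sqrt(2), tolerance = 1e-6)
  set.seed(77)
  x <- rnorm(101)
  acc <- 0; for (v in x) acc <- acc + v^2
  expect_equal(rms(x), sqrt(acc / length(x)), tolerance = 1e-12)
  expect_equal(rms(-2.5 * x), 2.5 * rms(x), tolerance = 1e-12)
  expect_error(rms(numeric(0)), "empty")
})

test_that("comparison metrics are scale invariant and reproduce the printed
           proportional error", {
  m0 <- comparison_metrics(c(2, 5), 10 * c(2, 5))
  expect_equal(m0$MAE, 0)
  expect_equal(m0$PD_pct, 0)
  expect_equal(m0$PE_pct, 0)
  # the validation worked example: simulated activity RMS vs kestrel EMG RMS
  m <- comparison_metrics(c(16, 37), c(0.1628, 0.3478))
  expect_equal(round(m$PE_pct, 2), 7.62)
  # invariance to separate positive rescaling of either pair
  m2 <- comparison_metrics(3.7 * c(16, 37), 0.01 * c(0.1628, 0.3478))
  expect_equal(m2$PE_pct, m$PE_pct, tolerance = 1e-12)
  expect_equal(m2$MAE, m$MAE, tolerance = 1e-12)
  # PE is asymmetric in its arguments by definition; MAE is not
  ms <- comparison_metrics(c(0.1628, 0.3478), c(16, 37))
  expect_equal(ms$MAE, m$MAE, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ms$PE_pct, m$PE_pct)))
  expect_error(comparison_metrics(c(0, 0), c(1, 2)), "positive maximum")
})

test_that("interval average error: identity, arithmetic and wrapping", {
  a <- rbind(c(0, 50))
  expect_equal(interval_average_error(a, a), 0)
  expect_equal(interval_average_error(rbind(c(2, 48)), rbind(c(0, 50))), 2)
  # wrapped pieces merge before matching
  w1 <- rbind(c(0, 20), c(80, 100))
  w2 <- rbind(c(0, 18), c(83, 100))
  expect_equal(interval_average_error(w1, w2), mean(c(3, 2)))
  expect_error(interval_average_error(rbind(c(0, 50), c(60, 70)), a),
               "structural change")
})

test_that("Hill-parameter sensitivity is exactly zero and the wrap-radius
           control detects real geometry edits", {
  model <- small_wing()
  motion <- default_motion()
  sens <- parameter_sensitivity(model, motion, parameters = c("l_om", "L_ts"),
                                deltas = c(-0.6, 0.6), samples = 80)
  expect_true(all(sens$max_rel_change_permille == 0))
  ctrl <- parameter_sensitivity(model, motion, parameters = "wrap_radius",
                                deltas = 0.2, samples = 80,
                                muscles = "M. subscapularis")
  expect_gt(ctrl$max_rel_change_permille, 0.1)
})

test_that("amplitude study: unit scale reproduces the base analysis and a
           zero scale degenerates to constant lengths", {
  model <- small_wing()
  motion <- default_motion()
  mus <- "M. scapulotriceps"
  amp <- amplitude_study(model, motion, scales = c(0.4, 1.0), muscles = mus,
                         samples = 100)
  base_tr <- length_trajectory(model, model$muscles[[mus]], motion, 100)
  expect_equal(amp[[mus]][["1"]]$trajectory$length_mm, base_tr$length_mm)
  expect_equal(amp[[mus]][["1"]]$periods,
               contraction_periods(base_tr))
  expect_true(is.na(amp[[mus]][["1"]]$avg_error_pct))
  zero <- scale_motion_amplitude(motion, 0)
  tr0 <- length_trajectory(model, model$muscles[[mus]], zero, 50)
  expect_lt(diff(range(tr0$length_mm)), 1e-9)
  expect_equal(nrow(contraction_periods(tr0)), 0)
})

test_that("a shoulder-only muscle keeps its contraction boundaries across
           amplitudes while boundaries vary continuously in general", {
  model <- small_wing()
  motion <- default_motion()
  amp <- amplitude_study(model, motion, scales = c(0.4, 0.6, 0.8, 1.0, 1.2),
                         samples = 120)
  # M. scapulotriceps spans only the shoulder; its monotone length response
  # to a single cosine dof pins the boundaries at the stroke reversals
  st <- amp[["M. scapulotriceps"]]
  errs <- vapply(st, function(r) r$avg_error_pct, 0)
  expect_true(all(errs[!is.na(errs)] < 0.01))
  # continuity: adjacent scales shift boundaries by less than 15% cycle
  for (mn in names(amp)) {
    sc <- names(amp[[mn]])
    for (i in seq_len(length(sc) - 1)) {
      p1 <- amp[[mn]][[sc[i]]]$periods; p2 <- amp[[mn]][[sc[i + 1]]]$periods
      if (nrow(p1) == 0 || nrow(p2) == 0) next
      shift <- tryCatch(interval_average_error(p1, p2), error = function(e) NA)
      if (!is.na(shift)) expect_lt(shift, 15)
    }
  }
})
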