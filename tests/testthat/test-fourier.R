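test_that("fit recovers exact Fourier inputs with a zero-width band", {
  T_ <- 0.5
  t <- seq(0, 3 * T_, length.out = 301)[-301]
  y <- 5 + 3 * cos(2 * pi * t / T_)
  fit <- fit_fourier(t, y, K = 3, period_s = T_)
  cf <- fit$motion$coefficients[[1]]
  expect_equal(cf$a0, 5, tolerance = 1e-9)
  expect_equal(cf$a, c(3, 0, 0), tolerance = 1e-9)
  expect_equal(cf$b, c(0, 0, 0), tolerance = 1e-9)
  band <- fit$band[[1]]
  expect_lt(max(abs(c(band$lo, band$hi)), na.rm = TRUE), 1e-9)

  const <- fit_fourier(t, rep(7, length(t)), K = 2, period_s = T_)
  cc <- const$motion$coefficients[[1]]
  expect_equal(cc$a0, 7, tolerance = 1e-12)
  expect_lt(max(abs(c(cc$a, cc$b))), 1e-12)
})

test_that("the fit is the exact linear least-squares optimum", {
  set.seed(14)
  T_ <- 1
  t <- sort(runif(200, 0, 6))
  y <- 2 - 4 * cos(2 * pi * t) + 1.5 * sin(4 * pi * t) + rnorm(200, 0, 0.5)
  fit <- fit_fourier(t, y, K = 3, period_s = T_)
  resid <- y - evaluate_motion(fit$motion, t)$angles[, 1]
  w <- 2 * pi * (1:3)
  X <- cbind(1, cos(outer(t, w)), sin(outer(t, w)))
  expect_lt(max(abs(crossprod(X, resid))), 1e-8)
})

test_that("noisy-fit coefficient errors respect the LS covariance prediction", {
  set.seed(31)
  T_ <- 1; sigma <- 2; K <- 3
  t <- seq(0, 6, length.out = 601)[-601]
  truth <- c(a0 = 3, a1 = 20, b2 = -7)
  y <- truth["a0"] + truth["a1"] * cos(2 * pi * t) + truth["b2"] * sin(4 * pi * t) +
    rnorm(length(t), 0, sigma)
  fit <- fit_fourier(t, y, K = K, period_s = T_)
  w <- 2 * pi * (1:K)
  X <- cbind(1, cos(outer(t, w)), sin(outer(t, w)))
  se <- sigma * sqrt(diag(solve(crossprod(X))))
  cf <- fit$motion$coefficients[[1]]
  beta_hat <- c(cf$a0, cf$a, cf$b)
  beta_true <- c(3, 20, 0, 0, 0, -7, 0)
  expect_true(all(abs(beta_hat - beta_true) < 3 * se))
})

test_that("analytic derivatives match closed form and finite differences", {
  m <- fourier_motion(0.5, list(d = list(a0 = 1, a = c(10, 0), b = c(0, 0))))
  ev <- evaluate_motion(m, c(0.125, 0.3))
  expect_equal(max(abs(evaluate_motion(m, seq(0, 0.5, 1e-4))$velocities)),
               10 * 2 * pi / 0.5, tolerance = 1e-4)
  # periodicity of the full triple
  e1 <- evaluate_motion(m, 0.17); e2 <- evaluate_motion(m, 0.17 + 0.5)
  expect_equal(e1, e2, tolerance = 1e-9)
  # finite-difference oracle
  mo <- default_motion()
  h <- 1e-6
  for (t0 in c(0.04, 0.21, 0.4)) {
    num_v <- (evaluate_motion(mo, t0 + h)$angles - evaluate_motion(mo, t0 - h)$angles) / (2 * h)
    expect_lt(max(abs(num_v - evaluate_motion(mo, t0)$velocities)), 1e-4)
  }
})

test_that("phase analysis: pure cosine decreases exactly on 0-50%", {
  m <- fourier_motion(1, list(d = list(a0 = 2, a = c(8, 0), b = c(0, 0))))
  ph <- phase_analysis(m)$d
  expect_equal(ph$amplitude_deg, 16, tolerance = 1e-9)
  expect_equal(as.numeric(ph$decreasing), c(0, 50), tolerance = 1e-6)
  # amplitude equals the dense max-min
  dense <- evaluate_motion(m, seq(0, 1, length.out = 5000))$angles
  expect_equal(ph$amplitude_deg, diff(range(dense)), tolerance = 1e-6)
})

test_that("phase intervals are invariant to adding a constant", {
  base <- default_motion()
  shifted <- base
  shifted$coefficients$xl_wrist$a0 <- shifted$coefficients$xl_wrist$a0 + 123
  p1 <- phase_analysis(base)$xl_wrist
  p2 <- phase_analysis(shifted)$xl_wrist
  expect_equal(p1$decreasing, p2$decreasing, tolerance = 1e-9)
  expect_equal(p1$amplitude_deg, p2$amplitude_deg, tolerance = 1e-9)
})

test_that("a constant dof is reported as no-stroke", {
  m <- fourier_motion(1, list(flat = list(a0 = 4, a = c(0, 0), b = c(0, 0))))
  ph <- phase_analysis(m)$flat
  expect_true(ph$no_stroke)
  expect_equal(ph$amplitude_deg, 0)
  expect_equal(nrow(ph$decreasing), 0)
})

test_that("under-determined fits are rejected", {
  expect_error(fit_fourier(seq(0, 1, length.out = 5), rnorm(5), K = 4,
                           period_s = 1), "under-determined")
})

test_that("amplitude scaling preserves the mean and scales the range", {
  m <- default_motion()
  s <- scale_motion_amplitude(m, 0.4)
  expect_equal(s$coefficients$xl_shoulder$a0, m$coefficients$xl_shoulder$a0)
  expect_equal(phase_analysis(s)$xl_shoulder$amplitude_deg, 0.4 * 64,
               tolerance = 1e-6)
  t <- seq(0, m$period_s, length.out = 401)[-401]
  expect_equal(mean(evaluate_motion(s, t)$angles[, "zl_wrist"]),
               mean(evaluate_motion(m, t)$angles[, "zl_wrist"]), tolerance = 1e-9)
})
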