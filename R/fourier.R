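#' Fourier-series joint motion
#'
#' Periodic joint-angle trajectories represented, per degree of freedom, as
#' a0 + sum_k [ a_k cos(2 pi k t / T) + b_k sin(2 pi k t / T) ], angles in
#' degrees. Derivatives are available analytically term-wise.
#'
#' @param period_s cycle period T in seconds.
#' @param coefficients named list, one entry per dof, each a list with
#'   numeric `a0`, and vectors `a`, `b` of equal length K (degrees).
#' @return object of class `fourier_motion`.
#' @export
fourier_motion <- function(period_s, coefficients) {
  stopifnot(period_s > 0, length(coefficients) >= 1, !is.null(names(coefficients)))
  for (nm in names(coefficients)) {
    cf <- coefficients[[nm]]
    if (length(cf$a) != length(cf$b))
      stop("dof '", nm, "': cosine/sine coefficient lengths differ")
    if (length(cf$a) < 1) stop("dof '", nm, "': need K >= 1 harmonics")
  }
  structure(list(period_s = period_s, coefficients = coefficients),
            class = "fourier_motion")
}

#' @export
print.fourier_motion <- function(x, ...) {
  cat(sprintf("<fourier_motion> T = %g s, dofs: %s\n", x$period_s,
              paste(names(x$coefficients), collapse = ", ")))
  invisible(x)
}

#' Dof names of a motion
#' @param motion `fourier_motion`.
#' @return character vector.
#' @export
motion_dofs <- function(motion) names(motion$coefficients)

#' Evaluate a Fourier motion
#'
#' Returns angles plus analytic (term-wise) first and second derivatives at
#' the requested times. No finite differences are involved.
#'
#' @param motion `fourier_motion`.
#' @param t numeric vector of times (s).
#' @param dofs dof subset (default all).
#' @return list with matrices `angles` (deg), `velocities` (deg/s),
#'   `accelerations` (deg/s^2); rows = times, columns = dofs.
#' @export
evaluate_motion <- function(motion, t, dofs = motion_dofs(motion)) {
  T_ <- motion$period_s
  ang <- vel <- acc <- matrix(0, length(t), length(dofs),
                              dimnames = list(NULL, dofs))
  for (nm in dofs) {
    cf <- motion$coefficients[[nm]]
    K <- length(cf$a)
    w <- 2 * pi * seq_len(K) / T_          # rad/s per harmonic
    ph <- outer(t, w)                       # n x K
    cosph <- cos(ph); sinph <- sin(ph)
    ang[, nm] <- cf$a0 + cosph %*% cf$a + sinph %*% cf$b
    vel[, nm] <- (-sinph) %*% (cf$a * w) + cosph %*% (cf$b * w)
    acc[, nm] <- (-cosph) %*% (cf$a * w^2) + (-sinph) %*% (cf$b * w^2)
  }
  list(angles = ang, velocities = vel, accelerations = acc)
}

#' Fit a Fourier series to sampled joint angles
#'
#' Linear least-squares fit of order-K Fourier coefficients to time-angle
#' samples, jointly across all cycles present in the series. The deviation
#' band is the per-cycle-fraction min/max envelope of the residuals around
#' the fit (use `band = "sd"` for a +/- 1 SD band instead).
#'
#' @param time sample times (s).
#' @param angles numeric vector or matrix (columns = dofs, degrees).
#' @param K Fourier order (default 4).
#' @param period_s known period; if NULL, estimated from the dominant
#'   periodogram frequency and refined by local optimization.
#' @param band "envelope" (default) or "sd".
#' @param n_band number of cycle-fraction bins for the band (default 100).
#' @return list with `motion` (a [fourier_motion()]), `band` (per dof, a
#'   data.frame fraction/lo/hi in degrees), `residual_rms` per dof, and the
#'   `period_s` used.
#' @export
fit_fourier <- function(time, angles, K = 4, period_s = NULL,
                        band = c("envelope", "sd"), n_band = 100) {
  band <- match.arg(band)
  A <- if (is.null(dim(angles))) matrix(angles, ncol = 1,
                                        dimnames = list(NULL, "dof1")) else as.matrix(angles)
  if (is.null(colnames(A))) colnames(A) <- paste0("dof", seq_len(ncol(A)))
  n <- length(time)
  if (is.null(period_s)) period_s <- estimate_period(time, A)
  if (n < 2 * K + 1) stop("under-determined fit: need at least 2K+1 samples")
  w <- 2 * pi * seq_len(K) / period_s
  X <- cbind(1, cos(outer(time, w)), sin(outer(time, w)))
  if (qr(X)$rank < ncol(X)) stop("under-determined fit: design matrix rank-deficient")
  beta <- qr.coef(qr(X), A)                # (2K+1) x ndof
  fitted <- X %*% beta
  resid <- A - fitted
  coefs <- lapply(seq_len(ncol(A)), function(j)
    list(a0 = unname(beta[1, j]), a = unname(beta[2:(K + 1), j]),
         b = unname(beta[(K + 2):(2 * K + 1), j])))
  names(coefs) <- colnames(A)
  motion <- fourier_motion(period_s, coefs)
  frac <- (time %% period_s) / period_s
  bin <- pmin(floor(frac * n_band), n_band - 1)
  bands <- lapply(seq_len(ncol(A)), function(j) {
    r <- resid[, j]
    lo <- hi <- rep(NA_real_, n_band)
    for (b in sort(unique(bin))) {
      rb <- r[bin == b]
      if (band == "envelope") { lo[b + 1] <- min(rb); hi[b + 1] <- max(rb) }
      else { s <- stats::sd(rb); m <- mean(rb)
             lo[b + 1] <- m - s; hi[b + 1] <- m + s }
    }
    data.frame(fraction = (seq_len(n_band) - 0.5) / n_band, lo = lo, hi = hi)
  })
  names(bands) <- colnames(A)
  list(motion = motion, band = bands,
       residual_rms = apply(resid, 2, function(r) sqrt(mean(r^2))),
       period_s = period_s)
}

# dominant-frequency periodogram pick, refined by minimizing the order-1
# least-squares residual over the period
estimate_period <- function(time, A) {
  dt <- stats::median(diff(time))
  y <- A[, 1] - mean(A[, 1])
  sp <- Mod(stats::fft(y))[2:floor(length(y) / 2)]
  k <- which.max(sp)
  T0 <- length(y) * dt / k
  rss <- function(T_) {
    w <- 2 * pi / T_
    X <- cbind(1, cos(w * time), sin(w * time))
    sum(stats::lsfit(X, A, intercept = FALSE)$residuals^2)
  }
  stats::optimize(rss, c(0.8 * T0, 1.25 * T0))$minimum
}

#' Phase analysis of a periodic motion
#'
#' Locates, per dof, the turning points of the analytic derivative (sign
#' changes bracketed on a 1000-sample grid and refined by bisection to 1e-6
#' cycle fraction) and reports the decreasing and increasing intervals as
#' percent of cycle, together with the peak-to-peak amplitude. A constant
#' dof is reported as a single "no stroke" interval.
#'
#' @param motion `fourier_motion`.
#' @param n_grid grid density per cycle (default 1000).
#' @return named list per dof: `amplitude_deg`, `decreasing`, `increasing`
#'   (2-column matrices of start/end cycle percentages), `turning_points`
#'   (cycle %), and logical `no_stroke`.
#' @export
phase_analysis <- function(motion, n_grid = 1000) {
  T_ <- motion$period_s
  out <- list()
  for (nm in motion_dofs(motion)) {
    vel1 <- function(f) evaluate_motion(motion, f * T_, nm)$velocities[, 1]
    g <- seq(0, 1, length.out = n_grid + 1)
    v <- vel1(g)
    amp_ref <- diff(range(evaluate_motion(motion, g * T_, nm)$angles))
    if (max(abs(v)) * T_ < 1e-9 || amp_ref < 1e-9) {
      out[[nm]] <- list(amplitude_deg = 0,
                        decreasing = matrix(numeric(0), 0, 2),
                        increasing = matrix(numeric(0), 0, 2),
                        turning_points = numeric(0), no_stroke = TRUE)
      next
    }
    sc <- which(v[-length(v)] * v[-1] < 0)
    roots <- vapply(sc, function(i)
      stats::uniroot(vel1, c(g[i], g[i + 1]), tol = 1e-8)$root, 0)
    roots <- c(roots, g[v == 0])           # roots landing on grid points
    roots <- sort(unique(round(roots, 8) %% 1))
    if (length(roots) == 0) stop("non-constant dof without turning points")
    # classify the interval following each root
    segs <- cbind(roots, c(roots[-1], roots[1] + 1))
    mid <- (segs[, 1] + segs[, 2]) / 2
    decr <- vel1(mid %% 1) < 0
    angs <- evaluate_motion(motion, (roots %% 1) * T_, nm)$angles[, 1]
    to_pct <- function(sel) {
      m <- 100 * segs[sel, , drop = FALSE]
      m[, 1] <- m[, 1] %% 100
      m[, 2] <- m[, 1] + 100 * (segs[sel, 2] - segs[sel, 1])
      colnames(m) <- c("start_pct", "end_pct"); m
    }
    out[[nm]] <- list(amplitude_deg = max(angs) - min(angs),
                      decreasing = to_pct(decr),
                      increasing = to_pct(!decr),
                      turning_points = sort(100 * roots), no_stroke = FALSE)
  }
  out
}

#' Scale the oscillatory part of a motion
#'
#' Multiplies every harmonic coefficient by `scale`, preserving each dof's
#' cycle mean (a0) and the cycle duration.
#'
#' @param motion `fourier_motion`.
#' @param scale positive scale factor.
#' @return scaled `fourier_motion`.
#' @export
scale_motion_amplitude <- function(motion, scale) {
  stopifnot(scale >= 0)
  cf <- lapply(motion$coefficients, function(c0)
    list(a0 = c0$a0, a = c0$a * scale, b = c0$b * scale))
  fourier_motion(motion$period_s, cf)
}
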