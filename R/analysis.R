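#' Root mean square of a signal
#'
#' @param x numeric vector (non-empty).
#' @return sqrt(mean(x^2)).
#' @export
rms <- function(x) {
  if (length(x) == 0) stop("rms of empty signal")
  sqrt(mean(x^2))
}

#' Validation metrics between simulated and experimental RMS pairs
#'
#' Both pairs (e.g. simulated muscle-activity RMS of two muscles, and the
#' electromyographic RMS of the homologous muscles in a reference species)
#' are max-normalized, making the metrics invariant to the arbitrary units
#' of either source. Metrics on the normalized pairs:
#' MAE = mean absolute difference; PD = mean absolute difference divided
#' by the mean normalized level, in percent; PE = the difference of the
#' non-maximal normalized elements relative to the experimental one, in
#' percent (asymmetric in its arguments by definition).
#'
#' @param sim numeric pair of simulated RMS values (positive).
#' @param exp numeric pair of experimental RMS values (positive).
#' @return list of class `comparison_metrics`: `MAE`, `PD_pct`, `PE_pct`,
#'   and the normalized pairs.
#' @export
comparison_metrics <- function(sim, exp) {
  stopifnot(length(sim) == 2, length(exp) == 2)
  if (max(sim) <= 0 || max(exp) <= 0) stop("pairs must have a positive maximum")
  s <- unname(sim / max(sim))
  e <- unname(exp / max(exp))
  mae <- mean(abs(s - e))
  pd <- mae / mean(c(s, e)) * 100
  i <- which.min(e)   # the non-maximal element (the other is 1 in both)
  pe <- abs(s[i] - e[i]) / e[i] * 100
  structure(list(MAE = mae, PD_pct = pd, PE_pct = pe,
                 sim_norm = s, exp_norm = e),
            class = "comparison_metrics")
}

#' @export
print.comparison_metrics <- function(x, ...) {
  cat(sprintf("MAE = %.5f, PD = %.2f%%, PE = %.2f%%\n", x$MAE, x$PD_pct, x$PE_pct))
  invisible(x)
}

#' Muscle-function study across flapping amplitudes
#'
#' Scales the oscillatory part of every dof of the base motion (cycle mean
#' and duration preserved), recomputes each muscle's length trajectory and
#' contraction periods at each scale, and reports the boundary agreement
#' with the unit-scale motion.
#'
#' @param model `wing_model`.
#' @param motion base `fourier_motion`.
#' @param scales amplitude factors (default the study set 0.4..1.2).
#' @param muscles muscle subset (default all).
#' @param samples trajectory samples per cycle.
#' @return nested list per muscle: per scale, `trajectory`, `periods`
#'   (matrix of % intervals), and `avg_error_pct` vs scale 1.0 (NA for the
#'   reference scale or on structural change).
#' @export
amplitude_study <- function(model, motion, scales = c(0.4, 0.6, 0.8, 1.0, 1.2),
                            muscles = names(model$muscles), samples = 200) {
  stopifnot(all(scales >= 0))
  if (!(1.0 %in% scales)) scales <- sort(c(1.0, scales))
  out <- list()
  for (mn in muscles) {
    res <- list()
    for (s in scales) {
      mo <- scale_motion_amplitude(motion, s)
      tr <- length_trajectory(model, model$muscles[[mn]], mo, samples)
      per <- contraction_periods(tr)
      res[[sprintf("%g", s)]] <- list(scale = s, trajectory = tr, periods = per)
    }
    ref <- res[["1"]]$periods
    for (nm in names(res)) {
      res[[nm]]$avg_error_pct <- if (res[[nm]]$scale == 1.0) NA_real_ else
        tryCatch(interval_average_error(res[[nm]]$periods, ref),
                 error = function(e) NA_real_)
    }
    out[[mn]] <- res
  }
  out
}

#' Average boundary error between two contraction-interval lists
#'
#' Mean absolute difference of matched interval boundaries, in percent of
#' cycle. Intervals are matched by order after wrap-around alignment (an
#' interval pair split across the cycle boundary is merged before
#' matching). A differing interval count is a structural change and is
#' reported as an error rather than averaged.
#'
#' @param intervals,reference 2-column matrices of start/end cycle
#'   percentages.
#' @return mean absolute boundary difference (% of cycle).
#' @export
interval_average_error <- function(intervals, reference) {
  a <- merge_wrapped(intervals); b <- merge_wrapped(reference)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty interval list")
  if (nrow(a) != nrow(b))
    stop(sprintf("structural change: %d vs %d contraction intervals",
                 nrow(a), nrow(b)))
  mean(abs(circ_diff_pct(as.numeric(a), as.numeric(b))))
}

# merge a trailing interval ending at 100 with a leading one starting at 0
merge_wrapped <- function(m) {
  if (nrow(m) >= 2 && m[nrow(m), 2] == 100 && m[1, 1] == 0) {
    merged <- c(m[nrow(m), 1], m[1, 2] + 100)
    m <- rbind(merged, m[-c(1, nrow(m)), , drop = FALSE])
  }
  m
}

circ_diff_pct <- function(a, b) {
  d <- (a - b) %% 100
  ifelse(d > 50, d - 100, d)
}

#' Sensitivity of muscle-tendon length trajectories to model parameters
#'
#' Recomputes every muscle's full length trajectory after perturbing a
#' parameter by each delta and reports the maximum relative change in per
#' mille. Hill parameters (optimal fiber length `l_om`, tendon slack
#' length `L_ts`) do not enter the path geometry, so their rows are
#' identically zero -- the geometric separation behind the model's
#' parameter robustness. Perturbing a wrap-object radius (`wrap_radius`)
#' is a positive control that produces genuine geometric change.
#'
#' @param model `wing_model`.
#' @param motion `fourier_motion`.
#' @param parameters subset of c("l_om", "L_ts", "wrap_radius").
#' @param deltas relative perturbations (default the study sweep
#'   +/-20/40/60%).
#' @param muscles muscle subset (default all).
#' @param samples trajectory samples per cycle.
#' @return data.frame of class `sensitivity_report`: muscle, parameter,
#'   delta_pct, max_rel_change_permille.
#' @export
parameter_sensitivity <- function(model, motion,
                                  parameters = c("l_om", "L_ts"),
                                  deltas = c(-0.6, -0.4, -0.2, 0.2, 0.4, 0.6),
                                  muscles = names(model$muscles),
                                  samples = 200) {
  stopifnot(all(abs(deltas) <= 0.6 + 1e-12))
  rows <- list()
  base <- lapply(muscles, function(mn)
    length_trajectory(model, model$muscles[[mn]], motion, samples)$length_mm)
  names(base) <- muscles
  for (param in parameters) {
    for (d in deltas) {
      pert <- perturb_model(model, param, d)
      for (mn in muscles) {
        tr <- length_trajectory(pert, pert$muscles[[mn]], motion, samples)$length_mm
        rel <- max(abs(tr - base[[mn]]) / base[[mn]]) * 1000
        rows[[length(rows) + 1L]] <- data.frame(
          muscle = mn, parameter = param, delta_pct = 100 * d,
          max_rel_change_permille = rel)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_report", class(out))
  out
}

perturb_model <- function(model, param, delta) {
  if (param %in% c("l_om", "L_ts")) {
    for (mn in names(model$muscles)) {
      f <- if (param == "l_om") "l_om" else "L_ts"
      model$muscles[[mn]]$params[[f]] <- model$muscles[[mn]]$params[[f]] * (1 + delta)
    }
  } else if (param == "wrap_radius") {
    for (mn in names(model$muscles)) {
      w <- model$muscles[[mn]]$path$wraps
      if (length(w)) for (k in seq_along(w))
        model$muscles[[mn]]$path$wraps[[k]]$radii <-
          w[[k]]$radii * (1 + delta)
    }
  } else stop("unknown parameter: ", param)
  model
}
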