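#' Pipeline run configuration
#'
#' One place for every stage parameter so a full run is reproducible from
#' a single object (or its JSON serialization). All stochastic stages draw
#' from streams derived from `seed`.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param synth [synth_config()] for the generators.
#' @param fourier_order Fourier order for refitting the sensor series.
#' @param fit [fit_config()] for the motion fit.
#' @param compare_joints also run the joint-type residual comparison
#'   (slower; default FALSE).
#' @param gains [cmc_gains()].
#' @param simulate_duration_s simulated tracking time (s).
#' @param dt integrator step (s).
#' @param emg_reference experimental RMS pair used in the validation
#'   metrics.
#' @param amplitude_scales amplitude sweep factors.
#' @param sensitivity_deltas parameter sweep deltas (fractions).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("wingflap_run_"),
                            synth = synth_config(seed = seed),
                            fourier_order = 4,
                            fit = fit_config(n_starts = 5, seed = seed + 1L),
                            compare_joints = FALSE,
                            gains = cmc_gains(),
                            simulate_duration_s = 0.1,
                            dt = 1e-3,
                            emg_reference = c(0.1628, 0.3478),
                            amplitude_scales = c(0.4, 0.6, 0.8, 1.0, 1.2),
                            sensitivity_deltas = c(-0.6, -0.4, -0.2, 0.2, 0.4, 0.6)) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, synth = synth,
                 fourier_order = fourier_order, fit = fit,
                 compare_joints = compare_joints, gains = gains,
                 simulate_duration_s = simulate_duration_s, dt = dt,
                 emg_reference = emg_reference,
                 amplitude_scales = amplitude_scales,
                 sensitivity_deltas = sensitivity_deltas),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage from a single configuration: synthetic-data
#' generation (model, posture clouds, sensor series), skeletal motion
#' fitting, Fourier refitting and phase analysis, computed-muscle-control
#' tracking, validation metrics, and both sensitivity analyses. All
#' artifacts are written under `config$out_dir`; a `report.json` collects
#' the key quantities.
#'
#' @param config [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return list with the stage results and `report` (also written to
#'   JSON), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()

  say("[synth] building synthetic wing and motion (seed %d)", config$seed)
  model <- make_synthetic_wing(config$synth)
  motion <- make_default_motion()
  write_wing_model(model, file.path(config$out_dir, "model.json"))
  postures <- c(default_postures(),
                list(folded = list(shoulder = 10, wrist = c(5, -40))))
  pc <- make_posture_clouds(model, postures,
                            noise_sigma = config$synth$cloud_noise_sigma,
                            seed = config$seed + 10L)
  for (cl in pc$clouds)
    write_point_cloud(cl$points, file.path(config$out_dir,
      sprintf("cloud_%s_j%d.ply", cl$bone, cl$posture)))
  series <- make_noisy_angle_series(motion, config$synth)
  utils::write.csv(series, file.path(config$out_dir, "angle_series.csv"),
                   row.names = FALSE)

  say("[fitmotion] fitting joint motion to posture clouds")
  fit <- fit_skeleton_motion(pc, config = config$fit)
  cmp <- NULL
  if (config$compare_joints) {
    say("[fitmotion] joint-type residual comparison")
    cmp <- compare_joint_types(pc, config = config$fit)
    utils::write.csv(cmp$table, file.path(config$out_dir, "joint_residuals.csv"),
                     row.names = FALSE)
  }

  say("[fourier] refitting sensor series (cycles 2..%d)", config$synth$n_cycles - 1)
  sel <- series[series$selected, ]
  dofc <- grep("_deg$", names(sel), value = TRUE)
  refit <- fit_fourier(sel$time_s, as.matrix(stats::setNames(sel[dofc],
                                                             sub("_deg$", "", dofc))),
                       K = config$fourier_order, period_s = motion$period_s)
  export_motion_file(refit$motion, file.path(config$out_dir, "motion.sto"),
                     n_samples = 200)
  phases <- phase_analysis(refit$motion)

  say("[simulate] computed muscle control, %.2f s", config$simulate_duration_s)
  cmc <- cmc_simulate(model, motion, gains = config$gains,
                      duration = config$simulate_duration_s, dt = config$dt)
  utils::write.csv(data.frame(time_s = cmc$time, cmc$activations,
                              check.names = FALSE),
                   file.path(config$out_dir, "activations.csv"),
                   row.names = FALSE)

  say("[analyze] validation metrics")
  shoulder_pair <- c("M. subscapularis", "M. scapulotriceps")
  sim_rms <- vapply(shoulder_pair, function(m) rms(cmc$activations[, m]), 0)
  metrics <- comparison_metrics(sim_rms, config$emg_reference)

  say("[sensitivity] parameter and amplitude sweeps")
  sens <- parameter_sensitivity(model, motion,
                                parameters = c("l_om", "L_ts", "wrap_radius"),
                                deltas = config$sensitivity_deltas)
  utils::write.csv(sens, file.path(config$out_dir, "sensitivity.csv"),
                   row.names = FALSE)
  amp <- amplitude_study(model, motion, scales = config$amplitude_scales)
  amp_rows <- do.call(rbind, lapply(names(amp), function(mn)
    do.call(rbind, lapply(amp[[mn]], function(r) data.frame(
      muscle = mn, scale = r$scale,
      periods = paste(apply(r$periods, 1, function(x)
        sprintf("%g-%g", x[1], x[2])), collapse = ", "),
      avg_error_pct = r$avg_error_pct)))))
  utils::write.csv(amp_rows, file.path(config$out_dir, "amplitude_study.csv"),
                   row.names = FALSE)

  hill_rows <- sens$parameter %in% c("l_om", "L_ts")
  report <- list(
    seed = config$seed,
    fit_residual_mm = fit$residual_mm,
    phase = lapply(phases, function(p)
      list(amplitude_deg = p$amplitude_deg, turning_points_pct = p$turning_points)),
    tracking_rms_deg = as.list(cmc$tracking_rms_deg),
    validation = list(sim_rms = as.list(sim_rms),
                      emg_rms = config$emg_reference,
                      MAE = metrics$MAE, PD_pct = metrics$PD_pct,
                      PE_pct = metrics$PE_pct),
    sensitivity = list(
      max_hill_param_change_permille = max(sens$max_rel_change_permille[hill_rows]),
      max_wrap_radius_change_permille = max(sens$max_rel_change_permille[!hill_rows])),
    runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] %.1f s, outputs in %s", report$runtime_s, config$out_dir)
  invisible(list(model = model, motion = motion, fit = fit, compare = cmp,
                 refit = refit, phases = phases, cmc = cmc, metrics = metrics,
                 sensitivity = sens, amplitude = amp, report = report))
}
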