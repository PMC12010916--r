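#' Synthetic-data configuration
#'
#' Collects every knob of the synthetic generators: the seed, bone lengths,
#' cloud sampling density and noise, sensor noise, and the flapping-cycle
#' sampling. Defaults emulate the study conditions: three sensors per wing,
#' eight flapping cycles of which cycles 2..7 are analyzed.
#'
#' @param seed integer RNG seed.
#' @param bone_lengths named vector, mm (humerus, ulna, metacarpus).
#' @param points_per_bone surface samples per bone cloud.
#' @param cloud_noise_sigma isotropic point-cloud noise SD (mm).
#' @param angle_noise_sigma sensor angle noise SD (deg).
#' @param n_cycles number of recorded flapping cycles.
#' @param samples_per_cycle sensor samples per cycle.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         bone_lengths = c(humerus = 75, ulna = 92, metacarpus = 52),
                         points_per_bone = 300L,
                         cloud_noise_sigma = 0.3,
                         angle_noise_sigma = 2,
                         n_cycles = 8L,
                         samples_per_cycle = 100L) {
  stopifnot(points_per_bone > 0, samples_per_cycle > 0, n_cycles > 0,
            cloud_noise_sigma >= 0, angle_noise_sigma >= 0,
            all(bone_lengths > 0))
  structure(list(seed = as.integer(seed), bone_lengths = bone_lengths,
                 points_per_bone = as.integer(points_per_bone),
                 cloud_noise_sigma = cloud_noise_sigma,
                 angle_noise_sigma = angle_noise_sigma,
                 n_cycles = as.integer(n_cycles),
                 samples_per_cycle = as.integer(samples_per_cycle)),
            class = "synth_config")
}

# evaluate `code` under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# uniform sampling of a capsule surface (cylinder + hemispherical caps)
sample_capsule <- function(p0, p1, r, n) {
  axis <- p1 - p0
  L <- sqrt(sum(axis^2))
  if (L <= 0) stop("degenerate bone: zero length")
  u <- axis / L
  B <- triad_from_z(u)                  # columns: e1, e2, u
  area_side <- 2 * pi * r * L
  area_caps <- 4 * pi * r^2
  on_side <- stats::runif(n) < area_side / (area_side + area_caps)
  pts <- matrix(0, n, 3)
  phi <- stats::runif(n, 0, 2 * pi)
  for (i in seq_len(n)) {
    if (on_side[i]) {
      h <- stats::runif(1, 0, L)
      pts[i, ] <- p0 + h * u + r * (cos(phi[i]) * B[, 1] + sin(phi[i]) * B[, 2])
    } else {
      # uniform on sphere, split into the two outward hemispheres
      z <- stats::runif(1, -1, 1)
      s <- sqrt(1 - z^2)
      d <- s * cos(phi[i]) * B[, 1] + s * sin(phi[i]) * B[, 2] + z * u
      pts[i, ] <- (if (z >= 0) p1 else p0) + r * d
    }
  }
  colnames(pts) <- c("x", "y", "z")
  pts
}

# shoulder center printed by the motion reconstruction; the wing extends
# along +y from it with realistic falcon bone lengths
shoulder_center <- function() c(-11.2, 0.1, 0.1)

# muscle attachment table, coordinates relative to the shoulder center
# (x lateral, y along the extended wing, z dorsal). Calibrated so that each
# muscle-tendon length range over the default flapping motion matches the
# measured range of the corresponding muscle.
synthetic_muscle_table <- function(lens) {
  E <- c(0, lens[["humerus"]], 0)
  W <- c(0, lens[["humerus"]] + lens[["ulna"]], 0)
  list(
    list(name = "M. subscapularis", bones = c("ground", "humerus"),
         origin = c(0, -6.5, -0.5), insertion = c(0, 7.5, -0.8),
         L_max = 14.6, L_min = 13.7, alpha_deg = 15, mass_g = 1.2,
         wrap = "shoulder_head"),
    # origin offset steeper than the stroke range (atan(1.5/1.2) = 51 deg)
    # keeps the moment arm one-signed across amplitudes up to 1.2
    list(name = "M. scapulotriceps", bones = c("ground", "ulna"),
         origin = c(0, 1.2, 1.5), insertion = c(0, lens[["humerus"]] + 0.35, 0),
         L_max = 74.9, L_min = 73.4, alpha_deg = 0, mass_g = 2.5,
         wrap = NA),
    list(name = "M. extensor digitorum communis", bones = c("humerus", "metacarpus"),
         origin = E + c(0, -5, 3),
         via = list(list(bone = "ulna", pos = W + c(0.5, -2, 0.8))),
         insertion = W + c(1.0, 40.5, 1.0),
         L_max = 139.0, L_min = 136.7, alpha_deg = 10, mass_g = 3.0,
         wrap = NA),
    list(name = "M. flexor carpi ulnaris", bones = c("humerus", "metacarpus"),
         origin = E + c(0, -5, -2), insertion = W + c(-2.5, 8, -1),
         L_max = 105.9, L_min = 103.2, alpha_deg = 0, mass_g = 2.2,
         wrap = NA),
    list(name = "M. extensor metacarpi radialis", bones = c("humerus", "metacarpus"),
         origin = E + c(3, -1, 0), insertion = W + c(6.5, 5, 0),
         L_max = 97.9, L_min = 89.9, alpha_deg = 0, mass_g = 2.8,
         wrap = NA),
    list(name = "M. extensor carpi ulnaris", bones = c("ulna", "metacarpus"),
         origin = c(-1, lens[["humerus"]] + 3, -2),
         via = list(list(bone = "ulna", pos = W + c(2.5, -1.5, -1))),
         insertion = W + c(4, 14, -1),
         L_max = 105.3, L_min = 100.3, alpha_deg = 0, mass_g = 2.0,
         wrap = NA)
  )
}

#' Build the synthetic six-muscle wing model
#'
#' Constructs the two-bar wing: a fused scapula+coracoid ground body, the
#' humerus (shoulder: revolute flap axis), the ulna carrying the radius
#' (elbow: fixed), and the metacarpus (wrist: universal, flap + fold axes).
#' Six muscle-tendon actuators span the shoulder and wrist; their geometry
#' is calibrated so the length range of each over the default flapping
#' motion matches the measured range, and their Hill parameters (tendon
#' slack length, optimal fiber length) are derived from those ranges with
#' [estimate_tendon_slack()]. Bone surfaces are capsules sampled uniformly.
#'
#' @param config [synth_config()].
#' @return a `wing_model` with attached reference surface clouds.
#' @export
make_synthetic_wing <- function(config = synth_config()) {
  lens <- config$bone_lengths
  S <- shoulder_center()
  E <- S + c(0, lens[["humerus"]], 0)
  W <- E + c(0, lens[["ulna"]], 0)
  TIP <- W + c(0, lens[["metacarpus"]], 0)
  SCAP <- S + c(0, -30, 0)
  surf <- with_seed(config$seed, list(
    ground = sample_capsule(SCAP, S + c(0, -4, 0), 4, config$points_per_bone),
    humerus = sample_capsule(S, E, 3, config$points_per_bone),
    ulna = sample_capsule(E, W, 2.5, config$points_per_bone),
    metacarpus = sample_capsule(W, TIP, 2, config$points_per_bone)
  ))
  bones <- list(
    wing_bone("ground", 0L, 50, bone_frame(SCAP), bone_frame(S), 4, surf$ground),
    wing_bone("humerus", 1L, 6, bone_frame(S), bone_frame(E), 3, surf$humerus),
    wing_bone("ulna", 2L, 5, bone_frame(E), bone_frame(W), 2.5, surf$ulna),
    wing_bone("metacarpus", 3L, 2, bone_frame(W), bone_frame(TIP), 2, surf$metacarpus)
  )
  # dof axes: flap about global +x; fold about global +z (dof order = triad columns)
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  joints <- list(
    joint_spec("shoulder", "revolute", "ground", "humerus", S,
               axes = cbind(ex, ey, ez), dof_labels = "xl_shoulder"),
    joint_spec("elbow", "fixed", "humerus", "ulna", E),
    joint_spec("wrist", "universal", "ulna", "metacarpus", W,
               axes = cbind(ex, ez, -ey), dof_labels = c("xl_wrist", "zl_wrist"))
  )
  wraps <- list(shoulder_head = wrap_object("sphere", "humerus", S, 1.5))
  muscles <- lapply(synthetic_muscle_table(lens), function(m) {
    vias <- if (!is.null(m$via))
      lapply(m$via, function(v) list(bone = v$bone, pos = S + v$pos)) else list()
    pts <- c(list(list(bone = m$bones[1], pos = S + m$origin)),
             vias,
             list(list(bone = m$bones[2], pos = S + m$insertion)))
    w <- if (!is.na(m$wrap)) wraps[m$wrap] else list()
    slack <- estimate_tendon_slack(m$L_min, m$L_max, m$alpha_deg)
    # maximum isometric force from mass-based physiological cross-section:
    # PCSA = m / (rho l_om), specific tension 0.3 N mm^-2, rho = 1.06 mg mm^-3
    pcsa_mm2 <- m$mass_g * 1000 / (1.06 * slack$l_om)
    params <- muscle_params(l_om = slack$l_om, alpha_deg = m$alpha_deg,
                            L_ts = slack$L_ts, F_max = 0.3 * pcsa_mm2)
    wing_muscle(muscle_path(m$name, pts, w), params)
  })
  names(muscles) <- vapply(muscles, `[[`, "", "name")
  wing_model(bones, joints, muscles)
}

#' Packaged default flapping motion
#'
#' The three-dof periodic flapping kinematics: shoulder flap (xl_shoulder),
#' wrist flap (xl_wrist) and wrist fold (zl_wrist), as a Fourier motion.
#' By construction: xl_shoulder decreases on exactly 0-50% of the cycle
#' with 64 deg peak-to-peak amplitude; xl_wrist decreases on 0-47% and
#' 84-100%; zl_wrist spans 75 deg with folding (decreasing) on 34-84%.
#' The asymmetric wrist-flap phase split is encoded exactly by placing the
#' roots of an order-2 trigonometric-polynomial derivative at the printed
#' cycle fractions and integrating.
#'
#' @param period_s flapping period (s); default 0.5.
#' @param wrist_flap_amplitude peak-to-peak xl_wrist amplitude (deg); the
#'   measured series constrains its phase structure, not its printed
#'   amplitude; default 50.
#' @param K Fourier order of the returned motion (higher harmonics zero).
#' @return `fourier_motion` with dofs xl_shoulder, xl_wrist, zl_wrist.
#' @export
make_default_motion <- function(period_s = 0.5, wrist_flap_amplitude = 50, K = 4) {
  stopifnot(K >= 2)
  pad <- function(v) c(v, rep(0, K - length(v)))
  # xl_shoulder: pure cosine, maximum at 0% -> decreasing on 0-50%
  sh <- list(a0 = 0, a = pad(32), b = pad(0))
  # zl_wrist: extrema exactly half a cycle apart (34% and 84%): pure
  # cosine with its maximum at 34% of the cycle; folded = -75 deg
  ph <- 2 * pi * 0.34
  zl <- list(a0 = -37.5, a = pad(37.5 * cos(ph)), b = pad(37.5 * sin(ph)))
  # xl_wrist: asymmetric extrema (minimum at 47%, maximum at 84%)
  xw <- asymmetric_stroke_dof(0.47, 0.84, wrist_flap_amplitude)
  wr <- list(a0 = 0, a = pad(xw$a), b = pad(xw$b))
  fourier_motion(period_s, list(xl_shoulder = sh, xl_wrist = wr, zl_wrist = zl))
}

# order-2 trigonometric dof with derivative roots exactly at cycle
# fractions f_min (minimum) and f_max (maximum) and no other turning
# points; amplitude is the peak-to-peak range in degrees. The derivative
# is chosen in the 2-parameter null space of the root constraints as the
# member maximizing the margin to spurious roots (deterministic scan).
asymmetric_stroke_dof <- function(f_min, f_max, amplitude) {
  basis <- function(p) c(cos(2 * pi * p), sin(2 * pi * p),
                         cos(4 * pi * p), sin(4 * pi * p))
  M <- rbind(basis(f_min), basis(f_max))
  ns <- svd(M, nv = 4)$v[, 3:4]
  g <- seq(0, 1, length.out = 2001)[-2001]
  vfun <- function(w) colSums(w * sapply(g, basis))
  best <- NULL
  vmid <- function(w, p) sum(w * basis(p))
  m_in <- (f_min + f_max) / 2
  m_out <- ((f_max + 1 + f_min) / 2) %% 1
  for (t in seq(0, pi, length.out = 361)) {
    w <- cos(t) * ns[, 1] + sin(t) * ns[, 2]
    v <- vfun(w)
    changes <- sum(diff(sign(v)) != 0) + (sign(v[1]) != sign(v[length(v)]))
    if (changes != 2) next
    if (vmid(w, m_in) < 0) w <- -w
    if (vmid(w, m_out) > 0) next
    margin <- min(abs(c(vmid(w, m_in), vmid(w, m_out))))
    if (is.null(best) || margin > best$margin) best <- list(w = w, margin = margin)
  }
  if (is.null(best)) stop("no valid stroke profile for the requested phases")
  w <- best$w
  # integrate the derivative termwise: int cos(2 pi k p) = sin(..)/(2 pi k)
  a <- c(-w[2] / (2 * pi), -w[4] / (4 * pi))
  b <- c(w[1] / (2 * pi), w[3] / (4 * pi))
  evalth <- function(p) a[1] * cos(2 * pi * p) + a[2] * cos(4 * pi * p) +
    b[1] * sin(2 * pi * p) + b[2] * sin(4 * pi * p)
  rng <- range(evalth(seq(0, 1, length.out = 4001)))
  s <- amplitude / diff(rng)
  list(a = a * s, b = b * s)
}

#' Default wing postures for motion reconstruction
#'
#' Three postures emulating the categorized wing states: extension (the
#' reference), upward flap and downward flap, as joint-angle sets.
#'
#' @return named list of angle lists (degrees) usable with
#'   [forward_kinematics()].
#' @export
default_postures <- function() {
  list(extension = list(shoulder = 0, wrist = c(0, 0)),
       upward = list(shoulder = 30, wrist = c(15, 0)),
       downward = list(shoulder = -30, wrist = c(-15, -20)))
}

#' Generate multi-posture bone point clouds
#'
#' Applies forward kinematics to each bone's reference surface cloud for
#' each posture and adds isotropic Gaussian noise, returning the observed
#' clouds together with the ground-truth transforms so downstream fits are
#' recovery tests.
#'
#' @param model `wing_model` with bone surfaces.
#' @param postures list of >= 2 angle sets (posture j = 1 is the reference).
#' @param noise_sigma isotropic noise SD (mm).
#' @param seed RNG seed.
#' @param bones bone subset (default: all moving bones plus ground).
#' @return list with `clouds` (list of `posture_cloud`: bone, bone_index,
#'   posture, points) and `truth` (per-posture fk transforms).
#' @export
make_posture_clouds <- function(model, postures = default_postures(),
                                noise_sigma = 0, seed = 1L,
                                bones = names(model$bones)) {
  if (length(postures) < 2) stop("need at least 2 postures")
  if (is.null(names(postures))) names(postures) <- paste0("posture", seq_along(postures))
  truth <- lapply(postures, function(p) forward_kinematics(model, p))
  clouds <- list()
  with_seed(seed, {
    for (j in seq_along(postures)) {
      for (b in bones) {
        ref <- model$bones[[b]]$surface
        if (is.null(ref) || nrow(ref) == 0)
          stop("bone '", b, "' has an empty reference cloud")
        pts <- apply_transform(truth[[j]][[b]], ref)
        if (noise_sigma > 0)
          pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sigma), nrow(pts), 3)
        clouds[[length(clouds) + 1L]] <- structure(
          list(bone = b, bone_index = model$bones[[b]]$index,
               posture = j, posture_name = names(postures)[j], points = pts),
          class = "posture_cloud")
      }
    }
  })
  list(clouds = clouds, truth = truth)
}

#' Simulated sensor angle series
#'
#' Samples a Fourier motion over `n_cycles` flapping cycles at
#' `samples_per_cycle` and adds i.i.d. Gaussian sensor noise. Cycles 2 to
#' `n_cycles - 1` are flagged as selected for analysis (the first and last
#' recorded cycles are discarded for continuity).
#'
#' @param motion `fourier_motion`.
#' @param config [synth_config()] (uses angle_noise_sigma, n_cycles,
#'   samples_per_cycle, seed).
#' @return data.frame with time_s, cycle, cycle_fraction, selected, and one
#'   `<dof>_deg` column per dof; the noise-free motion is attached as
#'   attribute `truth`.
#' @export
make_noisy_angle_series <- function(motion, config = synth_config()) {
  stopifnot(config$n_cycles >= 1)
  n <- config$n_cycles * config$samples_per_cycle
  t <- (seq_len(n) - 1) / config$samples_per_cycle * motion$period_s
  ang <- evaluate_motion(motion, t)$angles
  noisy <- with_seed(config$seed,
                     ang + matrix(stats::rnorm(length(ang), 0, config$angle_noise_sigma),
                                  nrow(ang), ncol(ang)))
  cyc <- as.integer(floor((seq_len(n) - 1) / config$samples_per_cycle)) + 1L
  out <- data.frame(time_s = t,
                    cycle = cyc,
                    cycle_fraction = ((seq_len(n) - 1) %% config$samples_per_cycle) /
                      config$samples_per_cycle,
                    selected = cyc >= 2L & cyc <= config$n_cycles - 1L)
  for (nm in colnames(ang)) out[[paste0(nm, "_deg")]] <- noisy[, nm]
  attr(out, "truth") <- motion
  out
}
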