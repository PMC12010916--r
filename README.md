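# wingflap

Musculoskeletal modeling and computed muscle control of raptor wing
flapping.

Raptor wings morph: the shoulder flaps the whole wing while the wrist
simultaneously flaps and folds the outer wing, and a small set of
shoulder and forearm muscles drives both. Direct measurement on raptors
is rarely possible, so this package provides the full simulation route
instead, for biomechanists and bio-inspired-flight researchers: a two-bar
musculoskeletal wing model (fused scapula+coracoid ground, humerus,
ulna/radius with a fused elbow, metacarpus), reconstruction of joint
kinematics from multi-posture bone point clouds, periodic joint
trajectories as Fourier series, Hill-type muscle-tendon actuators, and a
computed-muscle-control loop — plus a synthetic-data generator that
emulates every measured input with known ground truth, so the whole
pipeline is testable end to end.

The core pieces, in the field's standard notation:

* **Skeletal motion reconstruction.** Per-bone rigid motions
  L_curr = R L_init + T are fitted to posture clouds by minimizing the
  mean point distance (the registration residual) over the joint
  variables q_i = [Center_i, Direction_i, Rotation_i], with fixed /
  revolute / universal / spherical / spiral joint constraint equations
  satisfied exactly by parameterizing transforms on the constraint
  manifold. Multi-start local optimization plus a closed-form (Kabsch)
  informed start; candidate joint types are compared by residual.
* **Flapping kinematics.** Each dof is a truncated Fourier series
  a0 + Σ a_k cos(2πkt/T) + b_k sin(2πkt/T) with analytic derivatives;
  phase analysis locates downstroke/upstroke and fold intervals from the
  derivative's sign structure. The packaged default motion reproduces the
  measured phase structure exactly: 64° shoulder amplitude with the
  downstroke on 0–50%, wrist flap decreasing on 0–47% and 84–100%, and a
  75° wrist fold on 34–84% of the cycle.
* **Muscle mechanics.** Activation da/dt = (u−a)/τ with τ_act/τ_deact;
  Hill-type force F_max[a·fl(l̃)·fv(ṽ) + fp(l̃)]cos α with an elastic
  tendon solved to equilibrium; path lengths with sphere / cylinder /
  ellipsoid wrapping; moment arms as tendon excursions −∂L_mt/∂q; tendon
  slack length estimated from the motion's length extremes.
* **Computed muscle control.** Per control window: desired accelerations
  q̈* = q̈_ref + k_v(q̇_ref−q̇) + k_p(q_ref−q); static optimization
  min Σa² subject to M q̈* = G + C + R f̄(a) (reserves heavily penalized);
  excitation feedback u = a* + k_u(a*−a); forward integration of
  q̈ = M⁻¹(G + C + R f_m + F_ext).
* **Analyses.** Muscle-activity RMS validation metrics (MAE/PD/PE on
  max-normalized pairs), muscle-function studies across flapping
  amplitudes 0.4–1.2, and parameter sensitivity sweeps (±20/40/60%) that
  demonstrate the geometric insensitivity of muscle-tendon length to Hill
  parameters, with a wrap-radius positive control.

## Worked example

```r
library(wingflap)

# the six-muscle synthetic wing and the default flapping motion
model  <- make_synthetic_wing(synth_config(seed = 1))
motion <- make_default_motion()

# phase structure of the packaged motion
ph <- phase_analysis(motion)
ph$xl_shoulder$amplitude_deg   # 64
ph$zl_wrist$decreasing         # fold interval: 34 -> 84 (% of cycle)

# recover joint kinematics from noiseless posture clouds
postures <- c(default_postures(),
              list(folded = list(shoulder = 10, wrist = c(5, -40))))
pc  <- make_posture_clouds(model, postures, noise_sigma = 0, seed = 2)
fit <- fit_skeleton_motion(pc, config = fit_config(n_starts = 3, seed = 4))
fit$residual_mm                     # ~1e-13 (exact-model limit)
fit$joints$shoulder$angles_deg[, 1] # 30, -30, 10 (truth: 30, -30, 10)

# muscle-tendon length trajectory and contraction periods
tr <- length_trajectory(model, model$muscles[["M. extensor metacarpi radialis"]],
                        motion, samples = 200)
range(tr$length_mm)        # 88.6 .. 97.9 mm (dissection range: 89.9 .. 97.9)
contraction_periods(tr)    # shortening intervals, % of cycle

# validation metrics from an activity-RMS pair and an EMG-RMS pair
comparison_metrics(c(16, 37), c(0.1628, 0.3478))
#> MAE = 0.01783, PD = 2.46%, PE = 7.62%

# Hill parameters do not move muscle-tendon length (geometry theorem);
# a wrap-radius edit does (positive control)
parameter_sensitivity(model, motion, parameters = c("l_om", "L_ts"),
                      deltas = -0.6, samples = 200)
#> max_rel_change_permille: all 0
```

The numbers shown are what the code prints: the fit residual is at the
numerical floor because the clouds are noiseless and the parameterization
is exact; the PE of 7.62% is the max-normalized proportional error of the
two RMS pairs; the zero sensitivity is exact because fiber/tendon
parameters never enter the path geometry.

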