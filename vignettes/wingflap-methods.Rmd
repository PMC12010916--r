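---
title: "Modeling raptor wing flapping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling raptor wing flapping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingflap)
```

wingflap models the flapping of a raptor wing with a deliberately small
musculoskeletal system: a two-bar skeleton (inner bar: humerus; outer bar:
forearm plus manus, with the elbow fused), a revolute flap axis at the
shoulder, a universal flap + fold joint at the wrist, and six muscle-tendon
actuators spanning those joints. This vignette explains the model, the
algorithms, and every place where the design was genuinely open and a
choice had to be made.

## The wing model and its conventions

Positions are millimetres, masses grams, angles degrees at every interface
(radians internally). The global frame is right-handed, `x` lateral, `y`
along the extended wing, `z` dorsal. The fused scapula + coracoid is the
ground body; rotations of the humerus, ulna/radius and metacarpus are
expressed relative to it.

Each joint degree of freedom is an axis-angle rotation about a fixed
reference axis through the joint center, applied in the order the dof
labels are listed; a universal joint is two successive rotations about the
first two columns of its axis triad. Forward kinematics composes these
rotations down the chain (product of exponentials with the reference
configuration), so the ground transform is always the identity, joint
centers are fixed points of their own joint's motion, and bone lengths are
conserved in every pose — properties the test suite asserts directly.

The radius is carried as geometry on the ulna body and takes no part in
fitting or dynamics; the elbow is a fixed joint, which makes the
humerus–ulna pair the single inner bar of the two-bar model.

## Synthetic data: what it emulates and what it does not

No skeletal scans or sensor recordings are distributed with the package,
so a synthetic-data module generates every input the downstream stages
need, with known ground truth:

* **Bone surfaces** are capsules (cylinders with hemispherical caps)
  sampled uniformly by surface area. Real bone surfaces are far richer;
  for rigid-motion fitting only the rigidity of the cloud matters, so a
  capsule is sufficient and keeps the generator transparent.
* **Posture clouds** are forward-kinematics copies of those surfaces in
  several postures plus isotropic Gaussian noise. Point correspondence is
  preserved, which real scan data would not provide; a nearest-neighbor
  residual is available for unmatched clouds, but all recovery experiments
  use matched clouds.
* **Sensor angle series** are the default motion sampled over eight
  flapping cycles with i.i.d. Gaussian noise (default SD 2 deg); cycles
  2–7 are flagged for analysis, mirroring the practice of discarding the
  first and last recorded cycles.

Passing tests on these data demonstrate that the algorithms recover what
they are designed to recover under the stated noise models. They say
nothing about segmentation error, soft-tissue artefact, sensor drift, or
aerodynamic loading — none of which the generator emulates.

A note on geometry: the reconstructed joint-center coordinates for the
shoulder, `(-11.2, 0.1, 0.1)`, and wrist, `(-17.3, 81.4, 39.2)`, imply a
shoulder-to-wrist span of about 90 mm, which cannot be reconciled with the
dissected muscle-tendon lengths (up to 139 mm between the distal humerus
and the manus) under any single millimetre scale. The synthetic wing
therefore keeps the shoulder at the reconstructed coordinates but uses
realistic falcon bone lengths — humerus 75 mm, ulna 92 mm, metacarpus
52 mm — so that the measured muscle length ranges are achievable with
near-straight paths. The generator's muscle attachments were calibrated
once so that each muscle's length range over the default motion matches
the dissection values (within a few percent; the test suite enforces
±15%), and are fixed constants of the package.

## The default flapping motion

Joint trajectories are truncated Fourier series, T-periodic with analytic
term-wise derivatives. The packaged default motion encodes the measured
phase structure of the flap:

* `xl_shoulder`: pure cosine, 64 deg peak-to-peak, decreasing (downstroke)
  on exactly 0–50% of the cycle.
* `zl_wrist`: pure cosine with its maximum placed at 34% of the cycle and
  a 75 deg range; folding is the decreasing phase, 34–84%. (The sign
  convention — folding as a decrease, 0 = fully extended — is the
  package's choice; the measurements constrain only the interval.)
* `xl_wrist`: the downstroke–upstroke structure is asymmetric (decreasing
  on 0–47% and 84–100%). A truncated Fourier fit of any piecewise profile
  shifts the turning points: projecting a piecewise-cosine stroke onto
  even ten harmonics leaves the 47% boundary at 46.5%. Instead the dof's
  *derivative* is constructed as an order-2 trigonometric polynomial with
  roots placed exactly at 0.47 and 0.84 (the two-dimensional null space of
  the root constraints is scanned deterministically for the member with no
  spurious roots and the largest sign margin) and integrated term-wise.
  The printed phase boundaries are then exact at any sampling density.
  The peak-to-peak amplitude of this dof is not constrained by the
  measurements; the default is 50 deg, a mid-range value between the
  shoulder flap (64 deg) and typical distal-joint excursions.

The flapping period defaults to 0.5 s (2 Hz). Manually actuated specimen
motion carries no usable frequency information, so the period is a free
parameter; 2 Hz is slow enough for the muscle model's force–velocity range
at the default fiber lengths.

`phase_analysis()` locates stroke boundaries as sign changes of the
analytic derivative, bracketed on a 1000-sample grid and refined by
bisection to 1e-6 cycle fraction. Amplitudes are max − min at the turning
points, so they agree with dense evaluation to the same tolerance.

## Reconstructing joint motion from posture clouds

The registration residual (mean point distance between a transformed
reference cloud and an observed cloud) is minimized over joint centers,
axes and per-posture angles, summed over all moving bones and postures,
for a selectable joint-kind pair (shoulder × wrist from {revolute,
universal, spherical}).

**Constraints by construction, not by penalty.** Transforms are
parameterized directly on the constraint manifold — each joint contributes
its center, its axis parameters, and per-posture angles, and bone
transforms are compositions of rotations about those centers. Every
kind-specific constraint is therefore satisfied exactly, the optimizer
never trades residual against violation, and the nested-dof ordering
(spherical ≤ universal ≤ revolute residual on the same data) can be
guaranteed by warm-starting richer kinds from the optima of poorer ones
(a revolute optimum embeds exactly into the universal parameterization,
universal into spherical). The kind-specific constraint equations are
still implemented (`joint_constraint_residual()`) and evaluated on fit
results as a diagnostic.

**Initialization.** Besides the configurable random multi-start (centers
near the child-bone centroid, axes uniform on the sphere, angles ±45 deg),
one *informed* start is derived in closed form: per-bone Kabsch
registration of the matched clouds gives exact per-posture transforms in
the noiseless case; the joint center then solves the stacked fixed-point
system (I − R_p) c = t_p in the least-squares sense, the revolute axis is
the rotation axis, and the universal axis pair is recovered from the
relative rotations by an alternating smallest-singular-vector scheme
seeded over a Fibonacci sphere grid (the bilinear constraint
a1' R_p a2 = 0 admits spurious stationary pairs, so candidates are scored
by how well the two-axis Euler decomposition reconstructs the rotations).
On noiseless data this start is already the optimum to machine precision.

**Identifiability.** Two caveats are inherent to the problem, not the
implementation. A revolute center is identifiable only up to sliding along
its axis, so center recovery is assessed as distance to the true axis
line. A universal joint observed in only two non-reference postures has a
one-parameter family of exact axis decompositions (seven unknowns against
six rotation constraints); recovery experiments therefore use three
non-reference postures (extension, upward flap, downward flap, plus a
folded pose), and per-posture rotations are compared as composed rotations,
which are identifiable regardless.

Angles are reported wrapped to (−180, 180] and axes signed so the largest
component of the axis triple is positive; recovered and true axes may
still differ by a simultaneous axis flip and angle negation, which leaves
the composed rotation unchanged.

The optimizer is BFGS with numeric gradients, 200 iterations per start,
relative tolerance 1e-12 on the mean squared residual, with a
finer-step polish pass; a start achieving an objective below 1e-16 mm²
(an exact fit) short-circuits the remaining starts.

## Muscle geometry and mechanics

**Paths and wrapping.** A muscle path is an ordered list of bone-fixed
points. Segment lengths are straight-line distances unless a segment
intersects one of the muscle's wrap objects, in which case the shortest
tangent–arc–tangent path is substituted: closed form for spheres, the
unwrapped-plane construction for cylinders (the planar circle wrap plus
the axial component combined pythagoreanly, since the geodesic unrolls to
a straight line), and an iterative 50-node midpoint-relaxation path for
ellipsoids. Engagement is automatic per pose — a segment that clears the
object is left straight — which produces the pose-dependent wrap
engagement visible in the shoulder muscle's length trajectory. An
attachment point inside a wrap object is an error.

**Moment arms** are tendon excursions, −∂L/∂q, by central finite
difference with a 1e-4 rad step; a path that does not cross a dof's joint
(detected from the chain topology) returns exactly zero. For a straight
path over a revolute joint this agrees with the geometric perpendicular
distance to about 1%, and halving the step changes the value by far less
than the geometric error, both asserted in tests.

**Hill model.** Activation follows first-order dynamics with separate
time constants (defaults tau_act = 10 ms, tau_deact = 40 ms, standard
lumped values), integrated exactly as an exponential update and clamped to
[0, 1]. The contractile element uses a Gaussian active force–length curve
fl = exp(−(l̃−1)²/0.45), an exponential passive curve normalized to reach
1 at 60% stretch, and a hyperbolic force–velocity curve (maximum
shortening velocity 10 optimal lengths/s, eccentric plateau 1.8); the
tendon is linear with 3.3% strain at maximum isometric force. Fiber and
tendon lengths are partitioned by solving the elastic equilibrium (tendon
force = fiber force along the tendon) with a bracketed root finder to
1e-12; an empty bracket falls back to the rigid-tendon model and says so.
The pennation angle is treated as constant. These curve shapes are the
package's defaults in the lumped-parameter tradition; the measurements
name the properties but not the curves.

**Tendon slack length** is estimated from the two length extremes of the
motion by solving L_mt = L_ts (1 + ε) + l̃ l_om cos α at both extremes for
(L_ts, l_om), with default normalized fiber lengths 0.85 and 1.05 and
default strains zero. The zero-strain default matters: the measured
muscle-tendon excursions (1–9% of length) are of the same order as peak
tendon strain, so assuming the tendon ramps from slack to fully loaded
across the stroke makes the linear system infeasible for the
low-excursion muscles. Users can supply non-zero strains where the
excursion supports them.

**Maximum isometric forces** are not measured; defaults scale with a
mass-based physiological cross-section (muscle mass / (density × optimal
fiber length), specific tension 0.3 N/mm²) from nominal muscle masses.
No headline analysis depends on them.

Muscle-tendon length trajectories depend only on the path geometry and the
joint motion — optimal fiber length and tendon slack length never enter
`path_length()`. The parameter-sensitivity sweep therefore returns
*identically zero* change for those parameters, a code-level theorem the
sensitivity report demonstrates empirically; a wrap-object radius sweep is
included as a positive control that the probe detects genuine geometric
edits.

## Forward dynamics and computed muscle control

Generalized accelerations follow q̈ = M(q)⁻¹(G + C + R f_m + F_ext), with
the mass matrix and bias terms assembled by recursive Newton–Euler over
the dof chain (bones fused across fixed joints into composite links; bone
inertia as a solid cylinder between the bone-end frames; gravity entering
through the base acceleration; internal SI units). The implementation is
validated against the closed-form compound pendulum and conserves energy
to 0.1% over a second of unforced swing.

The control loop runs four stages per window: desired accelerations
q̈* = q̈_ref + k_v(q̇_ref − q̇) + k_p(q_ref − q) with the reference evaluated
one window ahead; static optimization minimizing Σa² with per-muscle force
linearized in activation at the current state and the acceleration match
enforced by a heavy quadratic penalty (the residual is the reserve usage,
reported so tests can assert it stays near zero); linear excitation
feedback u = a* + k_u(a* − a) clamped to [0, 1]; and forward integration
of the coupled activation and rigid-body dynamics over the window
(adaptive Runge–Kutta 4/5 with the step bounded by `dt`).

**Gains.** The defaults are k_p = 900 s⁻², k_v = 60 s⁻¹ (critically
damped, k_v² = 4 k_p), k_u = 5, window 5 ms. The excitation gain deserves
explanation: with first-order activation dynamics, driving a to a* within
one window of length w requires u ≈ (a* − a e^{−w/τ})/(1 − e^{−w/τ}),
which is exactly the stage-3 law with k_u = e^{−w/τ}/(1 − e^{−w/τ}) —
about 3.5 for the deactivation time constant at w = 10 ms. Small k_u
(≪ 1) leaves the 40 ms deactivation lag uncompensated inside the loop; on
the antagonist benchmark that raises tracking error from under a degree to
tens of degrees. The default k_u = 5 slightly over-drives and relies on
the [0, 1] clamp, giving near-deadbeat activation tracking in both
directions.

The single-dof antagonist benchmark (`make_antagonist_benchmark()`) is a
rod on a revolute joint driven by an equal, opposite muscle pair, with
joint viscous damping chosen to dominate inertia at flapping frequencies
(0.01 N m s against a peak inertial torque an order of magnitude smaller
at 1 Hz). Damping dominance makes the torque demand co-sign with velocity,
so each muscle's activity bursts coincide with its shortening phases —
the operational link between activation and contraction that the analyses
rely on. In an inertia-dominated regime that alignment genuinely breaks
(deceleration demands eccentric antagonist work), which is a property of
the mechanics, not a failure of the controller.

## Analyses

* `rms()` is the plain root mean square.
* `comparison_metrics()` max-normalizes a simulated RMS pair and an
  experimental RMS pair — making the comparison invariant to the units of
  either source — and reports MAE (mean absolute difference of the
  normalized pairs), PD (MAE over the mean normalized level, percent) and
  PE (difference of the non-maximal normalized elements relative to the
  experimental one, percent). PE has a unique standard reading and is the
  metric the package's acceptance checks pin down; MAE and PD are
  implemented under the documented definitions above, which need not
  coincide with other conventions (sum- or mean-normalization would give
  different MAE/PD values from the same inputs).
* `amplitude_study()` scales every dof's harmonic content (cycle mean and
  period preserved) over 0.4–1.2, recomputes length trajectories and
  contraction periods, and reports the mean absolute boundary shift
  against unit scale. Contraction periods are where the smoothed (order-6
  Fourier refit) trajectory strictly decreases, with boundaries reported
  to 0.5% cycle resolution; a differing interval count is reported as a
  structural change rather than averaged. A muscle spanning only the
  shoulder, whose length responds monotonically to a single cosine dof,
  keeps its boundaries pinned at the stroke reversals across all
  amplitudes — the geometric mechanism behind amplitude-robust activation
  periods.

## Problem sizes and tolerances

The test suite and reproduction script run on deliberately modest sizes
chosen as sufficient for the properties they demonstrate: 40–150 surface
points per bone for the registration experiments, 200–1000 trajectory
samples per cycle, 1.5 s of benchmark tracking at a 5 ms control window,
and 2–5 optimizer starts where the informed start is available. Key
tolerances: orthonormality and composition 1e-9; phase boundaries 1e-6
cycle fraction; equilibrium residual 1e-8 of maximum force; noiseless
registration residual below 1e-6 mm; angle recovery 0.1 deg and center
recovery 0.1 mm.

## Known limitations

Joints are ideal revolute/universal pairs — no cartilage deformation,
ligament elasticity or translation; the elbow is fused; aerodynamic and
other external loads default to zero; pennation is constant; activation
is a scalar per muscle. The synthetic wing is calibrated to measured
muscle length *ranges*, not to subject-specific attachment anatomy, so
its moment-arm profiles are plausible rather than measured. Conclusions
about a real wing require real geometry in place of the generator's.
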