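Package: wingflap
Title: Musculoskeletal Modeling and Computed Muscle Control of Raptor Wing Flapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing and simulating the flapping motion of a
    raptor wing with a two-bar musculoskeletal model. Provides rigid-body
    kinematics of the shoulder-elbow-wrist chain, constrained point-cloud
    registration that recovers joint centers, axes and rotation angles from
    multi-posture bone point clouds, Fourier-series representations of
    periodic joint trajectories with phase analysis, Hill-type muscle-tendon
    actuators with geometric path wrapping and moment arms, a computed
    muscle control loop (desired accelerations, static optimization,
    excitation feedback, forward integration), and the downstream analyses:
    muscle-activity RMS validation metrics, amplitude-scaled muscle-function
    studies, and parameter sensitivity sweeps. A synthetic-data generator
    emulates every measured input (bone point clouds, sensor angle series,
    six-muscle wing model) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
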