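Package: joyreach
Title: Closed-Loop Simulation and Kinematic Analysis of Mouse Joystick
    Reaching Tasks
Version: 0.1.0
Authors@R:
    person("Morgan", "Avery", email = "mavery.neuro@posteo.net",
           role = c("aut", "cre"))
Description: A software twin of an open-source head-fixed mouse joystick
    platform.  Provides tick-based finite-state machines for four operant
    reaching tasks (basic center-out, variable-amplitude operant, cued
    reaction-time, and a direction-dependent two-armed bandit), a synthetic
    mouse that closes the loop with minimum-jerk reaches, baseline jitter,
    postural blips and rev-up pre-movements, an offline reach-segmentation
    and kinematics pipeline (threshold-crossing detection expanded forward
    and backward in time, peak amplitude, outward velocity, duration,
    inter-reach intervals, reaction times), an automated shaping scheduler
    that escalates reward threshold and delay across sessions, and
    round-trip session-log CSV I/O with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    data.table,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
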