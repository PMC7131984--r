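# joyreach

Closed-loop simulation and kinematic analysis of joystick reaching tasks
for head-fixed mice.

Joystick manipulanda give rodent motor-control and decision-making
experiments what lever presses cannot: a continuous, millisecond-resolution
x–y readout of limb position, usable both for rich offline kinematics and
for triggering stimulation in closed loop. `joyreach` is a pure-software
twin of such a platform, for people who build, test or analyze these
experiments without an animal or a rig in the loop: task designers
validating schedule logic, analysts developing segmentation pipelines
against ground truth, and methods work that needs reproducible session
logs at will.

The package provides:

* **Task engine** — tick-based (1 kHz) finite-state machines for four
  operant reaching tasks: basic center-out, variable-amplitude operant
  (VAO), cued reaction-time, and a direction-dependent two-armed bandit.
  The reward rule is the radial displacement from baseline,
  `d = sqrt((x - x0)^2 + (y - y0)^2)`, against an amplitude threshold
  `theta`; reward follows the crossing after a 1-s delay, trials are
  separated by a fixed 3-s inter-trial interval, and anticipatory
  (pre-cue) reaches earn a 5000-ms timeout with a randomized restart ITI.
* **Synthetic mouse** — closes the loop: minimum-jerk out-and-back
  reaches (`A(10 tau^3 - 15 tau^4 + 6 tau^5)` per half-movement, peak
  speed `1.875 A / D`), Poisson initiations, baseline jitter,
  sub-threshold postural "blips", opposite-direction "rev-up"
  pre-movements, cue-locked latencies with occasional anticipation, and a
  win-stay/lose-shift bandit policy.
* **Reach analysis** — offline segmentation that works forward and
  backward in time from minimal-amplitude threshold crossings to reach
  initiation/termination, then extracts peak amplitude, peak outward
  velocity, duration, direction, inter-reach intervals, reaction times
  (RTs above 5 s omitted) and session summaries including the expert
  criterion (>100 rewarded reaches at the 0.9-cm threshold).
* **Automated trainer** — the shaping schedule: two 30-min sessions/day
  for three days then one, threshold escalating 0.1 → 0.9 cm at ≤ 1 mm
  per day once the movement–water association is acquired, reward delay
  500 ms → 1 s at 50 ms per day.
* **Session I/O and CLI** — bit-exact round-trip session CSVs with typed
  event logs, JSON configs, and `run | analyze | train | summarize |
  fixtures` subcommands.

See `vignettes/joyreach-methods.Rmd` for the models, parameter tables and
the design decisions taken where the original platform leaves things
open.

## Worked example

Simulate a 30-min expert-level center-out session, segment the trace at
the task threshold and summarize it:

```r
library(joyreach)

cfg <- task_config("center_out", amp_threshold = 0.9)
rec <- run_session(cfg, agent_params(), seed = 42)
rec
#> <session_record> center_out | 1800000 samples | 629 events | 157 rewards

reaches <- detect_reaches(rec$series, cfg$baseline,
                          segmentation_params(detect_threshold = 0.9))
reaches <- mark_rewarded(reaches, rec$events)
session_summary(rec, reaches)
#> <session_summary> 215 reaches | 157 rewarded | 0 punished | median RT - ms | expert: TRUE

head(as.data.frame(reaches)[, 1:6], 3)
#>   onset_ms offset_ms amplitude_cm peak_velocity_cm_s duration_ms direction_rad
#> 1    18979     19449        1.354              70.13         470         1.499
#> 2    24464     24758        1.676              94.21         294        -1.959
#> 3    46400     46743        1.437              73.27         343         1.118
```

The session produced 157 rewarded reaches at the 0.9-cm threshold, so the
expert criterion (>100 at ≥0.9 cm) is met. The 215 detected reaches
include supra-threshold movements made during inter-trial intervals,
which earn no reward; amplitudes cluster around the agent's 1.2-cm mean,
and the ~70–95 cm/s peak outward velocities follow from the minimum-jerk
profile at those amplitudes and durations. Median inter-reach interval
here is 6.5 s — the 3-s ITI plus the reward delay and the mouse's own
pacing put a floor under it.

The same flow from a shell:

```sh
Rscript -e 'joyreach::joyreach_cli()' run --config task.json --seed 7 --out s.csv
Rscript -e 'joyreach::joyreach_cli()' analyze --in s.csv --out reaches.csv,summary.json
Rscript -e 'joyreach::joyreach_cli()' train --days 21 --seed 1 --out progression.csv
```

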