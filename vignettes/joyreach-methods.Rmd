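---
title: "joyreach: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{joyreach: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`joyreach` is a software twin of an open-source joystick platform for
head-fixed mice: a tick-based task engine for four operant reaching
tasks, a synthetic mouse that closes the loop, an offline
reach-segmentation and kinematics pipeline, and an automated shaping
scheduler. This vignette records the underlying models, the parameters
that matter, and the choices made where the original system leaves the
design open.

## The task engine

Every variant shares one reward rule: the radial (Euclidean) displacement
of the joystick from its resting **baseline**,
$d(t) = \sqrt{(x - x_0)^2 + (y - y_0)^2}$, is compared against an
**amplitude threshold** (cm). The engine is a finite-state machine
advanced once per sample at a 1 kHz tick (`tick_ms = 1`); all durations
are snapped to the tick grid.

* **center_out** — while *armed*, the first tick with
  $d \ge \theta$ emits `threshold_cross`; `reward` follows after
  `reward_delay_ms` (default 1000 ms, there to dissociate movement- and
  reward-related neural activity); a fixed `iti_ms` (3000 ms) separates
  trials so movements stay discrete.
* **vao** — identical, but the threshold in force is looked up per trial
  from a `(trial, threshold)` schedule.
* **reaction_time** — each trial opens in a *pre-cue* phase with a cue
  delay drawn uniformly on `rt_cue_range_ms` (default 1–4 s; the
  original system does not print its cue-delay distribution, so this is
  a declared stand-in). A crossing before the cue is an anticipatory
  response: `punishment_start`, a 5000-ms timeout in which no cue or
  reward can occur, then a restart with an ITI drawn uniformly on
  `iti_random_range_ms` (3–6 s, also a stand-in). Crossings after the
  cue are rewarded as in the basic task.
* **bandit** — at the crossing the displacement vector is classified
  into one of two angular sectors (default forward/backward, half-width
  45°, upper boundary exclusive, reflecting the strong forward/backward
  preference of mice on this manipulandum); reward is Bernoulli with the
  sector's current probability. After each rewarded trial past a minimum
  block length (20 trials) the two probabilities swap with probability
  0.1 — the published account says only that the rates "change randomly",
  so the block rule is ours and fully configurable.

Three commitments the original firmware leaves implicit are made
explicit here: reward is **latched at the crossing tick** (retracting
during the delay does not cancel it); further crossings are **ignored
until the next trial start** (one reward per trial); and bandit direction
is classified **at the crossing sample**, not the reach apex, matching
the real-time constraint of a closed-loop system.

Every stochastic engine decision (cue delay, bandit draw, block switch,
restart ITI) flows through a draw provider and is recorded in the event
payload, so a recorded session can be replayed draw-for-draw through the
pure-R reference FSM (`replay_events`). The production loop is compiled
(Rcpp) and consumes R's RNG in exactly the same order as the reference;
the test suite holds the two paths to identical event logs. Position
series agree to within one unit in the last place (the compiled code and
R link different libm builds whose `cos` can differ by 1 ulp).

## The synthetic mouse

The generator replaces the animal and all hardware. It emulates, with no
claim of biological mechanism:

* **reaches** as straight-line out-and-back excursions with a
  minimum-jerk radial profile $A(10\tau^3 - 15\tau^4 + 6\tau^5)$ per
  half-movement — chosen because the platform's recorded reaches show
  smooth bell-shaped amplitude and velocity traces but no formula is
  published. Peak outward speed is $1.875\,A/D_{\text{half}}$.
* **spontaneous initiation** as a Poisson process (`reach_rate`,
  0.15 s⁻¹) suppressed while a reach is in flight and during punishment
  timeouts.
* **amplitude and duration** as Gaussian draws, `amp_dist` (1.2, 0.25) cm
  and `dur_dist` (500, 100) ms — set to land in the regimes a trained
  mouse occupies (amplitudes near 1 cm and up to ~2 cm, inter-reach
  intervals of several seconds).
* **baseline jitter** (isotropic Gaussian, sd 0.02 cm), **blips**
  (sub-threshold 0.15-cm excursions at 0.05 s⁻¹ standing in for postural
  adjustment and grooming) and **rev-ups** (a small opposite-direction
  pre-movement before 30% of reaches, 15% of the main amplitude, 0.4 of
  its duration) — idiosyncrasies reported for real animals.
* **cued behavior**: response latency Gaussian (400, 100) ms after the
  cue, anticipation probability 0.1 with a uniform 300–1200 ms latency
  from trial start. The platform's within-session RT distribution is not
  published; these are stand-ins. A per-session practice factor
  (`rt_improve = 0.93` toward a 150-ms floor, applied by the trainer)
  models the steady RT decrease seen across training sessions — a static
  agent cannot show that trend.
* **bandit policy**: win-stay/lose-shift with a 0.8 shift probability
  after unrewarded trials. Bandit initiations wait for the armed window
  so the previous outcome is always known to the policy; without that
  commitment rule a reach planned during the reward delay would use a
  stale outcome.

What a green test therefore establishes: the engine, pipeline and
scheduler behave exactly as specified on traces with the *structure* of
mouse reaching. What it does not establish: anything about real mice —
curved trajectories, fatigue, motivation drift, bimanual asymmetries and
learning dynamics (beyond the RT practice factor) are all out of scope.

## The analysis pipeline

Segmentation starts from crossings of a minimal detection threshold and
works backward and forward in time to the reach's initiation and
termination. The level defining those endpoints is `onset_frac` (10%) of
the detection threshold: the published rule says only "exact reach
initiation and termination"; a low fractional level selects full reaches
while rejecting baseline noise, and a velocity-based refinement was
rejected for determinism. Runs closer than `merge_gap_ms` (20 ms) merge;
reaches shorter than `min_duration_ms` (50 ms) are dropped; reaches
truncated by the session edge are kept and flagged.

One consequence worth stating precisely: with a minimum-jerk profile the
measured duration between crossings of level $qA$ understates the
planned duration by $2\tau^*(q) \cdot D/2$ where
$10\tau^{*3} - 15\tau^{*4} + 6\tau^{*5} = q$ — about 16% of $D$ at
$q = 0.04$. The parameter-recovery test asserts this exact bound (to
within a tick per side) rather than a nominal percentage; amplitude
recovery is exact because reach apices are generated on the tick grid.

Kinematics: amplitude is the peak displacement, outward velocity the
forward difference of displacement at native resolution (optional odd
moving-average smoothing, default off), duration onset-to-offset.
Inter-reach intervals are onset-to-onset, so in a rewarded basic-task
session they include the 3-s ITI. Reaction time is reach onset minus the
latest cue at or before the reach's crossing; values above 5 s are
omitted, strictly (an RT of exactly 5000 ms is retained). The expert
criterion is more than 100 rewarded reaches in a session run at a
threshold of at least 0.9 cm — the protocol's own cap is 0.9 cm, so the
bound is read inclusively.

## The training scheduler

Two 30-min sessions per day for three days, then one; threshold
0.1 → 0.9 cm at no more than 1 mm per day; reward delay 500 → 1000 ms at
50 ms per day. Where the protocol defers to experimenter judgment we
substitute explicit, configurable gates: acquisition is a session with
≥ 20 rewarded reaches (the published account says only "typically one to
six sessions"), and the threshold advances on a day boundary only if the
day's last session produced ≥ 50 rewarded reaches. The delay advances
unconditionally once acquisition is declared, reading the schedule's
"50 ms/d alongside the threshold" as calendar-driven. Punishment for
anticipatory reaches switches on at day 14; "light-early" and
"light-late" regimens introduce the go-cue at session 1 or 7.

## Numerical and degenerate-input choices

* Thresholds accumulate on a 1-mm grid and are re-rounded after each
  increment so `0.1 + 0.1 + …` cannot drift off `0.9` in floating point.
* Amplitude draws are floored at 0.1 cm and durations at 50 ms (snapped
  to an even tick count so the apex lies on the grid).
* Sector membership uses `[center − hw, center + hw)` — the exclusive
  upper edge makes the two default sectors partition their union without
  double-counting the boundary ray.
* An empty series segments to an empty reach set; a constant "reach" has
  zero outward velocity; a session log with non-monotone time or an
  unknown event code is rejected with the offending line number, and a
  ragged row is a parse error rather than a silent truncation.
* Session CSVs carry floats as `%.17g`, so `read(write(r))` is
  bit-exact; the full configuration travels in the header as one JSON
  line.

## Known limitations

* The engine works in cm; voltage-to-cm calibration of a physical
  joystick is out of scope.
* Reaches are radial; curvature, per-axis mechanics and unimanual
  vs bimanual distinctions are not modeled.
* The bandit block rule and all trainer gates are stand-ins; published
  block probabilities and advancement rules do not exist to compare
  against.
* Agent learning is limited to the RT practice factor; rewarded-reach
  counts do not replicate any published learning curve quantitatively,
  and the package makes no statistical claims about animals.
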