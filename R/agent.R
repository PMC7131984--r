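#' Synthetic mouse parameters
#'
#' Describes a simulated head-fixed mouse: spontaneous reach initiations
#' as a Poisson process, bell-shaped (minimum-jerk) out-and-back reaches
#' along a preferred-direction mixture, baseline positional jitter, small
#' sub-threshold "blips" (postural adjustments, grooming), optional
#' opposite-direction "rev-up" pre-movements, cue-locked reaction-time
#' behavior with occasional anticipatory reaches, and a win-stay /
#' lose-shift policy for the two-armed bandit.
#'
#' Defaults land in the regimes a trained mouse occupies on this
#' platform: peak amplitudes around 1.2 cm (reaches can cover upwards of
#' 2 cm), ~500-ms reaches, inter-reach intervals of several seconds.
#'
#' @param reach_rate mean spontaneous reach initiations per second
#'   (center-out / VAO / bandit variants).
#' @param amp_mean,amp_sd peak reach amplitude distribution (cm; draws
#'   are floored at 0.1 cm).
#' @param dur_mean,dur_sd reach duration distribution (ms; floored at
#'   50 ms and snapped to an even number of ticks so the apex falls on
#'   the tick grid).
#' @param dir_angles,dir_weights mixture of preferred reach directions
#'   (radians, `atan2` convention) and their probabilities.
#' @param angular_sd per-reach angular scatter around the chosen
#'   direction (radians).
#' @param rt_mean,rt_sd cue-to-initiation latency (ms) in the
#'   reaction-time task.
#' @param anticip_prob probability of planning an anticipatory (pre-cue)
#'   reach on a given reaction-time trial.
#' @param anticip_range_ms uniform range of the anticipatory latency
#'   after trial start (ms).
#' @param revup_prob probability a reach is preceded by a small
#'   opposite-direction rev-up.
#' @param revup_frac rev-up amplitude as a fraction of the main reach
#'   (its duration is 0.4 of the main reach duration).
#' @param jitter_sd baseline positional noise sd per axis (cm).
#' @param blip_rate,blip_amp,blip_dur_ms rate (per second), amplitude
#'   (cm) and duration (ms) of non-reach blips.
#' @param lose_shift_prob bandit policy: probability of switching sector
#'   after an unrewarded trial (stays after rewarded trials).
#' @param rt_improve per-session multiplicative practice factor applied
#'   to `rt_mean` by the trainer (1 = no learning).
#' @param rt_floor_ms lower bound on the practiced `rt_mean`.
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(reach_rate = 0.15,
                         amp_mean = 1.2, amp_sd = 0.25,
                         dur_mean = 500, dur_sd = 100,
                         dir_angles = c(pi / 2, -pi / 2),
                         dir_weights = c(0.5, 0.5),
                         angular_sd = 0.2,
                         rt_mean = 400, rt_sd = 100,
                         anticip_prob = 0.1,
                         anticip_range_ms = c(300, 1200),
                         revup_prob = 0.3, revup_frac = 0.15,
                         jitter_sd = 0.02,
                         blip_rate = 0.05, blip_amp = 0.15,
                         blip_dur_ms = 150,
                         lose_shift_prob = 0.8,
                         rt_improve = 0.93, rt_floor_ms = 150) {
  stopifnot(reach_rate >= 0, blip_rate >= 0, amp_sd >= 0, dur_sd >= 0,
            jitter_sd >= 0, angular_sd >= 0, rt_sd >= 0,
            length(dir_angles) == length(dir_weights))
  probs <- c(anticip_prob, revup_prob, lose_shift_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (revup_frac >= 1 || revup_frac < 0) stop("revup_frac must lie in [0, 1)")
  if (any(dir_weights < 0) || sum(dir_weights) <= 0)
    stop("dir_weights must be non-negative and sum > 0")
  structure(
    list(reach_rate = reach_rate, amp_mean = amp_mean, amp_sd = amp_sd,
         dur_mean = dur_mean, dur_sd = dur_sd,
         dir_angles = as.numeric(dir_angles),
         dir_weights = as.numeric(dir_weights) / sum(dir_weights),
         angular_sd = angular_sd,
         rt_mean = rt_mean, rt_sd = rt_sd, anticip_prob = anticip_prob,
         anticip_range_ms = as.numeric(anticip_range_ms),
         revup_prob = revup_prob, revup_frac = revup_frac,
         jitter_sd = jitter_sd, blip_rate = blip_rate, blip_amp = blip_amp,
         blip_dur_ms = as.numeric(blip_dur_ms),
         lose_shift_prob = lose_shift_prob,
         rt_improve = rt_improve, rt_floor_ms = rt_floor_ms),
    class = "agent_params")
}

#' Minimum-jerk position profile
#'
#' Monotone half-movement from 0 to `A` over `D` ms:
#' `A (10 tau^3 - 15 tau^4 + 6 tau^5)` with `tau = t/D`.  Its peak speed
#' is `1.875 A / D` at `tau = 0.5`.  Out-and-back reaches are composed of
#' two mirrored halves.
#'
#' @param A amplitude (cm).
#' @param D half-movement duration (ms); must be positive.
#' @param t time within the movement (ms), vectorized, `0 <= t <= D`.
#' @return radial position (cm).
#' @export
minimum_jerk_profile <- function(A, D, t) {
  if (D <= 0) stop("D must be > 0")
  if (any(t < 0 | t > D)) stop("t must lie in [0, D]")
  tau <- t / D
  t3 <- tau * tau * tau
  t4 <- t3 * tau
  t5 <- t4 * tau
  A * (10 * t3 - 15 * t4 + 6 * t5)
}

# out-and-back excursion: apex A at s = D/2, back to 0 at s = D
mj_out_and_back <- function(A, D, s) {
  half <- D / 2
  ifelse(s <= half,
         minimum_jerk_profile(A, half, pmin(pmax(s, 0), half)),
         minimum_jerk_profile(A, half, pmin(pmax(D - s, 0), half)))
}

#' Reach plan
#'
#' @param t_start start time (ms).
#' @param direction reach direction (radians).
#' @param amplitude peak amplitude (cm).
#' @param duration_ms total out-and-back duration (ms).
#' @param revup optional numeric `c(amplitude, duration_ms)` of an
#'   opposite-direction pre-movement.
#' @return an object of class `reach_plan`.
#' @export
reach_plan <- function(t_start = 0, direction = pi / 2, amplitude = 1.2,
                       duration_ms = 400, revup = NULL) {
  if (duration_ms <= 0 || amplitude <= 0)
    stop("amplitude and duration must be > 0")
  structure(list(t_start = t_start, direction = direction,
                 amplitude = amplitude, duration_ms = duration_ms,
                 revup = revup), class = "reach_plan")
}

# signed radial offset s ms into the plan (rev-up first, then main reach)
plan_offset <- function(plan, s) {
  main <- mj_out_and_back(plan$amplitude, plan$duration_ms,
                          pmin(pmax(s - plan_revup_ms(plan), 0),
                               plan$duration_ms))
  if (is.null(plan$revup)) return(main)
  rd <- plan$revup[2L]
  ifelse(s < rd, -mj_out_and_back(plan$revup[1L], rd, pmin(pmax(s, 0), rd)),
         main)
}

plan_revup_ms <- function(plan) if (is.null(plan$revup)) 0 else plan$revup[2L]

plan_total_ms <- function(plan) plan$duration_ms + plan_revup_ms(plan)

#' Generate one reach trajectory
#'
#' Samples a planned reach at the tick rate: the optional rev-up segment
#' (opposite direction), the main minimum-jerk out-and-back excursion
#' along `plan$direction`, plus additive isotropic Gaussian jitter of sd
#' `params$jitter_sd`.
#'
#' @param plan a [reach_plan()].
#' @param params an [agent_params()] (only `jitter_sd` is used).
#' @param tick_ms sampling period (ms).
#' @return data frame with columns `t_ms` (0-based, relative to reach
#'   start), `dx_cm`, `dy_cm` (offsets from baseline).
#' @export
generate_reach <- function(plan, params = agent_params(), tick_ms = 1) {
  s <- seq(0, plan_total_ms(plan), by = tick_ms)
  r <- plan_offset(plan, s)
  ux <- cos(plan$direction); uy <- sin(plan$direction)
  dx <- ux * r
  dy <- uy * r
  if (params$jitter_sd > 0) {
    dx <- dx + stats::rnorm(length(s), 0, params$jitter_sd)
    dy <- dy + stats::rnorm(length(s), 0, params$jitter_sd)
  }
  data.frame(t_ms = s, dx_cm = dx, dy_cm = dy)
}

# ---- tick-level agent (reference implementation) --------------------------

#' Initialize synthetic-mouse state
#'
#' @param params an [agent_params()].
#' @param config the session's [task_config()].
#' @return an environment of class `agent_state` consumed by
#'   [agent_step()] (mutated in place).
#' @export
agent_init <- function(params, config) {
  ag <- new.env(parent = emptyenv())
  ag$params <- params
  ag$config <- config
  ag$active <- FALSE
  ag$plan <- NULL
  ag$t0 <- NA_real_
  ag$sched_t <- NA_real_    # cue-locked reach start (reaction_time)
  ag$anticip_t <- NA_real_  # anticipatory reach start (reaction_time)
  ag$in_timeout <- FALSE
  ag$in_trial <- FALSE      # between trial_start and the trial's crossing
  ag$last_k <- NA_integer_  # bandit: last chosen sector index
  ag$have_history <- FALSE
  ag$last_win <- FALSE
  ag$crossed_this <- FALSE
  ag$rewarded_this <- FALSE
  class(ag) <- "agent_state"
  ag
}

#' One synthetic-mouse tick
#'
#' Produces the joystick sample for tick `t`, given the task events
#' emitted up to and including the previous tick (the closed-loop driver
#' feeds each tick's events to the agent on the following tick, a one-tick
#' sensory latency).  Spontaneous reaches are initiated as a Poisson
#' process at `reach_rate` (suppressed while a reach is in flight and
#' during punishment timeouts); in the reaction-time task reaches are
#' instead locked to the go-cue (or anticipate it); in the bandit task
#' the reach direction follows a win-stay / lose-shift policy.
#'
#' @param agent an [agent_init()] environment (mutated in place).
#' @param t tick time (ms).
#' @param new_events event-log data frame rows not yet seen by the agent
#'   (may have zero rows).
#' @return numeric `c(x, y)` joystick position (cm).
#' @export
agent_step <- function(agent, t, new_events = NULL) {
  p <- agent$params
  cfg <- agent$config
  tick <- cfg$tick_ms

  if (!is.null(new_events) && nrow(new_events) > 0L) {
    for (i in seq_len(nrow(new_events))) {
      kind <- new_events$kind[i]
      if (kind == "trial_start") {
        agent$in_timeout <- FALSE
        agent$in_trial <- TRUE
        if (cfg$variant == "reaction_time") {
          agent$sched_t <- NA_real_
          if (stats::runif(1) < p$anticip_prob) {
            lat <- p$anticip_range_ms[1L] + stats::runif(1) *
              (p$anticip_range_ms[2L] - p$anticip_range_ms[1L])
            agent$anticip_t <- t + round(lat / tick) * tick
          } else agent$anticip_t <- NA_real_
        }
      } else if (kind == "cue_on") {
        lat <- stats::rnorm(1, p$rt_mean, p$rt_sd)
        agent$sched_t <- t + max(tick, round(lat / tick) * tick)
        agent$anticip_t <- NA_real_
      } else if (kind == "punishment_start") {
        agent$in_timeout <- TRUE
        agent$in_trial <- FALSE
        agent$sched_t <- NA_real_
        agent$anticip_t <- NA_real_
      } else if (kind == "threshold_cross") {
        agent$crossed_this <- TRUE
        agent$in_trial <- FALSE
      } else if (kind == "reward") {
        agent$rewarded_this <- TRUE
      } else if (kind == "iti_start") {
        agent$in_timeout <- FALSE
        agent$in_trial <- FALSE
        if (agent$crossed_this) {
          agent$have_history <- TRUE
          agent$last_win <- agent$rewarded_this
        }
        agent$crossed_this <- FALSE
        agent$rewarded_this <- FALSE
      }
    }
  }

  if (agent$active && t - agent$t0 >= plan_total_ms(agent$plan))
    agent$active <- FALSE

  if (!agent$active && !agent$in_timeout) {
    if (cfg$variant == "reaction_time") {
      if ((!is.na(agent$sched_t) && t >= agent$sched_t) ||
          (!is.na(agent$anticip_t) && t >= agent$anticip_t)) {
        agent$plan <- draw_reach_plan(agent, bandit = FALSE)
        agent$t0 <- t
        agent$active <- TRUE
        agent$sched_t <- NA_real_
        agent$anticip_t <- NA_real_
      } else if (stats::runif(1) < p$blip_rate * tick / 1000) {
        agent$plan <- draw_blip_plan(agent)
        agent$t0 <- t
        agent$active <- TRUE
      }
    } else {
      # bandit choices wait for the armed window, by which time the
      # previous trial's outcome is known (win-stay/lose-shift needs it)
      may_reach <- cfg$variant != "bandit" || agent$in_trial
      if (may_reach && stats::runif(1) < p$reach_rate * tick / 1000) {
        agent$plan <- draw_reach_plan(agent, bandit = cfg$variant == "bandit")
        agent$t0 <- t
        agent$active <- TRUE
      } else if (stats::runif(1) < p$blip_rate * tick / 1000) {
        agent$plan <- draw_blip_plan(agent)
        agent$t0 <- t
        agent$active <- TRUE
      }
    }
  }

  r <- if (agent$active) plan_offset(agent$plan, t - agent$t0) else 0
  x <- cfg$baseline[1L] + cos(agent$plan$direction %||% 0) * r
  y <- cfg$baseline[2L] + sin(agent$plan$direction %||% 0) * r
  if (p$jitter_sd > 0) {
    x <- x + stats::rnorm(1, 0, p$jitter_sd)
    y <- y + stats::rnorm(1, 0, p$jitter_sd)
  }
  c(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_reach_plan <- function(agent, bandit) {
  p <- agent$params
  cfg <- agent$config
  tick <- cfg$tick_ms
  if (bandit) {
    k <- if (!agent$have_history) {
      if (stats::runif(1) < 0.5) 1L else 2L
    } else if (agent$last_win) {
      agent$last_k
    } else if (stats::runif(1) < p$lose_shift_prob) {
      3L - agent$last_k
    } else agent$last_k
    agent$last_k <- k
    ang <- cfg$bandit$centers[k]
  } else {
    u <- stats::runif(1)
    k <- findInterval(u, cumsum(p$dir_weights)) + 1L
    k <- min(k, length(p$dir_angles))
    ang <- p$dir_angles[k]
  }
  if (p$angular_sd > 0) ang <- ang + stats::rnorm(1, 0, p$angular_sd)
  A <- max(0.1, stats::rnorm(1, p$amp_mean, p$amp_sd))
  half <- max(25, round(stats::rnorm(1, p$dur_mean, p$dur_sd) / 2 / tick))
  D <- 2 * half * tick
  revup <- NULL
  if (stats::runif(1) < p$revup_prob) {
    rd <- 2 * max(1, round(0.2 * D / tick)) * tick
    revup <- c(p$revup_frac * A, rd)
  }
  reach_plan(0, ang, A, D, revup)
}

draw_blip_plan <- function(agent) {
  p <- agent$params
  tick <- agent$config$tick_ms
  ang <- -pi + 2 * pi * stats::runif(1)
  D <- 2 * max(1, round(p$blip_dur_ms / 2 / tick)) * tick
  reach_plan(0, ang, p$blip_amp, D, NULL)
}

#' Pure-R closed-loop session (reference path)
#'
#' Drives [engine_step()] and [agent_step()] tick by tick, consuming R's
#' RNG in the same order as the compiled loop used by [run_session()].
#' Intended for short sessions in validation; it is several thousand
#' times slower than the compiled path.
#'
#' @inheritParams run_session
#' @return a `session_record`, structured exactly as [run_session()]'s.
#' @export
run_session_r <- function(config, agent = agent_params(), seed = NULL,
                          subject_id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  n <- config$session_ms %/% config$tick_ms
  st <- engine_init(config)
  ag <- agent_init(agent, config)
  draws <- live_draws(config)
  xs <- numeric(n); ys <- numeric(n); ts <- numeric(n)
  evs <- vector("list", 512L); n_ev <- 0L
  pending <- NULL
  for (i in seq_len(n)) {
    t <- (i - 1) * config$tick_ms
    pos <- agent_step(ag, t, pending)
    ts[i] <- t; xs[i] <- pos[1L]; ys[i] <- pos[2L]
    res <- engine_step(st, t, pos[1L], pos[2L], config, draws)
    pending <- if (nrow(res$events) > 0L) res$events else NULL
    if (!is.null(pending)) {
      n_ev <- n_ev + 1L
      if (n_ev > length(evs)) evs <- c(evs, vector("list", length(evs)))
      evs[[n_ev]] <- pending
    }
  }
  events <- if (n_ev > 0L) do.call(rbind, evs[seq_len(n_ev)])
            else events_to_df(list())
  structure(
    list(meta = list(subject_id = subject_id, variant = config$variant,
                     seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                     tick_ms = config$tick_ms),
         series = data.frame(t_ms = ts, x_cm = xs, y_cm = ys),
         events = events, config = config),
    class = "session_record")
}
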