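#' Initialize automated-training state
#'
#' The shaping schedule: mice run two 30-min sessions per day for the
#' first three days, then one per day.  After the movement-water
#' association is acquired, the reward amplitude threshold escalates from
#' 0.1 cm toward 0.9 cm by at most 1 mm per day (held on days whose last
#' session missed the performance gate) and the reward delay escalates
#' from 500 ms to 1 s at 50 ms per day.
#'
#' The published protocol leaves the acquisition and advancement rules
#' to the experimenter; the defaults here (acquisition: a session with at
#' least 20 rewarded reaches; daily advancement gate: at least 50) are
#' declared stand-ins and fully configurable.
#'
#' @param variant task variant trained.
#' @param thr_start,thr_cap,thr_step_cm threshold schedule (cm).
#' @param delay_start,delay_cap,delay_step_ms reward-delay schedule (ms).
#' @param acquisition_n rewarded reaches in one session that establish
#'   the movement-water association.
#' @param gate_n rewarded reaches in the day's last session required to
#'   advance the threshold the next day.
#' @param two_session_days number of initial days with two sessions.
#' @param punish_from_day day from which anticipatory reaches are
#'   punished (reaction-time training).
#' @param cue_intro_session session from which the go-cue is active
#'   (1 = "light early", 7 = "light late"); before it a reaction-time
#'   trainee runs the basic center-out task.
#' @param session_ms session length.
#' @return an object of class `training_state`.
#' @export
training_state <- function(variant = "center_out",
                           thr_start = 0.1, thr_cap = 0.9, thr_step_cm = 0.1,
                           delay_start = 500L, delay_cap = 1000L,
                           delay_step_ms = 50L,
                           acquisition_n = 20L, gate_n = 50L,
                           two_session_days = 3L,
                           punish_from_day = 14L,
                           cue_intro_session = 1L,
                           session_ms = 1800000L) {
  structure(
    list(variant = variant, day = 1L, session_in_day = 1L, session = 1L,
         amp_threshold = thr_start, reward_delay_ms = as.integer(delay_start),
         acquired = FALSE, history = list(),
         thr_cap = thr_cap, thr_step_cm = thr_step_cm,
         delay_cap = as.integer(delay_cap),
         delay_step_ms = as.integer(delay_step_ms),
         acquisition_n = as.integer(acquisition_n),
         gate_n = as.integer(gate_n),
         two_session_days = as.integer(two_session_days),
         punish_from_day = as.integer(punish_from_day),
         cue_intro_session = as.integer(cue_intro_session),
         session_ms = as.integer(session_ms)),
    class = "training_state")
}

sessions_per_day <- function(state, day) {
  if (day <= state$two_session_days) 2L else 1L
}

#' Task configuration for the scheduled session
#'
#' @param state a [training_state()].
#' @return the [task_config()] the trainer would run next.
#' @export
session_config <- function(state) {
  variant <- state$variant
  if (variant == "reaction_time" && state$session < state$cue_intro_session)
    variant <- "center_out"
  task_config(variant = variant,
              amp_threshold = state$amp_threshold,
              reward_delay_ms = state$reward_delay_ms,
              punishment = state$day >= state$punish_from_day,
              session_ms = state$session_ms)
}

#' Advance the training schedule by one completed session
#'
#' Appends the session's summary, declares acquisition once a session
#' reaches the acquisition criterion, and at each day boundary escalates
#' the reward delay (unconditionally, once acquired) and the amplitude
#' threshold (only if the day's last session met the performance gate).
#' Both escalations are capped: the threshold never rises by more than
#' `thr_step_cm` (1 mm) per day nor beyond `thr_cap`, the delay never by
#' more than `delay_step_ms` per day nor beyond `delay_cap`.
#'
#' @param state a [training_state()].
#' @param latest the [session_summary()] of the session just run.
#' @return a list with elements `state` (advanced) and `config` (the
#'   [task_config()] for the next session).
#' @export
next_config <- function(state, latest) {
  stopifnot(inherits(state, "training_state"),
            inherits(latest, "session_summary"))
  state$history[[length(state$history) + 1L]] <- latest
  if (latest$n_rewarded >= state$acquisition_n) state$acquired <- TRUE

  if (state$session_in_day >= sessions_per_day(state, state$day)) {
    state$day <- state$day + 1L
    state$session_in_day <- 1L
    if (state$acquired) {
      state$reward_delay_ms <- min(state$delay_cap,
                                   state$reward_delay_ms + state$delay_step_ms)
      if (latest$n_rewarded >= state$gate_n)
        state$amp_threshold <- round(min(state$thr_cap,
                                         state$amp_threshold + state$thr_step_cm),
                                     5L)  # keep 0.1+0.1+... on the mm grid
    }
  } else {
    state$session_in_day <- state$session_in_day + 1L
  }
  state$session <- state$session + 1L
  list(state = state, config = session_config(state))
}

#' Simulate an automated training progression
#'
#' Runs one closed-loop session per scheduled slot (two per day for the
#' first three days, one thereafter), analyzes each with the offline
#' pipeline at the session's own threshold, and feeds the summary back
#' into the scheduler.  Deterministic given `seed`.
#'
#' The synthetic mouse improves its cue reaction time with practice:
#' before session *s* its `rt_mean` is scaled by `rt_improve^(s - 1)`,
#' floored at `rt_floor_ms`.
#'
#' @param agent an [agent_params()].
#' @param n_days number of training days.
#' @param seed integer seed.
#' @param state a [training_state()] describing the protocol.
#' @return an object of class `training_progression`: a data frame with
#'   one row per session (`day`, `session`, `variant`, `threshold_cm`,
#'   `delay_ms`, `n_reaches`, `n_rewarded`, `n_punishments`,
#'   `median_rt_ms`, `expert`), with the per-session summaries attached
#'   as attribute `summaries`.
#' @export
simulate_training <- function(agent = agent_params(), n_days = 21L,
                              seed = 1L, state = training_state()) {
  set.seed(seed)
  rows <- list()
  summaries <- list()
  while (state$day <= n_days) {
    cfg <- session_config(state)
    ag <- agent
    ag$rt_mean <- max(agent$rt_floor_ms,
                      agent$rt_mean * agent$rt_improve^(state$session - 1L))
    rec <- run_session(cfg, ag, seed = NULL)
    reaches <- detect_reaches(
      rec$series, cfg$baseline,
      segmentation_params(detect_threshold = cfg$amp_threshold))
    reaches <- mark_rewarded(reaches, rec$events)
    summ <- session_summary(rec, reaches)
    rows[[length(rows) + 1L]] <- data.frame(
      day = state$day, session = state$session, variant = cfg$variant,
      threshold_cm = cfg$amp_threshold, delay_ms = cfg$reward_delay_ms,
      n_reaches = summ$n_reaches, n_rewarded = summ$n_rewarded,
      n_punishments = summ$n_punishments,
      median_rt_ms = summ$median_rt, expert = summ$expert,
      stringsAsFactors = FALSE)
    summaries[[length(summaries) + 1L]] <- summ
    state <- next_config(state, summ)$state
  }
  out <- do.call(rbind, rows)
  attr(out, "summaries") <- summaries
  class(out) <- c("training_progression", "data.frame")
  out
}

#' Per-day threshold and delay sequences of a progression
#'
#' @param progression a `training_progression`.
#' @return data frame with one row per day: `day`, `threshold_cm`,
#'   `delay_ms` (the values in force on that day).
#' @export
daily_schedule <- function(progression) {
  sp <- split(progression, progression$day)
  data.frame(day = as.integer(names(sp)),
             threshold_cm = vapply(sp, function(d) d$threshold_cm[1L], 0),
             delay_ms = vapply(sp, function(d) d$delay_ms[1L], 0),
             row.names = NULL)
}
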