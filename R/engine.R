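#' Radial displacement from baseline
#'
#' The reward rule of every task variant: the Euclidean distance between
#' the joystick's resting (baseline) position and its current position.
#'
#' @param x,y joystick position (cm); vectorized.
#' @param baseline two-element numeric `c(x0, y0)`.
#' @return non-negative displacement in cm.
#' @export
radial_displacement <- function(x, y, baseline = c(0, 0)) {
  sqrt((x - baseline[1L])^2 + (y - baseline[2L])^2)
}

#' Estimate the resting baseline of a position series
#'
#' Componentwise median of the first `window_ms` of samples.  Used when
#' ingesting recorded logs; the closed-loop engine itself takes the
#' baseline from its configuration.
#'
#' @param series data frame with columns `t_ms`, `x_cm`, `y_cm`.
#' @param window_ms settling window length (ms).
#' @return two-element numeric `c(x0, y0)`.
#' @export
estimate_baseline <- function(series, window_ms = 500) {
  idx <- series$t_ms < series$t_ms[1L] + window_ms
  if (nrow(series) == 0L || max(series$t_ms) - series$t_ms[1L] + 1 < window_ms)
    stop("series shorter than the ", window_ms,
         " ms settling window; cannot estimate baseline")
  c(stats::median(series$x_cm[idx]), stats::median(series$y_cm[idx]))
}

#' Classify a displacement vector into a bandit response sector
#'
#' Sector membership uses `atan2(dy, dx)`; a sector covers
#' `[center - halfwidth, center + halfwidth)` with the upper boundary
#' exclusive.  Vectors in neither sector return `NA`.
#'
#' @param dx,dy displacement components (cm).
#' @param schedule a [bandit_schedule()].
#' @return sector label, or `NA_character_` if in neither sector.
#' @export
classify_direction <- function(dx, dy, schedule) {
  if (dx == 0 && dy == 0) stop("cannot classify a zero displacement vector")
  ang <- atan2(dy, dx)
  for (i in seq_along(schedule$labels)) {
    d <- wrap_angle(ang - schedule$centers[i])
    if (d >= -schedule$halfwidth && d < schedule$halfwidth)
      return(schedule$labels[i])
  }
  NA_character_
}

# ---- single-tick finite-state machine (reference implementation) ----------

#' Initialize engine state
#'
#' Creates the mutable state consumed by [engine_step()].  The state is an
#' environment and is updated in place; [engine_step()] also returns it
#' for a functional calling style.
#'
#' @param config a [task_config()].
#' @return an environment of class `engine_state` with fields `phase`
#'   (`iti`/`armed`/`pre_cue`/`reward_pending`/`timeout`), `trial`,
#'   `threshold`, reward/punishment counters and bandit block state.
#' @export
engine_init <- function(config) {
  st <- new.env(parent = emptyenv())
  st$started <- FALSE
  st$phase <- "iti"
  st$phase_entry_t <- 0
  st$trial <- 0L
  st$threshold <- config$amp_threshold
  st$cross_t <- NA_real_
  st$cue_t <- NA_real_
  st$iti_end <- NA_real_
  st$timeout_end <- NA_real_
  st$pending_iti <- NA_real_
  st$rewards <- 0L
  st$punishments <- 0L
  st$p <- if (config$variant == "bandit") config$bandit$p_reward else c(NA, NA)
  st$block_count <- 0L
  class(st) <- "engine_state"
  st
}

#' Advance the task engine by one sample
#'
#' The tick-based finite-state machine shared by all four task variants.
#' Scheduled transitions (reward after the programmed delay, end of ITI,
#' end of timeout, go-cue onset) are processed first; the sample's
#' displacement is then tested against the threshold in force.  A reward
#' is latched at the crossing tick: retracting during the reward delay
#' does not cancel it, and further crossings are ignored until the next
#' trial start.
#'
#' Sample timestamps must advance by exactly `config$tick_ms` per call.
#'
#' @param state an [engine_init()] environment (mutated in place).
#' @param t sample time (ms since session start; first sample at 0).
#' @param x,y joystick position (cm).
#' @param config a [task_config()].
#' @param draws a draw provider from [live_draws()] or [replay_draws()];
#'   every stochastic engine decision (cue delay, bandit reward draw,
#'   block switch, post-punishment ITI) flows through it and is recorded
#'   in event payloads so that a recorded session can be replayed
#'   draw-for-draw.
#' @return a list with elements `state` and `events` (data frame with
#'   columns `t_ms`, `kind`, `trial`, `payload`; zero rows on most ticks).
#' @export
engine_step <- function(state, t, x, y, config, draws = live_draws(config)) {
  ev <- list()
  emit <- function(kind, payload)
    ev[[length(ev) + 1L]] <<- list(t_ms = t, kind = kind,
                                   trial = state$trial, payload = payload)

  start_trial <- function(t) {
    state$trial <- state$trial + 1L
    state$cross_t <- NA_real_
    if (config$variant == "vao")
      state$threshold <- vao_threshold(config$vao_schedule, state$trial,
                                       config$amp_threshold)
    if (config$variant == "reaction_time") {
      cd <- draws$cue_delay()
      state$cue_t <- t + cd
      state$phase <- "pre_cue"
      emit("trial_start", sprintf("trial=%d&cue_delay=%d", state$trial, cd))
    } else {
      state$phase <- "armed"
      emit("trial_start", sprintf("trial=%d", state$trial))
    }
    state$phase_entry_t <- t
  }

  enter_iti <- function(t, iti) {
    state$phase <- "iti"
    state$phase_entry_t <- t
    state$iti_end <- t + iti
    emit("iti_start", sprintf("trial=%d&iti=%d", state$trial, as.integer(iti)))
  }

  if (!state$started) {
    if (t != 0) stop("first sample must have t = 0")
    state$started <- TRUE
    state$last_t <- t
    start_trial(t)
  } else {
    if (t != state$last_t + config$tick_ms)
      stop("non-contiguous timestamps: expected t = ",
           state$last_t + config$tick_ms, ", got ", t)
    state$last_t <- t
    if (state$phase == "reward_pending" &&
        t == state$cross_t + config$reward_delay_ms) {
      state$rewards <- state$rewards + 1L
      if (config$variant == "bandit") {
        state$block_count <- state$block_count + 1L
        if (state$block_count >= config$bandit$min_block_trials) {
          u <- draws$switch_u()
          emit("reward", sprintf("trial=%d&switch_u=%.17g", state$trial, u))
          if (u < config$bandit$switch_prob) {
            state$p <- rev(state$p)
            state$block_count <- 0L
            emit("block_switch",
                 sprintf("trial=%d&p1=%.17g&p2=%.17g",
                         state$trial, state$p[1L], state$p[2L]))
          }
        } else {
          emit("reward", sprintf("trial=%d", state$trial))
        }
      } else {
        emit("reward", sprintf("trial=%d", state$trial))
      }
      enter_iti(t, config$iti_ms)
    } else if (state$phase == "iti" && t == state$iti_end) {
      start_trial(t)
    } else if (state$phase == "timeout" && t == state$timeout_end) {
      enter_iti(t, state$pending_iti)
    } else if (state$phase == "pre_cue" && t == state$cue_t) {
      state$phase <- "armed"
      state$phase_entry_t <- t
      emit("cue_on", sprintf("trial=%d", state$trial))
    }
  }

  # threshold test on the current sample
  dx <- x - config$baseline[1L]
  dy <- y - config$baseline[2L]
  d <- sqrt(dx * dx + dy * dy)
  if (state$phase == "armed" && d >= state$threshold) {
    if (config$variant == "bandit") {
      dir <- classify_direction(dx, dy, config$bandit)
      u <- draws$bandit_u()
      if (is.na(dir)) {
        emit("threshold_cross",
             sprintf("trial=%d&threshold=%.17g&direction=none&u=%.17g",
                     state$trial, state$threshold, u))
        state$block_count <- state$block_count + 1L
        enter_iti(t, config$iti_ms)
      } else {
        i <- match(dir, config$bandit$labels)
        p <- state$p[i]
        emit("threshold_cross",
             sprintf("trial=%d&threshold=%.17g&direction=%s&p=%.17g&u=%.17g",
                     state$trial, state$threshold, dir, p, u))
        if (u < p) {
          state$cross_t <- t
          state$phase <- "reward_pending"
          state$phase_entry_t <- t
        } else {
          state$block_count <- state$block_count + 1L
          enter_iti(t, config$iti_ms)
        }
      }
    } else {
      emit("threshold_cross", sprintf("trial=%d&threshold=%.17g",
                                      state$trial, state$threshold))
      state$cross_t <- t
      state$phase <- "reward_pending"
      state$phase_entry_t <- t
    }
  } else if (state$phase == "pre_cue" && d >= state$threshold &&
             config$punishment) {
    niti <- draws$punish_iti()
    emit("punishment_start", sprintf("trial=%d&timeout=%d&next_iti=%d",
                                     state$trial, config$timeout_ms,
                                     as.integer(niti)))
    state$punishments <- state$punishments + 1L
    state$phase <- "timeout"
    state$phase_entry_t <- t
    state$timeout_end <- t + config$timeout_ms
    state$pending_iti <- niti
  }

  list(state = state, events = events_to_df(ev))
}

vao_threshold <- function(schedule, trial, fallback) {
  ok <- schedule$trial <= trial
  if (!any(ok)) fallback else schedule$threshold[max(which(ok))]
}

events_to_df <- function(ev) {
  if (length(ev) == 0L)
    return(data.frame(t_ms = numeric(), kind = character(),
                      trial = integer(), payload = character(),
                      stringsAsFactors = FALSE))
  data.frame(t_ms = vapply(ev, `[[`, 0, "t_ms"),
             kind = vapply(ev, `[[`, "", "kind"),
             trial = vapply(ev, `[[`, 0L, "trial"),
             payload = vapply(ev, `[[`, "", "payload"),
             stringsAsFactors = FALSE)
}

# ---- draw providers -------------------------------------------------------

#' Engine draw providers
#'
#' The engine's stochastic decisions are routed through a draw provider.
#' `live_draws` samples from R's RNG (uniform integers on the configured
#' ranges, snapped to the tick grid).  `replay_draws` replays the draws
#' recorded in an event log's payloads, so that [engine_step()] run over
#' a recorded position series reproduces the original event log exactly.
#'
#' @param config a [task_config()].
#' @return a list of draw functions `cue_delay()`, `bandit_u()`,
#'   `switch_u()`, `punish_iti()`.
#' @export
live_draws <- function(config) {
  tick <- config$tick_ms
  unif_ms <- function(range) {
    n_vals <- (range[2L] - range[1L]) %/% tick + 1L
    range[1L] + tick * floor(stats::runif(1) * n_vals)
  }
  list(
    cue_delay = function() unif_ms(config$rt_cue_range_ms),
    bandit_u = function() stats::runif(1),
    switch_u = function() stats::runif(1),
    punish_iti = function() unif_ms(config$iti_random_range_ms)
  )
}

#' @rdname live_draws
#' @param events an event log data frame (columns `kind`, `payload`).
#' @export
replay_draws <- function(events) {
  queue <- function(kinds, key) {
    sel <- events$kind %in% kinds
    vals <- payload_field(events$payload[sel], key)
    vals <- vals[!is.na(vals)]
    i <- 0L
    function() {
      i <<- i + 1L
      if (i > length(vals)) stop("replay draw queue '", key, "' exhausted")
      vals[i]
    }
  }
  list(
    cue_delay = queue("trial_start", "cue_delay"),
    bandit_u = queue("threshold_cross", "u"),
    switch_u = queue("reward", "switch_u"),
    punish_iti = queue("punishment_start", "next_iti")
  )
}

#' Extract a numeric field from event payload strings
#'
#' Payloads are `key=value` pairs joined by `&`.
#'
#' @param payload character vector of payload strings.
#' @param key field name.
#' @return numeric vector (`NA` where the key is absent).
#' @export
payload_field <- function(payload, key) {
  pat <- paste0("(?:^|&)", key, "=([^&]*)")
  m <- regmatches(payload, regexec(pat, payload))
  vapply(m, function(g) if (length(g) == 2L) suppressWarnings(as.numeric(g[2L]))
                        else NA_real_, 0)
}

#' @rdname payload_field
#' @export
payload_field_chr <- function(payload, key) {
  pat <- paste0("(?:^|&)", key, "=([^&]*)")
  m <- regmatches(payload, regexec(pat, payload))
  vapply(m, function(g) if (length(g) == 2L) g[2L] else NA_character_, "")
}

#' Re-derive an event log from a recorded position series
#'
#' Runs the pure-R [engine_step()] FSM over every sample of a recorded
#' series, replaying the stochastic draws stored in the recorded event
#' log.  Used to validate recorded sessions (including those produced by
#' the compiled closed-loop simulator) against the reference FSM.
#'
#' @param series data frame with columns `t_ms`, `x_cm`, `y_cm`.
#' @param config the session's [task_config()].
#' @param events the recorded event log (for draw replay); pass `NULL`
#'   for variants that draw nothing (center-out, VAO).
#' @return an event log data frame.
#' @export
replay_events <- function(series, config, events = NULL) {
  draws <- if (is.null(events)) live_draws(config) else replay_draws(events)
  st <- engine_init(config)
  out <- vector("list", 256L)
  n_out <- 0L
  for (i in seq_len(nrow(series))) {
    res <- engine_step(st, series$t_ms[i], series$x_cm[i], series$y_cm[i],
                       config, draws)
    if (nrow(res$events) > 0L) {
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- res$events
    }
  }
  if (n_out == 0L) return(events_to_df(list()))
  do.call(rbind, out[seq_len(n_out)])
}

# ---- closed-loop session --------------------------------------------------

#' Run a closed-loop session
#'
#' Couples the task engine to a synthetic mouse at the configured tick
#' rate and returns the full session: position series, typed event log,
#' configuration and metadata.  The loop runs in compiled code; given the
#' same `(config, agent, seed)` the returned record is bit-identical.
#'
#' @param config a [task_config()].
#' @param agent an [agent_params()].
#' @param seed integer seed; `NULL` continues from the current RNG state
#'   (used by the trainer to chain sessions deterministically).
#' @param subject_id metadata label.
#' @return an object of class `session_record`: a list with elements
#'   `meta`, `series` (data frame `t_ms`, `x_cm`, `y_cm`), `events`
#'   (data frame `t_ms`, `kind`, `trial`, `payload`) and `config`.
#' @export
run_session <- function(config, agent = agent_params(), seed = NULL,
                        subject_id = "synthetic") {
  stopifnot(inherits(config, "task_config"), inherits(agent, "agent_params"))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_session(engine_cfg_list(config), unclass_deep(agent),
                         config$session_ms %/% config$tick_ms)
  series <- data.frame(t_ms = res$t, x_cm = res$x, y_cm = res$y)
  events <- data.frame(t_ms = res$ev_t, kind = res$ev_kind,
                       trial = res$ev_trial, payload = res$ev_payload,
                       stringsAsFactors = FALSE)
  structure(
    list(meta = list(subject_id = subject_id, variant = config$variant,
                     seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                     tick_ms = config$tick_ms),
         series = series, events = events, config = config),
    class = "session_record")
}

# flatten a task_config into the list the C++ loop expects
engine_cfg_list <- function(config) {
  vi <- match(config$variant, c("center_out", "vao", "reaction_time", "bandit")) - 1L
  vs <- config$vao_schedule
  list(variant = vi, tick_ms = config$tick_ms,
       amp_threshold = config$amp_threshold,
       reward_delay_ms = config$reward_delay_ms, iti_ms = config$iti_ms,
       timeout_ms = config$timeout_ms,
       cue_lo = config$rt_cue_range_ms[1L], cue_hi = config$rt_cue_range_ms[2L],
       piti_lo = config$iti_random_range_ms[1L],
       piti_hi = config$iti_random_range_ms[2L],
       punishment = config$punishment,
       vao_trials = if (is.null(vs)) integer() else as.integer(vs$trial),
       vao_thresholds = if (is.null(vs)) numeric() else as.numeric(vs$threshold),
       centers = config$bandit$centers, halfwidth = config$bandit$halfwidth,
       labels = config$bandit$labels,
       p_reward = config$bandit$p_reward,
       min_block = config$bandit$min_block_trials,
       switch_prob = config$bandit$switch_prob,
       x0 = config$baseline[1L], y0 = config$baseline[2L])
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s | %d samples | %d events | %d rewards\n",
              x$meta$variant, nrow(x$series), nrow(x$events),
              sum(x$events$kind == "reward")))
  invisible(x)
}
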