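#' Two-armed bandit reward schedule
#'
#' Defines the two angular response sectors of the direction-dependent
#' bandit task, the per-direction reward probabilities of the current
#' block, and the block-switching rule.  Reaches whose displacement vector
#' at the threshold-crossing sample falls inside a sector are rewarded
#' with that sector's probability; probabilities swap between sectors at
#' random block boundaries.
#'
#' A sector covers angles `[center - halfwidth, center + halfwidth)`
#' (upper boundary exclusive), so the two default sectors -- forward and
#' backward, each 90 degrees wide -- leave the lateral directions
#' unrewarded, reflecting the strong forward/backward preference of
#' head-fixed mice on this manipulandum.
#'
#' @param labels character vector of two sector names.
#' @param centers sector center angles in radians (`atan2` convention:
#'   +y is `pi/2`).
#' @param halfwidth angular half-width of each sector (radians).
#' @param p_reward numeric vector of two reward probabilities for the
#'   current block, in sector order.
#' @param min_block_trials minimum number of completed trials between
#'   probability swaps.
#' @param switch_prob probability, evaluated after each rewarded trial
#'   once the minimum block length is reached, that the two reward
#'   probabilities swap.
#' @return an object of class `bandit_schedule`.
#' @export
bandit_schedule <- function(labels = c("forward", "backward"),
                            centers = c(pi / 2, -pi / 2),
                            halfwidth = pi / 4,
                            p_reward = c(0.8, 0.2),
                            min_block_trials = 20L,
                            switch_prob = 0.1) {
  stopifnot(length(labels) == 2L, length(centers) == 2L,
            length(p_reward) == 2L)
  if (any(p_reward < 0 | p_reward > 1))
    stop("p_reward must lie in [0, 1]")
  if (halfwidth <= 0 || halfwidth > pi / 2)
    stop("halfwidth must lie in (0, pi/2]")
  d <- abs(wrap_angle(centers[1L] - centers[2L]))
  if (d < 2 * halfwidth)
    stop("bandit sectors overlap: centers closer than 2*halfwidth")
  structure(
    list(labels = as.character(labels), centers = as.numeric(centers),
         halfwidth = as.numeric(halfwidth), p_reward = as.numeric(p_reward),
         min_block_trials = as.integer(min_block_trials),
         switch_prob = as.numeric(switch_prob)),
    class = "bandit_schedule")
}

#' Task configuration
#'
#' Bundles every parameter of the tick-based task engine.  Defaults are
#' the platform's published operating point: 1 kHz sampling, reward
#' delivered 1 s after the threshold crossing, a fixed 3-s inter-trial
#' interval, a 5000-ms punishment timeout followed by a new random ITI,
#' and 30-min sessions.
#'
#' @param variant one of `"center_out"`, `"vao"`, `"reaction_time"`,
#'   `"bandit"`.
#' @param tick_ms sampling period in ms (all durations must be integer
#'   multiples of it).
#' @param amp_threshold reward amplitude threshold in cm (radial
#'   displacement from baseline).
#' @param reward_delay_ms delay between threshold crossing and reward.
#' @param iti_ms fixed inter-trial interval after a completed trial.
#' @param timeout_ms punishment timeout triggered by anticipatory
#'   (pre-cue) crossings in the reaction-time task.
#' @param session_ms session length.
#' @param rt_cue_range_ms two-element range (ms) from which the go-cue
#'   delay is drawn uniformly at each reaction-time trial start.
#' @param iti_random_range_ms two-element range (ms) for the random ITI
#'   imposed after a punishment timeout.
#' @param punishment logical; whether anticipatory crossings are punished
#'   (the trainer keeps this off before day 14).
#' @param vao_schedule for the variable-amplitude task: a data frame with
#'   columns `trial` and `threshold`; the threshold in force for trial
#'   *i* is taken from the row with the largest `trial <= i`.
#' @param bandit a [bandit_schedule()].
#' @param baseline two-element numeric, the joystick rest position (cm)
#'   displacement is measured from.
#' @param range_cm physical excursion bound of the joystick (cm).
#' @return an object of class `task_config`.
#' @export
task_config <- function(variant = c("center_out", "vao", "reaction_time",
                                    "bandit"),
                        tick_ms = 1L,
                        amp_threshold = 0.9,
                        reward_delay_ms = 1000L,
                        iti_ms = 3000L,
                        timeout_ms = 5000L,
                        session_ms = 1800000L,
                        rt_cue_range_ms = c(1000L, 4000L),
                        iti_random_range_ms = c(3000L, 6000L),
                        punishment = TRUE,
                        vao_schedule = NULL,
                        bandit = bandit_schedule(),
                        baseline = c(0, 0),
                        range_cm = 2.5) {
  variant <- match.arg(variant)
  tick_ms <- as.integer(tick_ms)
  if (tick_ms < 1L) stop("tick_ms must be >= 1")
  if (amp_threshold <= 0) stop("amp_threshold must be > 0")
  if (reward_delay_ms < 0) stop("reward_delay_ms must be >= 0")
  durs <- c(reward_delay_ms, iti_ms, timeout_ms, session_ms,
            rt_cue_range_ms, iti_random_range_ms)
  if (any(durs %% tick_ms != 0))
    stop("all durations must be integer multiples of tick_ms")
  if (variant == "vao") {
    if (is.null(vao_schedule))
      vao_schedule <- data.frame(trial = 1L, threshold = amp_threshold)
    stopifnot(is.data.frame(vao_schedule),
              all(c("trial", "threshold") %in% names(vao_schedule)))
    vao_schedule <- vao_schedule[order(vao_schedule$trial), , drop = FALSE]
    if (any(vao_schedule$threshold <= 0))
      stop("vao thresholds must be > 0")
  }
  if (variant == "bandit" && !inherits(bandit, "bandit_schedule"))
    stop("bandit must be a bandit_schedule")
  structure(
    list(variant = variant, tick_ms = tick_ms,
         amp_threshold = as.numeric(amp_threshold),
         reward_delay_ms = as.integer(reward_delay_ms),
         iti_ms = as.integer(iti_ms), timeout_ms = as.integer(timeout_ms),
         session_ms = as.integer(session_ms),
         rt_cue_range_ms = as.integer(rt_cue_range_ms),
         iti_random_range_ms = as.integer(iti_random_range_ms),
         punishment = isTRUE(punishment),
         vao_schedule = vao_schedule, bandit = bandit,
         baseline = as.numeric(baseline), range_cm = as.numeric(range_cm)),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config> variant:", x$variant,
      sprintf("| threshold %.2f cm | delay %d ms | ITI %d ms | %d min\n",
              x$amp_threshold, x$reward_delay_ms, x$iti_ms,
              x$session_ms %/% 60000L))
  invisible(x)
}

#' Read / write task and agent configuration files
#'
#' Configurations are stored as JSON with two top-level sections:
#' `task` (arguments of [task_config()], with `bandit` and
#' `vao_schedule` nested) and `agent` (arguments of [agent_params()]).
#' Either section may be omitted.
#'
#' @param path file path.
#' @return `read_config` returns a list with elements `task`
#'   (a `task_config`) and `agent` (an `agent_params`).
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  task <- if (!is.null(raw$task)) do.call(task_config, prep_task_args(raw$task))
          else task_config()
  agent <- if (!is.null(raw$agent)) do.call(agent_params, as.list(raw$agent))
           else agent_params()
  list(task = task, agent = agent)
}

prep_task_args <- function(x) {
  x <- as.list(x)
  if (!is.null(x$bandit)) x$bandit <- do.call(bandit_schedule, as.list(x$bandit))
  if (!is.null(x$vao_schedule)) x$vao_schedule <- as.data.frame(x$vao_schedule)
  x
}

#' @rdname read_config
#' @param task a `task_config` (or NULL to omit the section).
#' @param agent an `agent_params` (or NULL).
#' @export
write_config <- function(path, task = NULL, agent = NULL) {
  out <- list()
  if (!is.null(task)) out$task <- unclass_deep(task)
  if (!is.null(agent)) out$agent <- unclass_deep(agent)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x) && !is.data.frame(x))
    x[] <- lapply(x, function(e) if (is.list(e) || inherits(e, "bandit_schedule"))
                                   unclass_deep(e) else e)
  x
}

# wrap an angle into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}
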