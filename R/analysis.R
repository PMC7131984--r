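#' Reach segmentation parameters
#'
#' Segmentation starts from crossings of a minimal amplitude threshold
#' and works backward and forward in time to the reach's true initiation
#' and termination, taken as the first/last samples above a low
#' fractional level of that threshold.  The detection threshold selects
#' full reaches and ignores small blips from postural adjustment or
#' grooming.
#'
#' @param detect_threshold minimal radial amplitude (cm) a candidate
#'   excursion must reach to count as a reach.
#' @param onset_frac fraction of `detect_threshold` defining the
#'   initiation/termination level.
#' @param min_duration_ms reaches shorter than this are dropped.
#' @param merge_gap_ms reaches separated by less than this of sub-level
#'   samples are merged into one.
#' @param smooth_ms odd moving-average width applied to the displacement
#'   before velocity extraction (0 = off).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(detect_threshold = 0.5, onset_frac = 0.1,
                                min_duration_ms = 50, merge_gap_ms = 20,
                                smooth_ms = 0) {
  if (detect_threshold <= 0) stop("detect_threshold must be > 0")
  if (onset_frac <= 0 || onset_frac >= 1) stop("onset_frac must lie in (0, 1)")
  structure(list(detect_threshold = detect_threshold,
                 onset_frac = onset_frac,
                 min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms,
                 smooth_ms = smooth_ms),
            class = "segmentation_params")
}

#' Segment reaches from a position series
#'
#' For each maximal run of samples whose displacement from baseline is at
#' or above `detect_threshold`, the onset is the first sample after the
#' last sub-level sample (below `onset_frac * detect_threshold`) before
#' the run, and the offset the last sample before the next sub-level
#' sample after it.  Reaches separated by less than `merge_gap_ms` of
#' sub-level samples are merged; reaches shorter than `min_duration_ms`
#' are dropped.  Returned reaches are disjoint and time-ordered.
#' Reaches truncated by the session edges are kept and flagged
#' `edge = TRUE`.
#'
#' @param series data frame with columns `t_ms`, `x_cm`, `y_cm`, sampled
#'   at a fixed tick.
#' @param baseline two-element numeric `c(x0, y0)`.
#' @param params a [segmentation_params()].
#' @return a data frame of class `reach_set`, one row per reach:
#'   `onset_ms`, `offset_ms`, `amplitude_cm`, `peak_velocity_cm_s`,
#'   `duration_ms`, `direction_rad`, `edge`, `rewarded` (`NA` until
#'   [mark_rewarded()]), plus hidden columns `onset_idx`, `offset_idx`
#'   indexing the series.
#' @export
detect_reaches <- function(series, baseline = c(0, 0),
                           params = segmentation_params()) {
  if (!inherits(params, "segmentation_params"))
    stop("params must be a segmentation_params")
  n <- nrow(series)
  if (n == 0L) return(empty_reach_set())
  tick <- if (n > 1L) series$t_ms[2L] - series$t_ms[1L] else 1
  disp <- radial_displacement(series$x_cm, series$y_cm, baseline)
  dsm <- smooth_displacement(disp, params$smooth_ms, tick)
  above <- dsm >= params$detect_threshold
  if (!any(above)) return(empty_reach_set())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs_s <- starts[r$values]
  runs_e <- ends[r$values]

  level <- params$onset_frac * params$detect_threshold
  below_idx <- which(dsm < level)
  if (length(below_idx) == 0L) {
    onset <- rep(1L, length(runs_s)); offset <- rep(n, length(runs_e))
    k <- rep(0L, length(runs_s)); k2 <- rep(1L, length(runs_e))
  } else {
    # onset: sample after the last sub-level sample before the run
    k <- findInterval(runs_s - 1L, below_idx)
    onset <- ifelse(k == 0L, 1L, below_idx[pmax(k, 1L)] + 1L)
    # offset: sample before the first sub-level sample after the run
    k2 <- findInterval(runs_e, below_idx) + 1L
    offset <- ifelse(k2 > length(below_idx), n,
                     below_idx[pmin(k2, length(below_idx))] - 1L)
  }
  edge <- (k == 0L & dsm[1L] >= level) | (k2 > length(below_idx) & dsm[n] >= level)

  # merge overlapping or nearly-contiguous reaches
  m_on <- integer(); m_off <- integer(); m_edge <- logical()
  cur_on <- onset[1L]; cur_off <- offset[1L]; cur_edge <- edge[1L]
  if (length(onset) > 1L) {
    for (i in 2L:length(onset)) {
      gap_ms <- (onset[i] - cur_off - 1L) * tick
      if (gap_ms < params$merge_gap_ms) {
        cur_off <- max(cur_off, offset[i])
        cur_edge <- cur_edge || edge[i]
      } else {
        m_on <- c(m_on, cur_on); m_off <- c(m_off, cur_off)
        m_edge <- c(m_edge, cur_edge)
        cur_on <- onset[i]; cur_off <- offset[i]; cur_edge <- edge[i]
      }
    }
  }
  m_on <- c(m_on, cur_on); m_off <- c(m_off, cur_off); m_edge <- c(m_edge, cur_edge)

  dur <- (m_off - m_on) * tick
  keep <- dur >= params$min_duration_ms
  m_on <- m_on[keep]; m_off <- m_off[keep]; m_edge <- m_edge[keep]
  if (length(m_on) == 0L) return(empty_reach_set())

  amp <- numeric(length(m_on)); pv <- numeric(length(m_on))
  dirn <- numeric(length(m_on))
  for (i in seq_along(m_on)) {
    sl <- m_on[i]:m_off[i]
    d <- dsm[sl]
    apex <- sl[which.max(d)]
    amp[i] <- d[which.max(d)]
    dirn[i] <- atan2(series$y_cm[apex] - baseline[2L],
                     series$x_cm[apex] - baseline[1L])
    pv[i] <- if (length(sl) > 1L) max(c(diff(d), 0)) / tick * 1000 else 0
  }
  structure(
    data.frame(onset_ms = series$t_ms[m_on], offset_ms = series$t_ms[m_off],
               amplitude_cm = amp, peak_velocity_cm_s = pv,
               duration_ms = (m_off - m_on) * tick, direction_rad = dirn,
               edge = m_edge, rewarded = NA,
               onset_idx = m_on, offset_idx = m_off),
    class = c("reach_set", "data.frame"))
}

empty_reach_set <- function() {
  structure(
    data.frame(onset_ms = numeric(), offset_ms = numeric(),
               amplitude_cm = numeric(), peak_velocity_cm_s = numeric(),
               duration_ms = numeric(), direction_rad = numeric(),
               edge = logical(), rewarded = logical(),
               onset_idx = integer(), offset_idx = integer()),
    class = c("reach_set", "data.frame"))
}

smooth_displacement <- function(disp, smooth_ms, tick) {
  if (smooth_ms <= 0) return(disp)
  w <- max(1L, round(smooth_ms / tick))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(disp)
  sm <- stats::filter(disp, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- disp[is.na(sm)]
  as.numeric(sm)
}

#' Extract the trajectory slice of one reach
#'
#' @param series the session position series.
#' @param reaches a `reach_set` from [detect_reaches()].
#' @param i reach row index.
#' @return the rows of `series` spanned by reach `i`.
#' @export
reach_trajectory <- function(series, reaches, i) {
  series[reaches$onset_idx[i]:reaches$offset_idx[i], , drop = FALSE]
}

#' Kinematic metrics of a segmented reach
#'
#' Amplitude is the peak radial displacement; peak outward velocity the
#' maximum positive forward difference of displacement per tick; duration
#' the onset-to-offset time.
#'
#' @param series the session position series.
#' @param baseline `c(x0, y0)`.
#' @param onset_idx,offset_idx sample indices of the reach span.
#' @param tick_ms sampling period.
#' @return a list with `amplitude_cm`, `peak_velocity_cm_s`, `duration_ms`.
#' @export
reach_kinematics <- function(series, baseline, onset_idx, offset_idx,
                             tick_ms = 1) {
  sl <- onset_idx:offset_idx
  d <- radial_displacement(series$x_cm[sl], series$y_cm[sl], baseline)
  pv <- if (length(sl) > 1L) max(c(diff(d), 0)) / tick_ms * 1000 else 0
  list(amplitude_cm = max(d), peak_velocity_cm_s = pv,
       duration_ms = (offset_idx - onset_idx) * tick_ms)
}

#' Flag reaches that earned a reward
#'
#' Joins a reach set with a session's event log: a reach is rewarded when
#' the threshold crossing of a rewarded trial falls inside its
#' `[onset, offset]` span.
#'
#' @param reaches a `reach_set`.
#' @param events event-log data frame.
#' @return the reach set with its `rewarded` column filled in.
#' @export
mark_rewarded <- function(reaches, events) {
  cross_t <- rewarded_cross_times(events)
  reaches$rewarded <- vapply(seq_len(nrow(reaches)), function(i)
    any(cross_t >= reaches$onset_ms[i] & cross_t <= reaches$offset_ms[i]),
    logical(1))
  reaches
}

# threshold-crossing times of trials that went on to be rewarded
rewarded_cross_times <- function(events) {
  rew <- events[events$kind == "reward", , drop = FALSE]
  cross <- events[events$kind == "threshold_cross", , drop = FALSE]
  cross$t_ms[cross$trial %in% rew$trial]
}

#' Inter-reach intervals
#'
#' Onset-to-onset differences of consecutive reaches (ms).  In a rewarded
#' basic-task session the reward delay plus the fixed 3-s ITI puts a
#' floor under these intervals.
#'
#' @param reaches a `reach_set` (time-ordered).
#' @return numeric vector of length `max(n - 1, 0)`.
#' @export
inter_reach_intervals <- function(reaches) {
  if (nrow(reaches) < 2L) return(numeric())
  diff(reaches$onset_ms)
}

#' Reaction times of rewarded reaches
#'
#' For each rewarded reach, RT is the reach onset time minus the most
#' recent go-cue onset at or before the reach's threshold crossing.
#' Reaction times above 5 s are omitted; the boundary is inclusive (an RT
#' of exactly 5000 ms is retained).  Rewarded reaches with no preceding
#' cue are skipped with a warning.
#'
#' @param session a `session_record` (reaction-time variant).
#' @param reaches its `reach_set`, already passed through
#'   [mark_rewarded()] (done automatically if `rewarded` is all `NA`).
#' @param max_rt_ms omission bound (ms, strict `>`).
#' @return numeric vector of retained RTs, in session order.
#' @export
reaction_times <- function(session, reaches, max_rt_ms = 5000) {
  if (all(is.na(reaches$rewarded)))
    reaches <- mark_rewarded(reaches, session$events)
  cues <- session$events$t_ms[session$events$kind == "cue_on"]
  cross_t <- rewarded_cross_times(session$events)
  rr <- reaches[which(reaches$rewarded), , drop = FALSE]
  rts <- numeric()
  for (i in seq_len(nrow(rr))) {
    ct <- cross_t[cross_t >= rr$onset_ms[i] & cross_t <= rr$offset_ms[i]]
    ct <- ct[1L]
    k <- findInterval(ct, cues)
    if (k == 0L) {
      warning("rewarded reach at t=", rr$onset_ms[i],
              " has no preceding cue; skipped")
      next
    }
    rts <- c(rts, rr$onset_ms[i] - cues[k])
  }
  rts[rts <= max_rt_ms]
}

#' Running mean of the last five reaction times
#'
#' Element *i* is the mean of `rts[max(1, i - window + 1) .. i]`, the
#' statistic shown on the platform's LCD readout.
#'
#' @param rts numeric vector of reaction times.
#' @param window window length.
#' @return numeric vector the same length as `rts`.
#' @export
moving_average_rt <- function(rts, window = 5L) {
  n <- length(rts)
  if (n == 0L) return(numeric())
  vapply(seq_len(n), function(i) mean(rts[max(1L, i - window + 1L):i]), 0)
}

#' Session summary
#'
#' Counts, retained reaction times and their running mean, inter-reach
#' intervals, and the expert flag: more than 100 rewarded reaches in a
#' session run at the 0.9-cm expert threshold.
#'
#' @param session a `session_record`.
#' @param reaches its `reach_set` (rewarded flags filled in if missing).
#' @param expert_threshold_cm amplitude threshold qualifying for expert
#'   level.
#' @param expert_n rewarded-reach count that must be strictly exceeded.
#' @return an object of class `session_summary`.
#' @export
session_summary <- function(session, reaches,
                            expert_threshold_cm = 0.9, expert_n = 100L) {
  if (nrow(reaches) > 0L && all(is.na(reaches$rewarded)))
    reaches <- mark_rewarded(reaches, session$events)
  n_rewarded <- sum(session$events$kind == "reward")
  rts <- if (session$config$variant == "reaction_time")
           reaction_times(session, reaches) else numeric()
  structure(
    list(n_reaches = nrow(reaches),
         n_rewarded = n_rewarded,
         n_punishments = sum(session$events$kind == "punishment_start"),
         rts = rts,
         median_rt = if (length(rts)) stats::median(rts) else NA_real_,
         moving_avg_rt5 = moving_average_rt(rts),
         iri = inter_reach_intervals(reaches),
         amp_threshold = session$config$amp_threshold,
         expert = n_rewarded > expert_n &&
                  session$config$amp_threshold >= expert_threshold_cm),
    class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf(
    "<session_summary> %d reaches | %d rewarded | %d punished | median RT %s ms | expert: %s\n",
    x$n_reaches, x$n_rewarded, x$n_punishments,
    ifelse(is.na(x$median_rt), "-", format(x$median_rt)),
    x$expert))
  invisible(x)
}
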