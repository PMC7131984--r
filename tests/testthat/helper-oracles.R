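# Independent brute-force oracles and fixture builders.  These
# deliberately re-derive results sample by sample, without reusing the
# package's vectorized internals.

# Brute-force reach segmentation: label supra-threshold runs, walk each
# boundary outward to the sub-level samples, merge nearby runs, filter by
# duration.  Returns a data.frame of onset/offset sample indices.
oracle_detect <- function(disp, tick, detect, onset_frac = 0.1,
                          min_dur = 50, merge_gap = 20) {
  n <- length(disp)
  level <- onset_frac * detect
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (disp[i] >= detect) {
      j <- i
      while (j < n && disp[j + 1L] >= detect) j <- j + 1L
      a <- i
      while (a > 1L && disp[a - 1L] >= level) a <- a - 1L
      b <- j
      while (b < n && disp[b + 1L] >= level) b <- b + 1L
      runs[[length(runs) + 1L]] <- c(a, b)
      i <- b + 1L
    } else i <- i + 1L
  }
  if (length(runs) == 0L)
    return(data.frame(onset = integer(), offset = integer()))
  merged <- list(runs[[1L]])
  for (r in runs[-1L]) {
    last <- merged[[length(merged)]]
    if ((r[1L] - last[2L] - 1L) * tick < merge_gap)
      merged[[length(merged)]] <- c(last[1L], max(last[2L], r[2L]))
    else merged[[length(merged) + 1L]] <- r
  }
  on <- vapply(merged, `[`, 0, 1L)
  off <- vapply(merged, `[`, 0, 2L)
  keep <- (off - on) * tick >= min_dur
  data.frame(onset = on[keep], offset = off[keep])
}

# Straight-line event scan for the basic center-out task: re-derives the
# event log from a displacement series and the stated rules alone.
oracle_center_out_events <- function(disp, tick, threshold, delay, iti) {
  n <- length(disp)
  ev <- data.frame(t_ms = numeric(), kind = character())
  add <- function(t, k) ev <<- rbind(ev, data.frame(t_ms = t, kind = k))
  t <- 0
  add(0, "trial_start")
  i <- 1L
  repeat {
    # first crossing at or after sample i (1-based; sample i is t=(i-1)*tick)
    cross <- which(disp[i:n] >= threshold)
    if (length(cross) == 0L) break
    ci <- i + cross[1L] - 1L
    tc <- (ci - 1L) * tick
    add(tc, "threshold_cross")
    tr <- tc + delay
    if (tr > (n - 1L) * tick) break
    add(tr, "reward"); add(tr, "iti_start")
    ts <- tr + iti
    if (ts > (n - 1L) * tick) break
    add(ts, "trial_start")
    i <- ts / tick + 1L
  }
  ev
}

# Build a series from a radial displacement profile along +y.
series_from_disp <- function(disp, tick = 1) {
  data.frame(t_ms = (seq_along(disp) - 1) * tick, x_cm = 0, y_cm = disp)
}

# Noise-free displacement of one out-and-back minimum-jerk reach embedded
# in a flat trace.
mj_disp <- function(n, onset_idx, A, D, tick = 1) {
  disp <- numeric(n)
  s <- seq(0, D, by = tick)
  prof <- vapply(s, function(si) {
    half <- D / 2
    if (si <= half) minimum_jerk_profile(A, half, si)
    else minimum_jerk_profile(A, half, D - si)
  }, 0)
  idx <- onset_idx + seq_along(s) - 1L
  ok <- idx <= n
  disp[idx[ok]] <- prof[ok]
  disp
}

# Drive the pure-R engine over a scripted sample stream; returns events.
run_stream <- function(cfg, x, y, draws = NULL) {
  if (is.null(draws)) draws <- live_draws(cfg)
  st <- engine_init(cfg)
  out <- list()
  for (i in seq_along(x)) {
    res <- engine_step(st, (i - 1) * cfg$tick_ms, x[i], y[i], cfg, draws)
    if (nrow(res$events) > 0L) out[[length(out) + 1L]] <- res$events
  }
  if (length(out) == 0L)
    return(data.frame(t_ms = numeric(), kind = character(),
                      trial = integer(), payload = character()))
  do.call(rbind, out)
}

# Fixed draw provider for engine unit tests.
fixed_draws <- function(cue_delay = 2000, punish_iti = 4000,
                        bandit_u = 0.5, switch_u = 0.99) {
  list(cue_delay = function() cue_delay,
       bandit_u = function() bandit_u,
       switch_u = function() switch_u,
       punish_iti = function() punish_iti)
}

# Minimal session_summary stand-in for trainer unit tests.
fake_summary <- function(n_rewarded) {
  structure(list(n_reaches = n_rewarded, n_rewarded = n_rewarded,
                 n_punishments = 0L, rts = numeric(), median_rt = NA_real_,
                 moving_avg_rt5 = numeric(), iri = numeric(),
                 amp_threshold = NA_real_, expert = FALSE),
            class = "session_summary")
}

# Quiet agents for engine-focused runs.
null_agent <- function() agent_params(reach_rate = 0, blip_rate = 0,
                                      jitter_sd = 0, revup_prob = 0,
                                      anticip_prob = 0)
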