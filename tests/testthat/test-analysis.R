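test_that("a single noise-free reach is segmented exactly", {
  disp <- mj_disp(3000, onset_idx = 1001, A = 1.2, D = 400)
  reaches <- detect_reaches(series_from_disp(disp), c(0, 0),
                            segmentation_params(detect_threshold = 0.5))
  expect_equal(nrow(reaches), 1)
  expect_equal(reaches$amplitude_cm, 1.2)
  # onset/offset land where the profile passes 10% of the detect threshold
  expect_lt(abs(reaches$onset_ms - 1000), 60)
  expect_equal(reaches$direction_rad, pi / 2)
  expect_false(reaches$edge)
  expect_error(detect_reaches(series_from_disp(disp), c(0, 0),
                              segmentation_params(detect_threshold = 0)),
               "detect_threshold")
})

test_that("pure jitter produces no reaches at a 6-sigma detection threshold", {
  cfg <- task_config("center_out", amp_threshold = 2.4, session_ms = 1800000L)
  ag <- agent_params(reach_rate = 0, blip_rate = 0, jitter_sd = 0.02)
  rec <- run_session(cfg, ag, seed = 41)
  reaches <- detect_reaches(rec$series, cfg$baseline,
                            segmentation_params(detect_threshold = 6 * 0.02))
  expect_equal(nrow(reaches), 0)
})

test_that("blips below the detection threshold are ignored", {
  disp <- mj_disp(4000, 501, A = 0.15, D = 150) +
          mj_disp(4000, 2001, A = 1.0, D = 400)
  reaches <- detect_reaches(series_from_disp(disp), c(0, 0),
                            segmentation_params(detect_threshold = 0.5))
  expect_equal(nrow(reaches), 1)
  expect_equal(reaches$amplitude_cm, 1.0)
})

test_that("nearby supra-threshold runs merge per the gap rule", {
  # two crossings separated by 10 ms of sub-level samples
  disp <- numeric(2000)
  disp[501:600] <- 0.8
  disp[611:710] <- 0.8          # gap of 10 sub-level samples
  disp[1001:1100] <- 0.8        # far away: stays separate
  p <- segmentation_params(detect_threshold = 0.5, merge_gap_ms = 20)
  reaches <- detect_reaches(series_from_disp(disp), c(0, 0), p)
  ref <- oracle_detect(disp, 1, 0.5, merge_gap = 20)
  expect_equal(nrow(reaches), 2)
  expect_equal(reaches$onset_idx, ref$onset)
  expect_equal(reaches$offset_idx, ref$offset)
})

test_that("segmentation matches the brute-force oracle on random traces", {
  set.seed(100)
  for (rep in 1:200) {
    n <- 1500
    disp <- abs(stats::filter(rnorm(n, 0, 0.4), rep(1, 25), sides = 1,
                              circular = TRUE)) / 5
    disp <- as.numeric(disp)
    detect <- runif(1, 0.2, 0.6)
    gap <- sample(c(5, 20, 40), 1)
    md <- sample(c(20, 50, 80), 1)
    p <- segmentation_params(detect_threshold = detect, merge_gap_ms = gap,
                             min_duration_ms = md)
    got <- detect_reaches(series_from_disp(disp), c(0, 0), p)
    ref <- oracle_detect(disp, 1, detect, 0.1, md, gap)
    expect_equal(got$onset_idx, ref$onset)
    expect_equal(got$offset_idx, ref$offset)
  }
})

test_that("segmentation is idempotent and monotone in the threshold", {
  cfg <- task_config("center_out", amp_threshold = 0.5, session_ms = 300000L)
  rec <- run_session(cfg, agent_params(reach_rate = 0.4), seed = 55)
  p <- segmentation_params(detect_threshold = 0.5)
  r1 <- detect_reaches(rec$series, cfg$baseline, p)
  r2 <- detect_reaches(rec$series, cfg$baseline, p)
  expect_identical(r1, r2)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2), function(thr)
    nrow(detect_reaches(rec$series, cfg$baseline,
                        segmentation_params(detect_threshold = thr))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("kinematics recover amplitude exactly and peak velocity to 1%", {
  A <- 1.0; D_out <- 400                # 400-ms outward half
  disp <- mj_disp(3000, 1001, A = A, D = 2 * D_out)
  reaches <- detect_reaches(series_from_disp(disp), c(0, 0),
                            segmentation_params(detect_threshold = 0.5))
  expect_equal(reaches$amplitude_cm, A)
  expect_equal(reaches$peak_velocity_cm_s, 1.875 * A / (D_out / 1000),
               tolerance = 0.01)

  # degenerate constant-position span has zero outward velocity
  flat <- data.frame(t_ms = 0:99, x_cm = 1, y_cm = 0)
  k <- reach_kinematics(flat, c(0, 0), 1, 100)
  expect_equal(k$peak_velocity_cm_s, 0)
  expect_equal(k$amplitude_cm, 1)
})

test_that("planned reaches are recovered within the profile's truncation bound", {
  # The onset/offset level q*A truncates each minimum-jerk half-movement at
  # tau* solving 10 t^3 - 15 t^4 + 6 t^5 = q; measured duration should be
  # D - 2 tau* (D/2) to within a tick per side.
  quiet <- agent_params(jitter_sd = 0)
  A <- 1.2; D <- 500; detect <- 0.5; onset_frac <- 0.1
  plan <- reach_plan(direction = pi / 2, amplitude = A, duration_ms = D)
  tr <- generate_reach(plan, quiet)
  n <- 2000
  series <- data.frame(t_ms = 0:(n - 1), x_cm = 0, y_cm = 0)
  series$x_cm[501 + tr$t_ms] <- tr$dx_cm
  series$y_cm[501 + tr$t_ms] <- tr$dy_cm
  reaches <- detect_reaches(series, c(0, 0),
                            segmentation_params(detect_threshold = detect,
                                                onset_frac = onset_frac))
  expect_equal(reaches$amplitude_cm, A)
  q <- onset_frac * detect / A
  tau_star <- uniroot(function(x) 10 * x^3 - 15 * x^4 + 6 * x^5 - q,
                      c(0, 0.5), tol = 1e-12)$root
  expected_dur <- D - 2 * tau_star * (D / 2)
  expect_lt(abs(reaches$duration_ms - expected_dur), 2.5)
})

test_that("inter-reach intervals are onset-to-onset", {
  r <- structure(
    data.frame(onset_ms = c(0, 4000, 9000), offset_ms = c(300, 4300, 9300)),
    class = c("reach_set", "data.frame"))
  expect_equal(inter_reach_intervals(r), c(4000, 5000))
  expect_equal(inter_reach_intervals(r[1, ]), numeric())
})

test_that("rewarded reaches in a basic-task session respect the ITI floor", {
  cfg <- task_config("center_out", amp_threshold = 0.5, session_ms = 600000L)
  rec <- run_session(cfg, agent_params(reach_rate = 0.3), seed = 61)
  reaches <- detect_reaches(rec$series, cfg$baseline,
                            segmentation_params(detect_threshold = 0.5))
  reaches <- mark_rewarded(reaches, rec$events)
  rew <- reaches[reaches$rewarded, ]
  expect_gt(nrow(rew), 10)
  expect_true(all(diff(rew$onset_ms) >= cfg$iti_ms))
})

test_that("reaction times subtract the latest cue and omit > 5 s strictly", {
  # arithmetic + boundary behavior on a hand-built record
  mk_rec <- function(cues, cross, onsets) {
    ev <- rbind(
      data.frame(t_ms = cues, kind = "cue_on", trial = seq_along(cues),
                 payload = sprintf("trial=%d", seq_along(cues))),
      data.frame(t_ms = cross, kind = "threshold_cross",
                 trial = seq_along(cross),
                 payload = sprintf("trial=%d", seq_along(cross))),
      data.frame(t_ms = cross + 1000, kind = "reward",
                 trial = seq_along(cross),
                 payload = sprintf("trial=%d", seq_along(cross))))
    ev <- ev[order(ev$t_ms), ]
    structure(list(meta = list(), events = ev,
                   config = task_config("reaction_time")),
              class = "session_record")
  }
  mk_reaches <- function(onsets, offsets) {
    structure(data.frame(onset_ms = onsets, offset_ms = offsets,
                         rewarded = TRUE),
              class = c("reach_set", "data.frame"))
  }
  rec <- mk_rec(cues = c(2000, 20000, 40000),
                cross = c(2500, 25300, 45100))
  reaches <- mk_reaches(c(2400, 25200, 45000), c(2900, 25700, 45500))
  # RTs: 400, 5200 (omitted), 5000 (kept: omission is strictly > 5000)
  expect_equal(reaction_times(rec, reaches), c(400, 5000))

  # a rewarded reach with no preceding cue is skipped with a warning
  rec2 <- mk_rec(cues = 10000, cross = 2500)
  reaches2 <- mk_reaches(2400, 2900)
  expect_warning(rts2 <- reaction_times(rec2, reaches2), "no preceding cue")
  expect_equal(rts2, numeric())
})

test_that("the running RT average uses the last five values", {
  expect_equal(moving_average_rt(c(100, 200, 300, 400, 500, 600)),
               c(100, 150, 200, 250, 300, 400))
  expect_equal(moving_average_rt(250), 250)
  expect_equal(moving_average_rt(rep(7, 10)), rep(7, 10))
  expect_equal(moving_average_rt(numeric()), numeric())
})

empty_reach_set_for_test <- function() {
  structure(data.frame(onset_ms = numeric(), offset_ms = numeric(),
                       rewarded = logical()),
            class = c("reach_set", "data.frame"))
}

test_that("the expert criterion needs >100 rewarded reaches at the 0.9-cm threshold", {
  mk <- function(n_rewarded, thr) {
    ev <- data.frame(t_ms = seq_len(n_rewarded) * 5000, kind = "reward",
                     trial = seq_len(n_rewarded),
                     payload = sprintf("trial=%d", seq_len(n_rewarded)))
    rec <- structure(list(meta = list(), events = ev,
                          config = task_config("center_out",
                                               amp_threshold = thr)),
                     class = "session_record")
    session_summary(rec, empty_reach_set_for_test())
  }
  expect_true(mk(101, 0.9)$expert)
  expect_false(mk(100, 0.9)$expert)   # strict >
  expect_false(mk(150, 0.5)$expert)   # threshold clause
})
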