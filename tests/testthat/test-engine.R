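test_that("radial displacement is the Euclidean distance from baseline", {
  expect_equal(radial_displacement(0.6, 0.8, c(0, 0)), 1.0)
  expect_equal(radial_displacement(0.1, -0.1, c(0.1, -0.1)), 0.0)
  # the expert threshold distance, straight along one axis
  expect_equal(radial_displacement(0.9, 0, c(0, 0)), 0.9)
  # symmetric in axes and vectorized
  expect_equal(radial_displacement(c(1, 0), c(0, 1)), c(1, 1))
})

test_that("baseline estimation is a componentwise median over the settling window", {
  const <- data.frame(t_ms = 0:599, x_cm = 0.1, y_cm = -0.1)
  expect_equal(estimate_baseline(const), c(0.1, -0.1))

  spiky <- data.frame(t_ms = 0:499, x_cm = 0, y_cm = 0)
  spiky$x_cm[250] <- 2.0; spiky$y_cm[250] <- -2.0
  expect_equal(estimate_baseline(spiky), c(0, 0))

  set.seed(11)
  jit <- data.frame(t_ms = 0:499,
                    x_cm = runif(500, -0.05, 0.05),
                    y_cm = runif(500, -0.05, 0.05))
  # independent oracle: sort-based median of exactly the window samples
  med <- function(v) { s <- sort(v); (s[250] + s[251]) / 2 }
  expect_equal(estimate_baseline(jit, 500), c(med(jit$x_cm), med(jit$y_cm)))

  expect_error(estimate_baseline(jit[1:100, ], 500), "settling")
})

test_that("direction classification respects sector spans and boundaries", {
  sch <- bandit_schedule()  # forward/backward, half-width 45 deg
  expect_equal(classify_direction(0, 1, sch), "forward")
  expect_equal(classify_direction(0, -1, sch), "backward")
  # exactly on the exclusive upper boundary of both sectors -> none
  expect_true(is.na(classify_direction(1, 0, sch)))
  expect_error(classify_direction(0, 0, sch), "zero")

  # brute-force angle check over random vectors
  set.seed(21)
  for (i in 1:200) {
    v <- rnorm(2)
    ang <- atan2(v[2], v[1])
    ref <- NA_character_
    for (k in 1:2) {
      d <- ang - sch$centers[k]
      d <- d - 2 * pi * floor((d + pi) / (2 * pi))  # wrap to (-pi, pi]
      if (d >= -sch$halfwidth && d < sch$halfwidth) { ref <- sch$labels[k]; break }
    }
    expect_identical(classify_direction(v[1], v[2], sch), ref)
  }
})

test_that("center-out FSM: crossing -> delayed reward -> fixed ITI -> next trial", {
  cfg <- task_config("center_out", amp_threshold = 0.9, session_ms = 20000L)
  disp <- numeric(16000)
  disp[10001:10201] <- 1.0            # crossing at t = 10000
  ev <- run_stream(cfg, rep(0, 16000), disp)

  expect_equal(ev$t_ms[ev$kind == "trial_start"], c(0, 14000))
  expect_equal(ev$t_ms[ev$kind == "threshold_cross"], 10000)
  expect_equal(ev$t_ms[ev$kind == "reward"], 11000)      # 1-s delay
  expect_equal(ev$t_ms[ev$kind == "iti_start"], 11000)   # 3-s ITI follows
  # re-arm rule: the sustained supra-threshold plateau yields one crossing
  expect_equal(sum(ev$kind == "threshold_cross"), 1)
})

test_that("reward is latched at the crossing tick even if the joystick returns", {
  cfg <- task_config("center_out", amp_threshold = 0.5, session_ms = 8000L)
  disp <- numeric(8000)
  disp[2001:2050] <- 0.6              # brief crossing, then back to rest
  ev <- run_stream(cfg, rep(0, 8000), disp)
  expect_equal(ev$t_ms[ev$kind == "reward"], 2000 + 1000)
})

test_that("VAO threshold follows the per-trial schedule", {
  cfg <- task_config("vao", amp_threshold = 0.3, session_ms = 20000L,
                     vao_schedule = data.frame(trial = c(1, 2),
                                               threshold = c(0.3, 0.6)))
  disp <- numeric(20000)
  disp[1001:1101] <- 0.4              # crosses 0.3 (trial 1)
  disp[8001:8101] <- 0.4              # sub-threshold for trial 2 (0.6)
  disp[12001:12101] <- 0.7            # crosses 0.6
  ev <- run_stream(cfg, rep(0, 20000), disp)
  crosses <- ev[ev$kind == "threshold_cross", ]
  expect_equal(crosses$t_ms, c(1000, 12000))
  expect_equal(payload_field(crosses$payload, "threshold"), c(0.3, 0.6))
})

test_that("reaction-time FSM: anticipatory crossing is punished, cued crossing rewarded", {
  cfg <- task_config("reaction_time", amp_threshold = 0.5, session_ms = 30000L)
  draws <- fixed_draws(cue_delay = 2000, punish_iti = 4000)

  # crossing 200 ms before the cue
  disp <- numeric(30000)
  disp[1801:1901] <- 0.6
  ev <- run_stream(cfg, rep(0, 30000), disp, draws)
  pun <- ev[ev$kind == "punishment_start", ]
  expect_equal(pun$t_ms, 1800)
  expect_equal(payload_field(pun$payload, "timeout"), 5000)
  expect_equal(sum(ev$kind == "reward"), 0)
  # timeout then the drawn random ITI, then trial restart
  expect_equal(ev$t_ms[ev$kind == "iti_start"], 1800 + 5000)
  expect_equal(ev$t_ms[ev$kind == "trial_start"], c(0, 1800 + 5000 + 4000))
  # no cue_on or reward during the timeout phase
  in_timeout <- ev$t_ms > 1800 & ev$t_ms < 6800
  expect_false(any(ev$kind[in_timeout] %in% c("cue_on", "reward")))

  # crossing after the cue is rewarded exactly as in center-out
  disp2 <- numeric(30000)
  disp2[2501:2601] <- 0.6
  ev2 <- run_stream(cfg, rep(0, 30000), disp2, draws)
  expect_equal(ev2$t_ms[ev2$kind == "cue_on"][1], 2000)
  expect_equal(ev2$t_ms[ev2$kind == "threshold_cross"], 2500)
  expect_equal(ev2$t_ms[ev2$kind == "reward"], 3500)
})

test_that("pre-cue crossings are ignored when punishment is disabled", {
  cfg <- task_config("reaction_time", amp_threshold = 0.5,
                     punishment = FALSE, session_ms = 10000L)
  disp <- numeric(10000)
  disp[1001:9000] <- 0.6               # held out from before the cue
  ev <- run_stream(cfg, rep(0, 10000), disp, fixed_draws(cue_delay = 2000))
  expect_equal(sum(ev$kind == "punishment_start"), 0)
  # armed only at each cue onset; the held position crosses at the cue tick
  # (trial 2 starts at 6000, its cue fires at 8000)
  expect_equal(ev$t_ms[ev$kind == "threshold_cross"], c(2000, 8000))
})

test_that("bandit FSM rewards by sector probability and swaps blocks", {
  sch <- bandit_schedule(p_reward = c(0.8, 0.2), min_block_trials = 1L,
                         switch_prob = 0.5)
  cfg <- task_config("bandit", amp_threshold = 0.5, session_ms = 30000L,
                     bandit = sch)
  disp <- numeric(30000)
  disp[1001:1101] <- 0.6   # forward reach (we script y = disp)
  disp[8001:8101] <- 0.6
  # u = 0.5 < p_forward = 0.8 -> rewarded; switch_u = 0.1 < 0.5 -> swap
  ev <- run_stream(cfg, rep(0, 30000), disp,
                   fixed_draws(bandit_u = 0.5, switch_u = 0.1))
  cross1 <- ev[ev$kind == "threshold_cross", ][1, ]
  expect_equal(payload_field_chr(cross1$payload, "direction"), "forward")
  expect_equal(payload_field(cross1$payload, "p"), 0.8)
  expect_equal(ev$t_ms[ev$kind == "reward"][1], 2000)
  sw <- ev[ev$kind == "block_switch", ]
  expect_equal(nrow(sw), 1)
  expect_equal(payload_field(sw$payload, "p1"), 0.2)  # swapped
  # second crossing is drawn against the swapped forward probability
  cross2 <- ev[ev$kind == "threshold_cross", ][2, ]
  expect_equal(payload_field(cross2$payload, "p"), 0.2)
  # u = 0.5 >= 0.2 -> unrewarded: trial ends straight into the ITI
  expect_equal(ev$t_ms[ev$kind == "iti_start"][2], 8000)
  expect_equal(sum(ev$kind == "reward"), 1)
})

test_that("engine rejects non-contiguous timestamps", {
  cfg <- task_config("center_out", session_ms = 1000L)
  st <- engine_init(cfg)
  draws <- live_draws(cfg)
  engine_step(st, 0, 0, 0, cfg, draws)
  expect_error(engine_step(st, 5, 0, 0, cfg, draws), "non-contiguous")
})
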