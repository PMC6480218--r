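test_that("yaw rate differentiates exactly on simple signals", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  r <- yaw_rate(make_cond(0.4 * t, fs))
  expect_equal(r, rep(0.4, length(t)), tolerance = 1e-9)
  expect_equal(yaw_rate(make_cond(rep(0.7, 100), fs)), rep(0, 100))

  # logistic transition: derivative peaks at the inflection
  tl <- seq(0, 10, by = 1 / fs)
  lg <- 1 / (1 + exp(-4 * (tl - 5)))
  rr <- yaw_rate(make_cond(lg, fs))
  expect_lte(abs(tl[which.max(rr)] - 5), 0.01 + 1e-9)
})

test_that("turn extrema must appear in rise-then-fall order", {
  fs <- 100
  t <- seq(0, 12, by = 1 / fs)
  up <- 3 * pmin(1, pmax(0, (t - 3.5) / 1))^2 - 2 * pmin(1, pmax(0, (t - 3.5) / 1))^3
  x <- up - (3 * pmin(1, pmax(0, (t - 7.5) / 1))^2 -
               2 * pmin(1, pmax(0, (t - 7.5) / 1))^3)
  r <- yaw_rate(make_cond(x, fs))
  ext <- locate_turn_extrema(r, t)
  expect_lt(abs(ext$t_max - 4), 0.05)
  expect_lt(abs(ext$t_min - 8), 0.05)

  # sign-flipped signal: fall precedes rise -> detection error
  rf <- yaw_rate(make_cond(-x, fs))
  expect_error(locate_turn_extrema(rf, t), "turn order",
               class = "tugseg_detection_error")
})

test_that("window search brackets a piecewise-linear turn and mirrors for turn2", {
  fs <- 100
  t <- seq(0, 12, by = 1 / fs)
  x <- pmin(1, pmax(0, (t - 4) / 1.5)) # ramp [4, 5.5], plateaus 0 and 1
  b <- window_search_turn_bounds(make_cond(x, fs), 4.75, "turn1_3m")
  expect_lt(abs(b$t_start - 4), 0.15)
  expect_lt(abs(b$t_end - 5.5), 0.15)

  # mirrored descent, searched with the turn2 level criteria
  xr <- rev(x)
  Tend <- t[length(t)]
  br <- window_search_turn_bounds(make_cond(xr, fs), Tend - 4.75,
                                  "turn2_presit")
  expect_equal(br$t_start, Tend - b$t_end)
  expect_equal(br$t_end, Tend - b$t_start)
})

test_that("a plateau below the high level runs the search to the edge with a flag", {
  fs <- 100
  t <- seq(0, 12, by = 1 / fs)
  x <- 0.85 * pmin(1, pmax(0, (t - 4) / 1.5)) # never reaches 0.9
  b <- window_search_turn_bounds(make_cond(x, fs), 4.75, "turn1_3m")
  expect_true(b$clamped_right)
  expect_equal(b$t_end, t[length(t)])
})

test_that("both turns are recovered on the example trial", {
  sim <- simulate_tug(example_scenario(seed = 31))
  tt <- detect_turns(condition_yaw(sim$recording))
  tr <- sim$truth$boundaries
  expect_lt(abs(tt$turn1$t_start - tr[["turn1_i"]]), 0.15)
  expect_lt(abs(tt$turn1$t_end - tr[["turn1_f"]]), 0.35)
  expect_lt(abs(tt$turn2$t_start - tr[["turn2_i"]]), 0.35)
  expect_lt(abs(tt$turn2$t_end - tr[["turn2_f"]]), 0.15)
  expect_lte(tt$turn1$t_end, tt$turn2$t_start)
  expect_gt(tt$turn1$rotation_span, 90)
  expect_lt(tt$turn1$rotation_span, 270)
})

test_that("window levels hold on the flanking plateaus of detected turns", {
  # direct restatement of the level criteria on a detected turn
  sim <- simulate_tug(example_scenario(seed = 32))
  cond <- condition_yaw(sim$recording)
  tt <- detect_turns(cond)
  before <- cond$values[cond$t >= tt$turn1$t_start - 0.5 &
                          cond$t < tt$turn1$t_start]
  after <- cond$values[cond$t > tt$turn1$t_end &
                         cond$t <= tt$turn1$t_end + 0.5]
  expect_lt(mean(before), 0.02 + 0.05)
  expect_gt(mean(after), 0.9 - 0.05)
})

test_that("same-direction turns fail literally but are recovered in robust mode", {
  sc <- example_scenario(seed = 33, turn_direction = "same")
  sim <- simulate_tug(sc)
  cond <- condition_yaw(sim$recording)
  expect_error(detect_turns(cond), class = "tugseg_detection_error")

  cfg <- algorithm_config(robust_turns = TRUE)
  tt <- detect_turns(cond, cfg)
  tr <- sim$truth$boundaries
  expect_lt(abs(tt$turn1$t_start - tr[["turn1_i"]]), 0.35)
  expect_lt(abs(tt$turn1$t_end - tr[["turn1_f"]]), 0.35)
  expect_lt(abs(tt$turn2$t_start - tr[["turn2_i"]]), 0.35)
  expect_lt(abs(tt$turn2$t_end - tr[["turn2_f"]]), 0.35)
  expect_true(any(grepl("robust_mode", tt$turn1$flags)))
})

test_that("time-reversing the recording swaps and mirrors the turns", {
  sc <- example_scenario(seed = 34, noise_sd_angle = 0, noise_sd_acc = 0,
                         noise_sd_gyr = 0)
  sim <- simulate_tug(sc)
  rec <- sim$recording
  recr <- imu_recording(t = rec$t, fs = rec$fs,
                        pitch = rev(rec$pitch), yaw = rev(rec$yaw))
  tt <- detect_turns(condition_yaw(rec))
  ttr <- detect_turns(condition_yaw(recr))
  Tend <- rec$t[length(rec$t)]
  w <- 0.1 + 0.01 # one window + one sample
  expect_lt(abs(ttr$turn1$t_start - (Tend - tt$turn2$t_end)), w)
  expect_lt(abs(ttr$turn1$t_end - (Tend - tt$turn2$t_start)), w)
  expect_lt(abs(ttr$turn2$t_start - (Tend - tt$turn1$t_end)), w)
  expect_lt(abs(ttr$turn2$t_end - (Tend - tt$turn1$t_start)), w)
})

test_that("turn bounds are consistent across random young trials", {
  errs <- c()
  for (i in 1:30) {
    sim <- simulate_tug(random_scenario(5000 + i, "young"))
    tt <- detect_turns(condition_yaw(sim$recording))
    tr <- sim$truth$boundaries
    errs <- c(errs, abs(c(tt$turn1$t_start - tr[["turn1_i"]],
                          tt$turn1$t_end - tr[["turn1_f"]],
                          tt$turn2$t_start - tr[["turn2_i"]],
                          tt$turn2$t_end - tr[["turn2_f"]])))
  }
  expect_lt(median(errs), 0.2)
  expect_lt(max(errs), 0.5)
})
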