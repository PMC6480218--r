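test_that("the two most prominent separated inclination peaks are found", {
  fs <- 100
  t <- seq(0, 12, by = 1 / fs)
  x <- rc_bump(t, 0.4, 1.6, 1.0) + rc_bump(t, 8.4, 9.6, 0.9)
  pk <- find_posture_peaks(make_cond(x, fs), 3)
  expect_lt(abs(pk$t_peak1 - 1.0), 0.05)
  expect_lt(abs(pk$t_peak2 - 9.0), 0.05)

  expect_error(find_posture_peaks(make_cond(rep(0, 1201), fs), 3),
               class = "tugseg_detection_error")

  # a small third bump is never selected over the two dominant ones
  x3 <- x + rc_bump(t, 4.5, 5.5, 0.2)
  pk3 <- find_posture_peaks(make_cond(x3, fs), 3)
  expect_lt(abs(pk3$t_peak1 - 1.0), 0.05)
  expect_lt(abs(pk3$t_peak2 - 9.0), 0.05)
})

test_that("slope-stop search finds ramp feet, collapses on shallow slopes, clamps at edges", {
  fs <- 100
  t <- seq(0, 4, by = 1 / fs)
  # triangular bump with slope 1.0 /s on [1, 3], peak at t = 2
  tri <- pmax(0, 1 - abs(t - 2))
  b <- slope_search_bounds(make_cond(tri, fs), 2)
  expect_gte(b$t_start, 0.9)
  expect_lte(b$t_start, 1.1)
  expect_gte(b$t_end, 2.9)
  expect_lte(b$t_end, 3.1)
  expect_false(b$clamped_left)

  # slope 0.3 /s: lagged difference 0.03 < 0.05 everywhere -> fires at i = 0
  sh <- pmax(0, 0.45 - 0.3 * abs(t - 2))
  bs <- slope_search_bounds(make_cond(sh, fs), 2)
  expect_equal(bs$t_start, 2)
  expect_equal(bs$t_end, 2)

  # peak too close to the start: left bound clamps to 0 with a flag
  edge <- pmax(0, 1 - 2 * abs(t - 0.05))
  be <- slope_search_bounds(make_cond(edge, fs), 0.05)
  expect_equal(be$t_start, 0)
  expect_true(be$clamped_left)
})

test_that("stand and sit events are recovered on the example trial", {
  sim <- simulate_tug(example_scenario(seed = 21))
  cond <- condition_pitch(sim$recording)
  ev <- detect_stand_sit(cond)
  tr <- sim$truth$boundaries
  expect_lt(abs(ev$standing$t_start - tr[["standing_i"]]), 0.25)
  expect_lt(abs(ev$standing$t_end - tr[["standing_f"]]), 0.25)
  expect_lt(abs(ev$sitting$t_start - tr[["sitting_i"]]), 0.25)
  expect_lt(abs(ev$sitting$t_end - tr[["sitting_f"]]), 0.25)
  expect_lt(ev$standing$t_end, ev$sitting$t_start)
})

test_that("a recording truncated before the sit-down raises a detection error", {
  sim <- simulate_tug(example_scenario(seed = 22))
  rec <- sim$recording
  keep <- rec$t < sim$truth$boundaries[["sitting_i"]] - 0.3
  short <- imu_recording(t = rec$t[keep], fs = rec$fs,
                         pitch = rec$pitch[keep], yaw = rec$yaw[keep])
  expect_error(detect_stand_sit(condition_pitch(short)),
               class = "tugseg_detection_error")
})

test_that("noiseless posture bounds are tight", {
  sim <- simulate_tug(example_scenario(seed = 23, noise_sd_angle = 0,
                                       noise_sd_acc = 0, noise_sd_gyr = 0))
  ev <- detect_stand_sit(condition_pitch(sim$recording))
  tr <- sim$truth$boundaries
  errs <- c(ev$standing$t_start - tr[["standing_i"]],
            ev$standing$t_end - tr[["standing_f"]],
            ev$sitting$t_start - tr[["sitting_i"]],
            ev$sitting$t_end - tr[["sitting_f"]])
  expect_lt(max(abs(errs)), 0.15)
})

test_that("time reversal of a symmetric two-bump signal mirrors the bounds", {
  fs <- 100
  t <- seq(0, 12, by = 1 / fs)
  x <- rc_bump(t, 0.5, 1.7, 1.0) + rc_bump(t, 10.3, 11.5, 1.0)
  ev <- detect_stand_sit(make_cond(x, fs))
  evr <- detect_stand_sit(make_cond(rev(x), fs))
  Tend <- t[length(t)]
  expect_equal(evr$standing$t_start, Tend - ev$sitting$t_end)
  expect_equal(evr$standing$t_end, Tend - ev$sitting$t_start)
  expect_equal(evr$sitting$t_start, Tend - ev$standing$t_end)
  expect_equal(evr$sitting$t_end, Tend - ev$standing$t_start)
})

test_that("posture bounds are recovered across random young trials", {
  errs <- c()
  shallow <- c()
  for (i in 1:30) {
    sc <- random_scenario(4000 + i, "young")
    sim <- simulate_tug(sc)
    ev <- detect_stand_sit(condition_pitch(sim$recording))
    tr <- sim$truth$boundaries
    e <- abs(c(ev$standing$t_start - tr[["standing_i"]],
               ev$standing$t_end - tr[["standing_f"]],
               ev$sitting$t_start - tr[["sitting_i"]],
               ev$sitting$t_end - tr[["sitting_f"]]))
    errs <- c(errs, e)
    # a bump is shallow when its normalised flank slope approaches the
    # 0.05-per-0.1-s slope-stop threshold; those bounds may collapse
    amps <- c(sc$pitch_amp_stand, sc$pitch_amp_sit)
    rel <- amps / max(amps)
    slopes <- 2 * rel / c(sc$durations[["standing"]], sc$durations[["sitting"]])
    shallow <- c(shallow, rep(rep(slopes < 0.75, each = 2), 1))
  }
  expect_lt(median(errs), 0.15)
  expect_lt(max(errs[!shallow]), 0.5)
})
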