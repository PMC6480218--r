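mk_stand <- function(s, p, e, kind = "standing") {
  structure(list(kind = kind, t_start = s, t_peak = p, t_end = e,
                 peak_value = 1, flags = character(0)),
            class = "transition_event")
}
mk_turn <- function(s, m, e, which = "turn1_3m") {
  structure(list(which = which, t_start = s, t_end = e, t_extremum = m,
                 rotation_span = 180, flags = character(0)),
            class = "turn_event")
}

test_that("segments assemble into six ordered intervals with the right total", {
  seg <- assemble_segments(mk_stand(0.5, 1.1, 1.7),
                           mk_stand(9.9, 10.6, 11.4, "sitting"),
                           mk_turn(4.0, 4.9, 5.8),
                           mk_turn(8.6, 9.2, 9.7, "turn2_presit"))
  expect_equal(seg$total_time, 10.9)
  expect_equal(seg$intervals$first_walk, c(1.7, 4.0))
  expect_equal(seg$intervals$second_walk, c(5.8, 8.6))
  expect_equal(seg$gap, 0.2, tolerance = 1e-9)
  iv <- do.call(rbind, seg$intervals)
  expect_true(all(iv[, 2] >= iv[, 1]))
  # contiguity through the middle of the test
  expect_equal(seg$intervals$standing[2], seg$intervals$first_walk[1])
  expect_equal(seg$intervals$turn_3m[2], seg$intervals$second_walk[1])
  # durations plus the labelled gap account for the total exactly
  durs <- vapply(seg$intervals, function(x) x[2] - x[1], numeric(1))
  expect_equal(sum(durs) + seg$gap, seg$total_time, tolerance = 1e-9)
})

test_that("small boundary overlaps snap to the midpoint, large ones error", {
  seg <- assemble_segments(mk_stand(0.5, 1.1, 1.7),
                           mk_stand(9.70, 10.6, 11.4, "sitting"),
                           mk_turn(4.0, 4.9, 5.8),
                           mk_turn(8.6, 9.2, 9.75, "turn2_presit"))
  expect_equal(seg$intervals$presit_turn[2], 9.725)
  expect_equal(seg$intervals$sitting[1], 9.725)
  expect_true(any(grepl("snapped_midpoint", seg$flags)))

  expect_error(
    assemble_segments(mk_stand(0.5, 1.1, 1.7),
                      mk_stand(9.9, 10.6, 11.4, "sitting"),
                      mk_turn(8.6, 9.2, 9.7),
                      mk_turn(4.0, 4.9, 5.8, "turn2_presit")),
    class = "tugseg_consistency_error")
})

test_that("step counting respects prominence and minimum distance", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  x <- 9.81 + 2 * sin(2 * pi * 2 * t) # 4 full gait cycles at 2 Hz
  cfg <- algorithm_config(step_min_prominence = 0.5, step_min_distance = 0.3)
  expect_equal(count_steps(x, fs, cfg), 4L)
  expect_equal(count_steps(rep(9.81, 200), fs, cfg), 0L)

  # two candidate peaks 0.1 s apart merge under a 0.3-s minimum distance
  g <- function(c) exp(-((t - c) / 0.03)^2)
  expect_equal(count_steps(2 * g(1.0) + 1.8 * g(1.1), fs, cfg), 1L)
  expect_equal(count_steps(numeric(0), fs, cfg), 0L)
})

test_that("features recover generator amplitudes and fall back without gyro", {
  sc <- example_scenario(seed = 41, pitch_amp_stand = 6,
                         peak_turn_rate = 150)
  sim <- simulate_tug(sc)
  res <- run_pipeline(sim$recording)
  f <- res$features
  expect_gt(f$pitch_su, 5.4); expect_lt(f$pitch_su, 6.6)
  expect_gt(f$vel_t1, 135); expect_lt(f$vel_t1, 165)
  expect_gt(f$acc_su, 0)
  expect_true(is.integer(f$steps_w1) || f$steps_w1 %% 1 == 0)

  rec2 <- sim$recording
  rec2$gyr_z <- NULL
  res2 <- run_pipeline(rec2)
  expect_true("turn_rate_derived_from_yaw" %in% res2$features$flags)
  expect_gt(res2$features$vel_t1, 120)
  expect_lt(res2$features$vel_t1, 180)

  rec3 <- sim$recording
  rec3$acc_z <- NULL
  res3 <- run_pipeline(rec3)
  expect_true(is.na(res3$features$acc_su))
  expect_true(is.na(res3$features$steps_w1))
})

test_that("risk classification is a nondecreasing step function with validated cutoffs", {
  expect_equal(classify_risk(42.99)$category, "high")
  expect_equal(classify_risk(9.59)$category, "no")
  expect_equal(classify_risk(15.0)$category, "low")
  expect_error(classify_risk(10, thresholds = c(20, 10)),
               class = "tugseg_config_error")
  expect_error(classify_risk(-1), class = "tugseg_value_error")

  sev <- c(no = 0, low = 1, high = 2)
  cats <- sev[vapply(seq(1, 40, by = 0.5),
                     function(tt) classify_risk(tt)$category, character(1))]
  expect_true(all(diff(cats) >= 0))
})

test_that("the pipeline is deterministic and shift invariant", {
  sim <- simulate_tug(example_scenario(seed = 42))
  r1 <- run_pipeline(sim$recording)
  r2 <- run_pipeline(sim$recording)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(r1$segmentation, r1$features, r1$risk, f1)
  write_report(r2$segmentation, r2$features, r2$risk, f2)
  expect_identical(readLines(f1), readLines(f2))

  shifted <- sim$recording
  shifted$t <- shifted$t + 5
  r3 <- run_pipeline(shifted)
  expect_equal(r3$segmentation$total_time, r1$segmentation$total_time,
               tolerance = 1e-9)
})

test_that("pipeline errors carry the failing stage name", {
  sim <- simulate_tug(example_scenario(seed = 43, noise_sd_angle = 0,
                                       noise_sd_acc = 0, noise_sd_gyr = 0))
  rec <- sim$recording
  keep <- rec$t < sim$truth$boundaries[["sitting_i"]] - 0.3
  short <- imu_recording(t = rec$t[keep], fs = rec$fs,
                         pitch = rec$pitch[keep], yaw = rec$yaw[keep],
                         acc_z = rec$acc_z[keep])
  expect_error(run_pipeline(short), "posture_transitions",
               class = "tugseg_detection_error")
})

test_that("all six boundaries stay within half a second on simulated trials", {
  for (seed in c(51, 52)) {
    sim <- simulate_tug(example_scenario(seed = seed))
    res <- run_pipeline(sim$recording)
    err <- segmentation_error(sim$truth, res$segmentation)
    expect_lt(max(abs(err$boundary)), 0.5)
  }
})

test_that("noiseless step counts are recovered exactly through the pipeline", {
  sc <- example_scenario(seed = 44, noise_sd_angle = 0, noise_sd_acc = 0,
                         noise_sd_gyr = 0)
  sim <- simulate_tug(sc)
  res <- run_pipeline(sim$recording)
  expect_equal(res$features$steps_w1, sim$truth$steps$first_walk)
  expect_equal(res$features$steps_w2, sim$truth$steps$second_walk)
})
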