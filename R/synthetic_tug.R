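#' Define a synthetic TUG scenario
#'
#' Parameterises a simulated 3-m TUG trial: sub-task durations, the trunk
#' pitch morphology (sharp-peaked triangular inclination bumps spanning
#' exactly the standing and sitting intervals), the yaw morphology (cubic
#' smoothstep transitions of `turn_angle` degrees spanning exactly the
#' turn intervals), vertical-acceleration step oscillations and stand/sit
#' transients, mounting offsets and white measurement noise. Defaults are
#' a typical healthy young adult trial: sub-task durations 1.16, 2.51,
#' 1.65, 2.39, 1.03 and 1.48 s, trunk inclination excursions of 5.35 /
#' 6.25 degrees, 180-degree turns in opposite directions and sub-degree
#' orientation noise.
#'
#' With a smoothstep transition the peak turn rate is analytically
#' `1.5 * turn_angle / duration`; supplying `peak_turn_rate` therefore
#' sets both turn durations to `1.5 * turn_angle / peak_turn_rate` rather
#' than carrying an inconsistent free parameter.
#'
#' @param durations Named numeric vector of the six sub-task durations in
#'   seconds: standing, first_walk, turn_3m, second_walk, presit_turn,
#'   sitting.
#' @param presit_gap Quiet stance between the pre-sitting turn and the
#'   sitting transition, seconds. Default 0.
#' @param lead_in,lead_out Quiet sitting time before the first and after
#'   the last event, seconds (the zero-reference baseline is estimated
#'   from the lead-in). Defaults 1.5.
#' @param pitch_amp_stand,pitch_amp_sit Inclination bump amplitudes,
#'   degrees.
#' @param turn_angle Rotation per turn, degrees. Default 180.
#' @param turn_direction `"opposite"` (heading returns to baseline) or
#'   `"same"` (heading advances to twice the turn angle).
#' @param peak_turn_rate Optional peak turn rate in deg/s; overrides the
#'   turn durations as described above.
#' @param cadence Steps per second during walks and turns.
#' @param step_acc_amp Step-oscillation amplitude in vertical
#'   acceleration, m/s^2.
#' @param acc_amp_stand,acc_amp_sit Stand/sit vertical-acceleration
#'   transient amplitudes, m/s^2.
#' @param pitch_baseline,yaw_baseline Mounting offsets, degrees.
#' @param noise_sd_angle Orientation white-noise SD, degrees.
#' @param noise_sd_acc Accelerometer white-noise SD, m/s^2.
#' @param noise_sd_gyr Gyroscope white-noise SD, deg/s.
#' @param fs Sampling rate, Hz. Default 100.
#' @param seed Integer seed fixing the noise sample path.
#' @return A validated `tug_scenario` list.
#' @export
tug_scenario <- function(durations = c(standing = 1.16, first_walk = 2.51,
                                       turn_3m = 1.65, second_walk = 2.39,
                                       presit_turn = 1.03, sitting = 1.48),
                         presit_gap = 0,
                         lead_in = 1.5, lead_out = 1.5,
                         pitch_amp_stand = 5.35, pitch_amp_sit = 6.25,
                         turn_angle = 180,
                         turn_direction = c("opposite", "same"),
                         peak_turn_rate = NULL,
                         cadence = 1.8, step_acc_amp = 3.0,
                         acc_amp_stand = 6.5, acc_amp_sit = 6.1,
                         pitch_baseline = 0, yaw_baseline = 0,
                         noise_sd_angle = 0.3, noise_sd_acc = 0.4,
                         noise_sd_gyr = 2.0,
                         fs = 100, seed = 1L) {
  turn_direction <- match.arg(turn_direction)
  need <- c("standing", "first_walk", "turn_3m", "second_walk",
            "presit_turn", "sitting")
  if (!all(need %in% names(durations)))
    stop_tugseg(sprintf("durations must be named: %s",
                        paste(need, collapse = ", ")), "value_error")
  durations <- durations[need]
  if (!is.null(peak_turn_rate)) {
    if (peak_turn_rate <= 0)
      stop_tugseg("peak_turn_rate must be positive", "value_error")
    td <- 1.5 * turn_angle / peak_turn_rate
    durations[["turn_3m"]] <- td
    durations[["presit_turn"]] <- td
  }
  if (any(durations <= 0))
    stop_tugseg("all durations must be positive", "value_error")
  if (presit_gap < 0 || lead_in < 0 || lead_out < 0)
    stop_tugseg("gaps and lead times must be non-negative", "value_error")
  if (noise_sd_angle < 0 || noise_sd_acc < 0 || noise_sd_gyr < 0)
    stop_tugseg("noise SDs must be non-negative", "value_error")
  if (cadence <= 0) stop_tugseg("cadence must be positive", "value_error")
  structure(list(durations = durations, presit_gap = presit_gap,
                 lead_in = lead_in, lead_out = lead_out,
                 pitch_amp_stand = pitch_amp_stand,
                 pitch_amp_sit = pitch_amp_sit,
                 turn_angle = turn_angle, turn_direction = turn_direction,
                 cadence = cadence, step_acc_amp = step_acc_amp,
                 acc_amp_stand = acc_amp_stand, acc_amp_sit = acc_amp_sit,
                 pitch_baseline = pitch_baseline,
                 yaw_baseline = yaw_baseline,
                 noise_sd_angle = noise_sd_angle,
                 noise_sd_acc = noise_sd_acc, noise_sd_gyr = noise_sd_gyr,
                 fs = fs, seed = as.integer(seed)),
            class = "tug_scenario")
}

#' @export
print.tug_scenario <- function(x, ...) {
  cat("TUG scenario\n")
  cat("  durations (s):",
      paste(sprintf("%s=%.2f", names(x$durations), x$durations),
            collapse = ", "), "\n")
  cat(sprintf("  turn: %g deg, %s direction; cadence %.2f steps/s\n",
              x$turn_angle, x$turn_direction, x$cadence))
  cat(sprintf("  pitch amplitudes %.2f / %.2f deg; noise sd %.2f deg, %.2f m/s^2\n",
              x$pitch_amp_stand, x$pitch_amp_sit,
              x$noise_sd_angle, x$noise_sd_acc))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# triangular bump on [0, 1]: sharp peak at the centre, linear flanks
tri_bump <- function(u) {
  v <- 1 - abs(2 * u - 1)
  v[u < 0 | u > 1] <- 0
  v
}

# cubic smoothstep on [0, 1]: zero slope at both knots
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  3 * u^2 - 2 * u^3
}

d_smoothstep <- function(u) {
  out <- 6 * u - 6 * u^2
  out[u < 0 | u > 1] <- 0
  out
}

#' Simulate a single-IMU TUG recording with exact ground truth
#'
#' Builds a 100-Hz recording whose morphology matches what the lumbar
#' sensor sees during a real trial: pitch = baseline + sharp-peaked
#' triangular inclination bumps spanning exactly the standing and sitting
#' intervals; yaw = baseline + smoothstep heading transitions spanning
#' exactly the turn intervals; vertical acceleration = gravity + one
#' sinusoidal oscillation per step during walks and turns + raised-cosine
#' transients at stand/sit; the gyroscope vertical channel is the
#' analytic derivative of the noiseless heading and the sagittal channel
#' the analytic derivative of the noiseless pitch. Gaussian white noise
#' is added per channel. All event knot times, step counts, peak rates
#' and amplitudes are returned as exact ground truth.
#'
#' @param scenario A [tug_scenario()].
#' @return A list with `recording` (an [imu_recording()]) and `truth`
#'   (a `tug_ground_truth`: named `boundaries` vector with standing_i/f,
#'   turn1_i/f, turn2_i/f, sitting_i/f; per-segment `steps`;
#'   `peak_turn_rate_1/2` in deg/s; amplitudes; `total_time`).
#' @export
simulate_tug <- function(scenario) {
  s <- scenario
  fs <- s$fs
  d <- s$durations
  a0 <- s$lead_in
  a1 <- a0 + d[["standing"]]
  a2 <- a1 + d[["first_walk"]]
  a3 <- a2 + d[["turn_3m"]]
  a4 <- a3 + d[["second_walk"]]
  a5 <- a4 + d[["presit_turn"]]
  a6 <- a5 + s$presit_gap
  a7 <- a6 + d[["sitting"]]
  total_dur <- a7 + s$lead_out
  t <- seq(0, total_dur, by = 1 / fs)
  n <- length(t)

  u_of <- function(lo, hi) (t - lo) / (hi - lo)

  pitch0 <- s$pitch_baseline +
    s$pitch_amp_stand * tri_bump(u_of(a0, a1)) +
    s$pitch_amp_sit * tri_bump(u_of(a6, a7))

  sgn2 <- if (s$turn_direction == "opposite") -1 else 1
  yaw0 <- s$yaw_baseline +
    s$turn_angle * smoothstep(u_of(a2, a3)) +
    sgn2 * s$turn_angle * smoothstep(u_of(a4, a5))

  # analytic rates of the noiseless orientation signals
  gyr_z0 <- s$turn_angle * d_smoothstep(u_of(a2, a3)) / (a3 - a2) +
    sgn2 * s$turn_angle * d_smoothstep(u_of(a4, a5)) / (a5 - a4)
  dtri <- function(lo, hi) {
    u <- u_of(lo, hi)
    out <- ifelse(u < 0.5, 2, -2) / (hi - lo)
    out[u < 0 | u > 1] <- 0
    out
  }
  gyr_y0 <- s$pitch_amp_stand * dtri(a0, a1) + s$pitch_amp_sit * dtri(a6, a7)

  seg_knots <- list(first_walk = c(a1, a2), turn_3m = c(a2, a3),
                    second_walk = c(a3, a4), presit_turn = c(a4, a5))
  steps <- vapply(seg_knots, function(k)
    max(1L, as.integer(round(s$cadence * (k[2] - k[1])))), integer(1))
  acc0 <- rep(9.81, n)
  for (nm in names(seg_knots)) {
    k <- seg_knots[[nm]]
    u <- u_of(k[1], k[2])
    inside <- u >= 0 & u <= 1
    acc0[inside] <- acc0[inside] +
      0.5 * s$step_acc_amp * (1 - cos(2 * pi * steps[[nm]] * u[inside]))
  }
  pulse <- function(lo, hi, amp) {
    # raised-cosine transient over the central 40% of the interval
    mid <- (lo + hi) / 2
    half <- 0.2 * (hi - lo)
    u <- (t - (mid - half)) / (2 * half)
    v <- amp * sin(pi * pmin(1, pmax(0, u)))^2
    v[u < 0 | u > 1] <- 0
    v
  }
  acc0 <- acc0 + pulse(a0, a1, s$acc_amp_stand) + pulse(a6, a7, s$acc_amp_sit)

  rec <- with_seed(s$seed, {
    nz <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
    # Orientation error of the onboard sensor-fusion filter is band
    # limited and slowly varying (attitude drift, magnetic disturbance),
    # not white at 100 Hz: modelled as a stationary AR(1) process with a
    # 2-s correlation time and SD noise_sd_angle. Inertial channels carry
    # genuine wideband noise and stay white.
    nz_angle <- function(sd) {
      if (sd <= 0) return(numeric(n))
      rho <- exp(-1 / (fs * 2))
      as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - rho^2)),
                               rho, method = "recursive",
                               init = stats::rnorm(1, 0, sd)))
    }
    imu_recording(
      t = t, fs = fs,
      pitch = pitch0 + nz_angle(s$noise_sd_angle),
      yaw = yaw0 + nz_angle(s$noise_sd_angle),
      roll = nz_angle(s$noise_sd_angle),
      acc_x = nz(s$noise_sd_acc),
      acc_y = nz(s$noise_sd_acc),
      acc_z = acc0 + nz(s$noise_sd_acc),
      gyr_x = nz(s$noise_sd_gyr),
      gyr_y = gyr_y0 + nz(s$noise_sd_gyr),
      gyr_z = gyr_z0 + nz(s$noise_sd_gyr),
      subject_meta = list(source = "simulated")
    )
  })
  boundaries <- c(standing_i = a0, standing_f = a1,
                  turn1_i = a2, turn1_f = a3,
                  turn2_i = a4, turn2_f = a5,
                  sitting_i = a6, sitting_f = a7)
  truth <- structure(list(
    boundaries = boundaries,
    steps = as.list(steps),
    peak_turn_rate_1 = 1.5 * s$turn_angle / (a3 - a2),
    peak_turn_rate_2 = 1.5 * s$turn_angle / (a5 - a4),
    pitch_amp_stand = s$pitch_amp_stand,
    pitch_amp_sit = s$pitch_amp_sit,
    acc_amp_stand = s$acc_amp_stand,
    acc_amp_sit = s$acc_amp_sit,
    total_time = a7 - a0
  ), class = "tug_ground_truth")
  list(recording = rec, truth = truth)
}

# population parameter tables for random scenarios: sub-task duration
# means/SDs from the video timings of each study group, amplitude and
# rate ranges from the per-group feature tables; truncation at +/-2 SD
# keeps draws physiologic.
scenario_population <- list(
  young = list(
    dur_mean = c(standing = 1.16, first_walk = 2.51, turn_3m = 1.65,
                 second_walk = 2.39, presit_turn = 1.03, sitting = 1.48),
    dur_sd = c(standing = 0.15, first_walk = 0.35, turn_3m = 0.25,
               second_walk = 0.36, presit_turn = 0.14, sitting = 0.17),
    pitch_su = c(5.35, 1.89, 2.30, 9.00),
    pitch_sd = c(6.25, 1.82, 3.24, 9.99),
    acc_su = c(6.49, 1.42, 3.91, 9.15),
    acc_sd = c(6.09, 0.87, 4.46, 7.50),
    cadence = c(1.75, 0.25, 1.20, 2.50)
  ),
  older = list(
    dur_mean = c(standing = 1.41, first_walk = 3.49, turn_3m = 2.23,
                 second_walk = 3.75, presit_turn = 1.32, sitting = 1.65),
    dur_sd = c(standing = 0.71, first_walk = 3.26, turn_3m = 1.82,
               second_walk = 3.75, presit_turn = 0.14, sitting = 0.56),
    pitch_su = c(7.48, 2.81, 2.82, 11.06),
    pitch_sd = c(8.68, 4.59, 1.33, 15.71),
    acc_su = c(7.20, 1.63, 3.89, 9.52),
    acc_sd = c(7.08, 2.18, 3.15, 10.16),
    cadence = c(2.00, 0.40, 1.30, 3.00)
  )
)

#' Draw a random population-typical TUG scenario
#'
#' Sub-task durations are drawn from truncated normal distributions with
#' the study groups' video-timing means and SDs; inclination and
#' acceleration amplitudes from the per-group feature distributions,
#' truncated to the observed ranges. Reproducible per seed; the caller's
#' RNG state is untouched.
#'
#' @param seed Integer seed.
#' @param population `"young"` or `"older"`.
#' @return A [tug_scenario()].
#' @export
random_scenario <- function(seed, population = c("young", "older")) {
  population <- match.arg(population)
  p <- scenario_population[[population]]
  with_seed(seed, {
    dur <- mapply(function(m, s) {
      rtruncnorm1(1, m, s, lower = max(0.4, m - 2 * s), upper = m + 2 * s)
    }, p$dur_mean, p$dur_sd)
    names(dur) <- names(p$dur_mean)
    draw <- function(v) rtruncnorm1(1, v[1], v[2], v[3], v[4])
    tug_scenario(
      durations = dur,
      pitch_amp_stand = draw(p$pitch_su),
      pitch_amp_sit = draw(p$pitch_sd),
      acc_amp_stand = draw(p$acc_su),
      acc_amp_sit = draw(p$acc_sd),
      cadence = draw(p$cadence),
      turn_angle = rtruncnorm1(1, 180, 8, 160, 200),
      pitch_baseline = stats::runif(1, -10, 10),
      yaw_baseline = stats::runif(1, -180, 180),
      seed = sample.int(.Machine$integer.max - 1L, 1)
    )
  })
}

#' Write a simulated recording to CSV
#'
#' Emits a delimited file with the same schema [read_recording()] ingests,
#' plus optionally the ground truth as JSON.
#'
#' @param sim Output of [simulate_tug()].
#' @param path CSV output path.
#' @param truth_path Optional JSON path for the ground truth.
#' @return Invisibly, `path`.
#' @export
write_simulated_csv <- function(sim, path, truth_path = NULL) {
  rec <- sim$recording
  df <- data.frame(time = rec$t, pitch = rec$pitch, yaw = rec$yaw,
                   roll = rec$roll,
                   acc_x = rec$acc_x, acc_y = rec$acc_y, acc_z = rec$acc_z,
                   gyr_x = rec$gyr_x, gyr_y = rec$gyr_y, gyr_z = rec$gyr_z)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth_path)) {
    jsonlite::write_json(unclass(sim$truth), truth_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
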