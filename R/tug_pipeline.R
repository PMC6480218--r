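#' Assemble the six sub-task intervals from the four detected events
#'
#' The walks fill the space between the posture transitions and the turns:
#' first walk = [standing end, turn1 start], second walk = [turn1 end,
#' turn2 start]. Any interval between the pre-sitting turn's end and the
#' sitting start is kept as an explicit labelled gap ("pre-sit stance")
#' rather than forced to zero. Total test time runs from the standing
#' start to the sitting end. Boundary inversions up to `tolerance`
#' seconds are resolved at the midpoint with a flag; larger ones raise a
#' consistency error.
#'
#' @param standing,sitting `transition_event`s from [detect_stand_sit()].
#' @param turn1,turn2 `turn_event`s from [detect_turns()].
#' @param tolerance Maximum boundary overlap (seconds) resolved by
#'   midpoint snapping. Default 0.2.
#' @return A `tug_segmentation`: six ordered intervals, the pre-sit
#'   stance gap, `total_time` and accumulated flags.
#' @export
assemble_segments <- function(standing, sitting, turn1, turn2,
                              tolerance = 0.2) {
  flags <- c(standing$flags, sitting$flags, turn1$flags, turn2$flags)
  b <- c(standing$t_start, standing$t_end,
         turn1$t_start, turn1$t_end,
         turn2$t_start, turn2$t_end,
         sitting$t_start, sitting$t_end)
  names(b) <- c("standing_i", "standing_f", "turn1_i", "turn1_f",
                "turn2_i", "turn2_f", "sitting_i", "sitting_f")
  for (k in 2:8) {
    if (b[k] < b[k - 1]) {
      overlap <- b[k - 1] - b[k]
      if (overlap > tolerance)
        stop_tugseg(sprintf(
          "event ordering violated: %s (%.3f s) precedes %s (%.3f s) by %.3f s",
          names(b)[k], b[k], names(b)[k - 1], b[k - 1], overlap),
          "consistency_error")
      mid <- (b[k] + b[k - 1]) / 2
      flags <- c(flags, sprintf("boundary_%s_%s_snapped_midpoint",
                                names(b)[k - 1], names(b)[k]))
      b[k - 1] <- mid
      b[k] <- mid
    }
  }
  intervals <- list(
    standing    = c(b[["standing_i"]], b[["standing_f"]]),
    first_walk  = c(b[["standing_f"]], b[["turn1_i"]]),
    turn_3m     = c(b[["turn1_i"]], b[["turn1_f"]]),
    second_walk = c(b[["turn1_f"]], b[["turn2_i"]]),
    presit_turn = c(b[["turn2_i"]], b[["turn2_f"]]),
    sitting     = c(b[["sitting_i"]], b[["sitting_f"]])
  )
  gap <- b[["sitting_i"]] - b[["turn2_f"]]
  total <- b[["sitting_f"]] - b[["standing_i"]]
  if (total <= 0)
    stop_tugseg("non-positive total test time", "consistency_error")
  structure(list(intervals = intervals,
                 gap = gap,
                 gap_interval = c(b[["turn2_f"]], b[["sitting_i"]]),
                 boundaries = b,
                 total_time = total,
                 flags = unique(flags)),
            class = "tug_segmentation")
}

#' @export
print.tug_segmentation <- function(x, ...) {
  cat("TUG segmentation\n")
  for (nm in names(x$intervals)) {
    iv <- x$intervals[[nm]]
    cat(sprintf("  %-12s [%6.2f, %6.2f] s  (%.2f s)\n",
                nm, iv[1], iv[2], iv[2] - iv[1]))
  }
  if (x$gap > 0)
    cat(sprintf("  %-12s %.2f s\n", "pre-sit gap", x$gap))
  cat(sprintf("  total time   %.2f s\n", x$total_time))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Count steps in a vertical-acceleration segment
#'
#' Simple local peak detection on the median-detrended vertical
#' acceleration: local maxima with at least `step_min_prominence` m/s^2
#' prominence separated by at least `step_min_distance` seconds.
#'
#' @param acc_z Vertical acceleration segment (m/s^2).
#' @param fs Sampling rate in Hz.
#' @param config An [algorithm_config()].
#' @return Integer step count (0 for empty/short segments).
#' @export
count_steps <- function(acc_z, fs, config = algorithm_config()) {
  if (length(acc_z) < 3L) return(0L)
  x <- acc_z - stats::median(acc_z)
  pk <- find_peaks(x, min_prominence = config$step_min_prominence,
                   min_distance = round(config$step_min_distance * fs))
  nrow(pk)
}

#' Extract per-sub-task mobility features
#'
#' Computes, per segmented sub-task: durations; peak detrended vertical
#' acceleration during standing and sitting (`acc_su`, `acc_sd`); peak
#' transverse rotation rate during each turn (`vel_t1`, `vel_t2`; from the
#' gyroscope vertical channel when present, else the differentiated
#' unwrapped yaw, flagged); step counts during the walks and turns; and
#' trunk-inclination excursion from the recording baseline during standing
#' and sitting (`pitch_su`, `pitch_sd`, degrees). Features whose source
#' channel is absent are `NA`, never zero.
#'
#' @param recording An [imu_recording()].
#' @param seg A `tug_segmentation` over the recording.
#' @param config An [algorithm_config()].
#' @return A `subtask_features` list.
#' @export
extract_features <- function(recording, seg, config = algorithm_config()) {
  t <- recording$t
  fs <- recording$fs
  idx <- function(nm) {
    iv <- seg$intervals[[nm]]
    which(t >= iv[1] & t <= iv[2])
  }
  durations <- vapply(seg$intervals, function(iv) iv[2] - iv[1], numeric(1))
  flags <- character(0)

  peak_detrended <- function(i) {
    a <- recording$acc_z[i]
    max(abs(a - stats::median(a)))
  }
  if (!is.null(recording$acc_z)) {
    acc_su <- peak_detrended(idx("standing"))
    acc_sd <- peak_detrended(idx("sitting"))
    steps <- vapply(c("first_walk", "second_walk", "turn_3m", "presit_turn"),
                    function(nm) count_steps(recording$acc_z[idx(nm)], fs, config),
                    integer(1))
  } else {
    acc_su <- acc_sd <- NA_real_
    steps <- rep(NA_integer_, 4)
    names(steps) <- c("first_walk", "second_walk", "turn_3m", "presit_turn")
    flags <- c(flags, "acc_z_absent")
  }

  if (!is.null(recording$gyr_z)) {
    turn_rate <- abs(recording$gyr_z)
  } else {
    u <- unwrap_heading(recording$yaw)
    n <- length(u)
    r <- numeric(n)
    r[1] <- (u[2] - u[1]) * fs
    r[n] <- (u[n] - u[n - 1]) * fs
    if (n > 2L) r[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) * fs / 2
    turn_rate <- abs(r)
    flags <- c(flags, "turn_rate_derived_from_yaw")
  }
  vel_t1 <- max(turn_rate[idx("turn_3m")])
  vel_t2 <- max(turn_rate[idx("presit_turn")])

  pbase_n <- max(1L, round(config$baseline_window * fs))
  pbase <- stats::median(recording$pitch[seq_len(pbase_n)])
  pitch_su <- max(abs(recording$pitch[idx("standing")] - pbase))
  pitch_sd <- max(abs(recording$pitch[idx("sitting")] - pbase))

  structure(list(durations = as.list(durations),
                 acc_su = acc_su, acc_sd = acc_sd,
                 vel_t1 = vel_t1, vel_t2 = vel_t2,
                 steps_w1 = steps[["first_walk"]],
                 steps_w2 = steps[["second_walk"]],
                 steps_t1 = steps[["turn_3m"]],
                 steps_t2 = steps[["presit_turn"]],
                 pitch_su = pitch_su, pitch_sd = pitch_sd,
                 flags = flags),
            class = "subtask_features")
}

#' Classify fall risk from total test time
#'
#' A step function of the total time against two configurable cutoffs:
#' below the first is "no" risk, between the cutoffs (inclusive) "low",
#' above the second "high". Defaults 10 s and 20 s.
#'
#' @param total_time Total test time in seconds (> 0).
#' @param thresholds Two strictly increasing cutoffs in seconds.
#' @return A `risk_assessment` with `category`, `total_time` and
#'   `thresholds_used`.
#' @export
classify_risk <- function(total_time, thresholds = c(10, 20)) {
  if (length(thresholds) != 2L || diff(thresholds) <= 0)
    stop_tugseg("thresholds must be two strictly increasing values",
                "config_error")
  if (!is.finite(total_time) || total_time <= 0)
    stop_tugseg("total_time must be positive", "value_error")
  category <- if (total_time < thresholds[1]) "no"
  else if (total_time <= thresholds[2]) "low"
  else "high"
  structure(list(category = category, total_time = total_time,
                 thresholds_used = thresholds),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("Fall risk: %s (total time %.2f s; cutoffs %g / %g s)\n",
              x$category, x$total_time,
              x$thresholds_used[1], x$thresholds_used[2]))
  invisible(x)
}

#' Run the full TUG analysis pipeline
#'
#' Conditioning -> posture-transition detection -> turn detection ->
#' segment assembly -> feature extraction -> risk classification.
#' Deterministic for a fixed recording and configuration. Errors from any
#' stage are re-raised with the stage name prefixed.
#'
#' @param recording An [imu_recording()].
#' @param config An [algorithm_config()].
#' @return A list with `segmentation`, `features`, `risk`, and the
#'   conditioned `pitch` and `yaw` signals.
#' @export
run_pipeline <- function(recording, config = algorithm_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, tugseg_error = function(e) {
      stop(errorCondition(sprintf("[%s] %s", name, conditionMessage(e)),
                          class = class(e)))
    })
  }
  pitch_c <- stage("preprocessing", condition_pitch(recording, config))
  yaw_c <- stage("preprocessing", condition_yaw(recording, config))
  ss <- stage("posture_transitions", detect_stand_sit(pitch_c, config))
  tt <- stage("turn_detector", detect_turns(yaw_c, config))
  seg <- stage("tug_pipeline",
               assemble_segments(ss$standing, ss$sitting, tt$turn1, tt$turn2))
  feats <- stage("tug_pipeline", extract_features(recording, seg, config))
  risk <- stage("tug_pipeline",
                classify_risk(seg$total_time, config$risk_thresholds))
  list(segmentation = seg, features = feats, risk = risk,
       pitch = pitch_c, yaw = yaw_c)
}
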