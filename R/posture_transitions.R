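#' Locate the stand and sit inclination peaks
#'
#' Finds the two most prominent local maxima of the conditioned pitch
#' signal separated by at least `min_separation` seconds. Prominence (not
#' raw height) ranks candidates so gait oscillations are rejected; the
#' earlier peak is the stand-up peak, the later the sit-down peak.
#'
#' @param pitch_norm A `conditioned_signal` from [condition_pitch()].
#' @param min_separation Minimum peak separation in seconds.
#' @return A list with `t_peak1`, `t_peak2` (seconds) and `value1`,
#'   `value2` (normalised peak heights).
#' @export
find_posture_peaks <- function(pitch_norm, min_separation = 3.0) {
  x <- pitch_norm$values
  fs <- pitch_norm$fs
  if (length(x) <= 2 * min_separation * fs)
    stop_tugseg("signal too short for two separated posture peaks",
                "detection_error")
  pk <- find_peaks(x, min_prominence = 0.1,
                   min_distance = round(min_separation * fs))
  if (nrow(pk) < 2L)
    stop_tugseg("posture peaks not found", "detection_error")
  top <- pk[order(pk$prominence, decreasing = TRUE)[1:2], ]
  top <- top[order(top$index), ]
  list(t_peak1 = pitch_norm$t[top$index[1]],
       t_peak2 = pitch_norm$t[top$index[2]],
       value1 = top$value[1], value2 = top$value[2])
}

#' Slope-stop search for a posture-transition's bounds
#'
#' Walks outward from an inclination peak in strides of `stride` seconds
#' and stops on each side the first time the lagged difference
#' `|x(t -/+ i -/+ stride) - x(t -/+ i)|` falls below `threshold`; the
#' stopping iterate gives the bound. A search that reaches the recording
#' edge before the criterion fires is clamped there with a flag. Shallow
#' transitions whose lagged difference never exceeds the threshold
#' collapse onto the peak (the bound fires at i = 0).
#'
#' @param pitch_norm A `conditioned_signal`.
#' @param t_peak Peak time in seconds (from [find_posture_peaks()]).
#' @param threshold Slope-stop threshold in normalised units.
#' @param stride Search stride in seconds.
#' @return A list with `t_start`, `t_end` (seconds, snapped to samples)
#'   and logical flags `clamped_left`, `clamped_right`.
#' @export
slope_search_bounds <- function(pitch_norm, t_peak,
                                threshold = 0.05, stride = 0.1) {
  x <- pitch_norm$values
  t <- pitch_norm$t
  n <- length(x)
  fs <- pitch_norm$fs
  step <- max(1L, round(stride * fs))
  ip <- time_to_index(t_peak, t)
  if (ip < 1L || ip > n)
    stop_tugseg("peak time outside the recording", "value_error")

  walk <- function(dir) {
    i <- 0L
    clamped <- FALSE
    repeat {
      b <- ip + dir * i
      a <- b + dir * step
      if (a < 1L || a > n) {
        b <- if (dir < 0) 1L else n
        clamped <- TRUE
        break
      }
      if (abs(x[a] - x[b]) < threshold) break
      i <- i + step
    }
    list(idx = b, clamped = clamped)
  }
  left <- walk(-1L)
  right <- walk(1L)
  list(t_start = t[left$idx], t_end = t[right$idx],
       clamped_left = left$clamped, clamped_right = right$clamped)
}

new_transition_event <- function(kind, t_start, t_peak, t_end, peak_value,
                                 flags = character(0)) {
  if (t_start > t_peak || t_peak > t_end)
    stop_tugseg(sprintf("%s event bounds out of order", kind),
                "consistency_error")
  if (t_start == t_peak || t_end == t_peak)
    flags <- c(flags, paste0(kind, "_degenerate_bound"))
  structure(list(kind = kind, t_start = t_start, t_peak = t_peak,
                 t_end = t_end, peak_value = peak_value, flags = flags),
            class = "transition_event")
}

#' @export
print.transition_event <- function(x, ...) {
  cat(sprintf("%s event: [%.2f, %.2f] s, peak %.2f at %.2f s\n",
              x$kind, x$t_start, x$t_end, x$peak_value, x$t_peak))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Detect the stand-up and sit-down events from conditioned pitch
#'
#' Composes [find_posture_peaks()] with [slope_search_bounds()] at each
#' peak: the earlier peak with its bounds is the standing event, the later
#' one the sitting event.
#'
#' @param pitch_norm A `conditioned_signal` from [condition_pitch()].
#' @param config An [algorithm_config()].
#' @return A list with `standing` and `sitting`, both `transition_event`s.
#' @export
detect_stand_sit <- function(pitch_norm, config = algorithm_config()) {
  pks <- find_posture_peaks(pitch_norm, config$peak_min_separation)
  mk <- function(kind, t_peak, val) {
    b <- slope_search_bounds(pitch_norm, t_peak,
                             threshold = config$slope_stop_threshold,
                             stride = config$slope_stride)
    flags <- character(0)
    if (b$clamped_left) flags <- c(flags, paste0(kind, "_clamped_left"))
    if (b$clamped_right) flags <- c(flags, paste0(kind, "_clamped_right"))
    new_transition_event(kind, b$t_start, t_peak, b$t_end, val, flags)
  }
  standing <- mk("standing", pks$t_peak1, pks$value1)
  sitting <- mk("sitting", pks$t_peak2, pks$value2)
  if (standing$t_end > sitting$t_start)
    stop_tugseg("standing and sitting events overlap", "consistency_error")
  list(standing = standing, sitting = sitting)
}
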