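#' Forward moving-average smoother
#'
#' Order-N causal-forward average: `y[n] = mean(x[n], ..., x[n + N - 1])`.
#' The final `N - 1` samples, where the forward window would run off the
#' signal, use the shrinking tail window `mean(x[n], ..., x[end])` so the
#' output has the same length as the input and event indices map 1:1 onto
#' raw samples.
#'
#' @param x Numeric signal.
#' @param N Window length in samples (default 5).
#' @return Smoothed signal, same length as `x`.
#' @export
moving_average <- function(x, N = 5L) {
  N <- as.integer(N)
  if (N < 1L) stop_tugseg("N must be >= 1", "value_error")
  n <- length(x)
  if (n < N) stop_tugseg("signal shorter than filter order", "value_error")
  cs <- c(0, cumsum(x))
  y <- numeric(n)
  full <- seq_len(n - N + 1L)
  y[full] <- (cs[full + N] - cs[full]) / N
  if (N > 1L) {
    tail_idx <- (n - N + 2L):n
    y[tail_idx] <- (cs[n + 1L] - cs[tail_idx]) / (n - tail_idx + 1L)
  }
  y
}

#' Normalise a signal by its absolute maximum
#'
#' Divides the signal by `max(abs(x))` so the extreme sample attains
#' exactly +/-1. An identically zero signal is returned unchanged with
#' `scale = 0` and the degenerate flag set.
#'
#' @param x Numeric signal.
#' @return A list with `values` (normalised signal), `scale` (the absolute
#'   maximum, in the signal's units) and `degenerate` (logical).
#' @export
normalize_abs_max <- function(x) {
  if (!length(x)) stop_tugseg("empty signal", "value_error")
  s <- max(abs(x))
  if (s == 0) {
    return(list(values = x, scale = 0, degenerate = TRUE))
  }
  list(values = x / s, scale = s, degenerate = FALSE)
}

#' Unwrap a wrapped heading signal
#'
#' Headings from the sensor wrap at +/-180 degrees while the turn-bound
#' criteria assume a continuous signal, so 360-degree multiples are added
#' or subtracted wherever a successive difference exceeds 180 degrees in
#' magnitude. Valid when the true per-sample rotation is well below 180
#' degrees, which holds at 100 Hz for human movement.
#'
#' @param yaw Heading in degrees.
#' @return Unwrapped heading in degrees; idempotent.
#' @export
unwrap_heading <- function(yaw) {
  if (length(yaw) < 2L) return(yaw)
  d <- diff(yaw)
  d <- ((d + 180) %% 360) - 180
  c(yaw[1], yaw[1] + cumsum(d))
}

#' Zero-reference a signal against its initial baseline
#'
#' Subtracts the median of the first `baseline_window` seconds, so a
#' constant mounting offset (e.g. a 15-degree resting pitch) does not
#' dominate the later absolute-maximum normalisation.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param baseline_window Seconds of initial signal used for the median.
#' @return `x` minus the baseline, with the baseline (in the signal's
#'   units) attached as attribute `"baseline"`.
#' @export
zero_reference <- function(x, fs, baseline_window = 0.5) {
  n0 <- max(1L, min(length(x), round(baseline_window * fs)))
  b <- stats::median(x[seq_len(n0)])
  out <- x - b
  attr(out, "baseline") <- b
  out
}

#' Orient a heading signal so the first turn is a positive rotation
#'
#' The turn detector assumes the first turn produces the global maximum of
#' the heading derivative, i.e. a positive rotation; subjects may turn
#' either way. If the extremum of largest magnitude in the zero-referenced
#' heading is negative the whole signal is mirrored.
#'
#' @param x Zero-referenced heading signal (degrees or normalised).
#' @return `x`, possibly negated, with attribute `"direction"` set to
#'   `"positive"` or `"negative"` (the original rotation sense); idempotent.
#' @export
orient_turn_sign <- function(x) {
  ext <- x[which.max(abs(x))]
  if (length(ext) && ext < 0) {
    out <- -x
    attr(out, "direction") <- "negative"
  } else {
    out <- x
    attr(out, "direction") <- "positive"
  }
  attr(out, "baseline") <- attr(x, "baseline")
  out
}

new_conditioned_signal <- function(values, t, fs, scale, baseline,
                                   degenerate = FALSE, direction = NULL,
                                   unwrapped = NULL) {
  structure(list(values = values, t = t, fs = fs, scale = scale,
                 baseline = baseline, degenerate = degenerate,
                 direction = direction, unwrapped = unwrapped),
            class = "conditioned_signal")
}

#' Condition the pitch signal for posture-transition detection
#'
#' Pipeline: zero-reference -> forward moving average (order N) ->
#' absolute-maximum normalisation. The stand and sit inclination bumps
#' then appear as local maxima near +/-1.
#'
#' @param recording An [imu_recording()].
#' @param config An [algorithm_config()].
#' @return A `conditioned_signal` with normalised values in [-1, 1], the
#'   normalisation `scale` (degrees) and the subtracted `baseline`.
#' @export
condition_pitch <- function(recording, config = algorithm_config()) {
  p <- recording$pitch
  if (config$invert_pitch) p <- -p
  z <- zero_reference(p, recording$fs, config$baseline_window)
  s <- moving_average(as.numeric(z), config$smooth_order_N)
  nrm <- normalize_abs_max(s)
  new_conditioned_signal(nrm$values, recording$t, recording$fs,
                         scale = nrm$scale,
                         baseline = attr(z, "baseline"),
                         degenerate = nrm$degenerate)
}

#' Condition the yaw signal for turn detection
#'
#' Pipeline (order matters; each step assumes the previous one's
#' contract): unwrap -> zero-reference -> orient so the first turn is a
#' positive rotation -> forward moving average -> absolute-maximum
#' normalisation. The unwrapped, oriented (but unsmoothed, degree-valued)
#' signal is retained for rotation-span measurements.
#'
#' @inheritParams condition_pitch
#' @return A `conditioned_signal`; `direction` records the subject's
#'   original first-turn rotation sense and `unwrapped` the oriented
#'   heading in degrees.
#' @export
condition_yaw <- function(recording, config = algorithm_config()) {
  y <- recording$yaw
  if (config$invert_yaw) y <- -y
  u <- unwrap_heading(y)
  z <- zero_reference(u, recording$fs, config$baseline_window)
  o <- orient_turn_sign(z)
  s <- moving_average(as.numeric(o), config$smooth_order_N)
  nrm <- normalize_abs_max(s)
  new_conditioned_signal(nrm$values, recording$t, recording$fs,
                         scale = nrm$scale,
                         baseline = attr(z, "baseline"),
                         degenerate = nrm$degenerate,
                         direction = attr(o, "direction"),
                         unwrapped = as.numeric(o))
}

#' @export
print.conditioned_signal <- function(x, ...) {
  cat(sprintf(
    "Conditioned signal: %d samples at %g Hz, scale %.3f deg, baseline %.3f deg\n",
    length(x$values), x$fs, x$scale, x$baseline))
  if (!is.null(x$direction)) cat("  first-turn direction:", x$direction, "\n")
  if (x$degenerate) cat("  [degenerate: identically zero]\n")
  invisible(x)
}
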