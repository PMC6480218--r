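#' Differentiate the conditioned yaw signal
#'
#' Central first difference scaled by the sampling rate (one-sided at the
#' edges); units are normalised units per second.
#'
#' @param yaw_norm A `conditioned_signal` from [condition_yaw()].
#' @return Numeric rate signal, same length as the input.
#' @export
yaw_rate <- function(yaw_norm) {
  v <- yaw_norm$values
  fs <- yaw_norm$fs
  n <- length(v)
  if (n < 2L) stop_tugseg("signal too short to differentiate", "value_error")
  r <- numeric(n)
  r[1] <- (v[2] - v[1]) * fs
  r[n] <- (v[n] - v[n - 1]) * fs
  if (n > 2L) r[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * fs / 2
  r
}

#' Locate the derivative extrema marking the two turns
#'
#' On the oriented signal the 3-m turn is the rising transition (global
#' maximum of the rate) and the pre-sitting turn the falling one (global
#' minimum); the maximum must precede the minimum.
#'
#' @param rate Rate signal from [yaw_rate()].
#' @param t Time stamps matching `rate`.
#' @return A list with `t_max` and `t_min` (seconds).
#' @export
locate_turn_extrema <- function(rate, t) {
  i_max <- which.max(rate)
  i_min <- which.min(rate)
  if (i_max >= i_min)
    stop_tugseg("turn order violated: rate maximum does not precede minimum",
                "detection_error")
  list(t_max = t[i_max], t_min = t[i_min])
}

#' Sliding-window search for a turn's bounds
#'
#' From the turn's rate extremum, slides a `turn_window`-sample window
#' outward one sample per step. For the 3-m turn the leftward search runs
#' while the window mean exceeds `turn_low_level` (stopping on the
#' pre-turn plateau; the bound is the final window's left edge) and the
#' rightward search runs while the mean is below `turn_high_level`
#' (stopping on the post-turn plateau; the bound is the final window's
#' right edge). For the pre-sitting turn the level criteria are mirrored.
#' Searches reaching the recording edge are clamped with a flag.
#'
#' @param yaw_norm A `conditioned_signal`, or a plain list with `values`,
#'   `t` and `fs` (the robust detector passes locally rescaled copies).
#' @param t_extremum Rate-extremum time (seconds).
#' @param which `"turn1_3m"` or `"turn2_presit"`.
#' @param config An [algorithm_config()].
#' @return A list with `t_start`, `t_end` and clamp flags.
#' @export
window_search_turn_bounds <- function(yaw_norm, t_extremum,
                                      which = c("turn1_3m", "turn2_presit"),
                                      config = algorithm_config()) {
  which <- match.arg(which)
  x <- yaw_norm$values
  t <- yaw_norm$t
  n <- length(x)
  W <- config$turn_window
  ie <- time_to_index(t_extremum, t)
  low <- config$turn_low_level
  high <- config$turn_high_level

  # keep_going(mean) is TRUE while the window is still inside the turn
  left_keep <- if (which == "turn1_3m") function(m) m > low else function(m) m < high
  right_keep <- if (which == "turn1_3m") function(m) m < high else function(m) m > low

  slide <- function(dir, keep) {
    i <- 0L
    clamped <- FALSE
    repeat {
      if (dir < 0) { a <- ie - W - i; b <- ie - i } else { a <- ie + i; b <- ie + W + i }
      if (a < 1L || b > n) {
        edge <- if (dir < 0) 1L else n
        return(list(idx = edge, clamped = TRUE))
      }
      if (!keep(mean(x[a:b]))) {
        return(list(idx = if (dir < 0) a else b, clamped = FALSE))
      }
      i <- i + 1L
    }
  }
  left <- slide(-1L, left_keep)
  right <- slide(1L, right_keep)
  list(t_start = t[left$idx], t_end = t[right$idx],
       clamped_left = left$clamped, clamped_right = right$clamped)
}

new_turn_event <- function(which, t_start, t_end, t_extremum, rotation_span,
                           flags = character(0)) {
  if (t_start > t_extremum || t_extremum > t_end)
    stop_tugseg(sprintf("%s bounds out of order", which), "consistency_error")
  if (is.finite(rotation_span) &&
      (rotation_span <= 90 || rotation_span >= 270))
    flags <- c(flags, paste0(which, "_rotation_span_outside_90_270"))
  structure(list(which = which, t_start = t_start, t_end = t_end,
                 t_extremum = t_extremum, rotation_span = rotation_span,
                 flags = flags),
            class = "turn_event")
}

#' @export
print.turn_event <- function(x, ...) {
  cat(sprintf("%s: [%.2f, %.2f] s, extremum at %.2f s, span %.1f deg\n",
              x$which, x$t_start, x$t_end, x$t_extremum, x$rotation_span))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

rotation_span_deg <- function(yaw_norm, t_start, t_end) {
  u <- yaw_norm$unwrapped
  if (is.null(u)) return(NA_real_)
  abs(u[time_to_index(t_end, yaw_norm$t)] -
        u[time_to_index(t_start, yaw_norm$t)])
}

#' Detect the 3-m and pre-sitting turns from conditioned yaw
#'
#' Literal mode (default) composes [yaw_rate()], [locate_turn_extrema()]
#' and [window_search_turn_bounds()] for each turn; it assumes the two
#' turns rotate in opposite directions so the rate extrema have opposite
#' signs. With `config$robust_turns = TRUE` the detector instead takes the
#' two largest-magnitude disjoint rate excursions (of either sign) and
#' rescales the window level criteria to each turn's flanking plateaus,
#' which also handles same-direction turners and incomplete turns.
#'
#' A rotation span outside (90, 270) degrees sets a warning flag on the
#' event rather than failing: turns are only approximately 180 degrees.
#'
#' @param yaw_norm A `conditioned_signal` from [condition_yaw()].
#' @param config An [algorithm_config()].
#' @return A list with `turn1` and `turn2`, both `turn_event`s.
#' @export
detect_turns <- function(yaw_norm, config = algorithm_config()) {
  if (config$robust_turns) return(detect_turns_robust(yaw_norm, config))
  rate <- yaw_rate(yaw_norm)
  ext <- locate_turn_extrema(rate, yaw_norm$t)
  mk <- function(which, t_ext) {
    b <- window_search_turn_bounds(yaw_norm, t_ext, which, config)
    flags <- character(0)
    if (b$clamped_left) flags <- c(flags, paste0(which, "_clamped_left"))
    if (b$clamped_right) flags <- c(flags, paste0(which, "_clamped_right"))
    new_turn_event(which, b$t_start, b$t_end, t_ext,
                   rotation_span_deg(yaw_norm, b$t_start, b$t_end), flags)
  }
  turn1 <- mk("turn1_3m", ext$t_max)
  turn2 <- mk("turn2_presit", ext$t_min)
  if (turn1$t_end > turn2$t_start)
    stop_tugseg("turns overlap: turn1 ends after turn2 starts",
                "consistency_error")
  list(turn1 = turn1, turn2 = turn2)
}

# Robust mode: find the two dominant |rate| excursions, estimate each
# turn's flanking plateau levels, locally rescale the transition to a
# 0 -> 1 ascent and reuse the turn1-style window criteria.
detect_turns_robust <- function(yaw_norm, config) {
  rate <- yaw_rate(yaw_norm)
  t <- yaw_norm$t
  fs <- yaw_norm$fs
  pk <- find_peaks(abs(rate), min_prominence = 0.05 * max(abs(rate)),
                   min_distance = round(1.5 * fs))
  if (nrow(pk) < 2L)
    stop_tugseg("fewer than two turn-rate excursions found",
                "detection_error")
  top <- pk[order(pk$prominence, decreasing = TRUE)[1:2], ]
  top <- top[order(top$index), ]

  plateau_levels <- function(ie) {
    thresh <- 0.05 * abs(rate[ie])
    quiet <- round(0.2 * fs)
    span <- round(0.3 * fs)
    scan <- function(dir) {
      j <- ie
      run <- 0L
      n <- length(rate)
      while (j > 1L && j < n) {
        j <- j + dir
        run <- if (abs(rate[j]) < thresh) run + 1L else 0L
        if (run >= quiet) break
      }
      idx <- if (dir < 0) max(1L, j - span):j else j:min(n, j + span)
      stats::median(yaw_norm$values[idx])
    }
    c(left = scan(-1L), right = scan(1L))
  }

  mk <- function(which, ie) {
    lv <- plateau_levels(ie)
    span <- lv["right"] - lv["left"]
    if (abs(span) < 1e-9)
      stop_tugseg("flat plateaus around turn-rate excursion",
                  "detection_error")
    local <- list(values = (yaw_norm$values - lv["left"]) / span,
                  t = t, fs = fs)
    b <- window_search_turn_bounds(local, t[ie], "turn1_3m", config)
    flags <- paste0(which, "_robust_mode")
    if (b$clamped_left) flags <- c(flags, paste0(which, "_clamped_left"))
    if (b$clamped_right) flags <- c(flags, paste0(which, "_clamped_right"))
    new_turn_event(which, b$t_start, b$t_end, t[ie],
                   rotation_span_deg(yaw_norm, b$t_start, b$t_end), flags)
  }
  turn1 <- mk("turn1_3m", top$index[1])
  turn2 <- mk("turn2_presit", top$index[2])
  if (turn1$t_end > turn2$t_start)
    stop_tugseg("turns overlap: turn1 ends after turn2 starts",
                "consistency_error")
  list(turn1 = turn1, turn2 = turn2)
}
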