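#' Algorithm configuration for TUG segmentation
#'
#' Collects every tunable of the segmentation pipeline in one validated
#' object. The defaults are the operating point of the feature-based
#' algorithm: an order-5 moving-average smoother, a 0.05 normalised-units
#' slope-stop threshold stepped in 0.1-s strides for the stand/sit bound
#' search, and a 10-sample sliding window with 0.02 / 0.9 level criteria
#' for the turn bound search, all defined at a 100-Hz sampling rate.
#'
#' @param smooth_order_N Order (samples) of the forward moving-average
#'   smoother applied to pitch and yaw. Default 5.
#' @param slope_stop_threshold Normalised-units threshold below which the
#'   lagged difference of smoothed pitch is considered flat, stopping the
#'   outward bound search around an inclination peak. Default 0.05.
#' @param slope_stride Stride (seconds) of the slope-stop search iterator;
#'   differences are taken between samples this far apart. Default 0.1.
#' @param turn_window Sliding-window length in samples for the turn bound
#'   search. Default 10 (0.1 s at 100 Hz).
#' @param turn_low_level,turn_high_level Window-mean levels (normalised
#'   units) bounding a turn: the search leaves a turn when the window mean
#'   drops below `turn_low_level` on the pre-turn plateau and when it rises
#'   above `turn_high_level` on the post-turn plateau. Defaults 0.02 / 0.9.
#' @param baseline_window Seconds of signal from the start of the recording
#'   whose median is used as the zero reference. Default 0.5.
#' @param peak_min_separation Minimum separation (seconds) between the
#'   stand and sit inclination peaks. Default 3.
#' @param step_min_prominence Minimum peak prominence (m/s^2) of the
#'   detrended vertical acceleration for a local maximum to count as a
#'   step. Default 1.
#' @param step_min_distance Minimum separation (seconds) between step
#'   peaks. Default 0.3.
#' @param risk_thresholds Two strictly increasing total-time cutoffs
#'   (seconds): below the first is no risk, between them low risk, above
#'   the second high risk. Default `c(10, 20)`.
#' @param target_fs Sampling rate (Hz) that recordings are resampled to on
#'   ingestion. Default 100.
#' @param invert_pitch,invert_yaw Flip the sign of the respective angle at
#'   the start of the pipeline, for upside-down sensor mounting. Forward
#'   trunk lean must be positive pitch for the peak search to work.
#' @param robust_turns Use the robust turn detector, which locates the two
#'   largest rate excursions of either sign and rescales the level
#'   criteria to each turn's flanking plateaus. Handles subjects who turn
#'   in the same direction both times (yaw 0 -> 180 -> 360), which the
#'   literal detector rejects. Default FALSE.
#'
#' @return An object of class `tug_config` (a validated named list).
#' @examples
#' cfg <- algorithm_config()
#' cfg$slope_stop_threshold
#' @export
algorithm_config <- function(smooth_order_N = 5L,
                             slope_stop_threshold = 0.05,
                             slope_stride = 0.1,
                             turn_window = 10L,
                             turn_low_level = 0.02,
                             turn_high_level = 0.9,
                             baseline_window = 0.5,
                             peak_min_separation = 3.0,
                             step_min_prominence = 1.0,
                             step_min_distance = 0.3,
                             risk_thresholds = c(10, 20),
                             target_fs = 100,
                             invert_pitch = FALSE,
                             invert_yaw = FALSE,
                             robust_turns = FALSE) {
  cfg <- list(
    smooth_order_N = as.integer(smooth_order_N),
    slope_stop_threshold = as.numeric(slope_stop_threshold),
    slope_stride = as.numeric(slope_stride),
    turn_window = as.integer(turn_window),
    turn_low_level = as.numeric(turn_low_level),
    turn_high_level = as.numeric(turn_high_level),
    baseline_window = as.numeric(baseline_window),
    peak_min_separation = as.numeric(peak_min_separation),
    step_min_prominence = as.numeric(step_min_prominence),
    step_min_distance = as.numeric(step_min_distance),
    risk_thresholds = as.numeric(risk_thresholds),
    target_fs = as.numeric(target_fs),
    invert_pitch = isTRUE(invert_pitch),
    invert_yaw = isTRUE(invert_yaw),
    robust_turns = isTRUE(robust_turns)
  )
  if (cfg$smooth_order_N < 1L)
    stop_tugseg("smooth_order_N must be >= 1", "config_error")
  if (cfg$slope_stride <= 0)
    stop_tugseg("slope_stride must be > 0", "config_error")
  if (!(cfg$turn_low_level > 0 && cfg$turn_low_level < cfg$turn_high_level &&
        cfg$turn_high_level < 1))
    stop_tugseg("need 0 < turn_low_level < turn_high_level < 1", "config_error")
  if (cfg$turn_window < 1L)
    stop_tugseg("turn_window must be >= 1 sample", "config_error")
  if (cfg$target_fs <= 0)
    stop_tugseg("target_fs must be > 0", "config_error")
  if (length(cfg$risk_thresholds) != 2L ||
      diff(cfg$risk_thresholds) <= 0)
    stop_tugseg("risk_thresholds must be two strictly increasing values",
                "config_error")
  structure(cfg, class = "tug_config")
}

#' Build a configuration from a key-value file
#'
#' Reads a YAML (or JSON) file whose keys mirror [algorithm_config()]
#' arguments and returns the resulting validated configuration. Unknown
#' keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A `tug_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_tugseg(sprintf("config file not found: %s", path), "io_error")
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_tugseg("yaml package required to read YAML config", "config_error")
    yaml::read_yaml(path)
  }
  known <- names(formals(algorithm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_tugseg(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
                "config_error")
  do.call(algorithm_config, vals)
}

#' @export
print.tug_config <- function(x, ...) {
  cat("TUG segmentation configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
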