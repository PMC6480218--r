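#' Construct an IMU recording
#'
#' The central data object: a uniformly sampled multi-channel time series
#' from a single lumbar-mounted IMU. Orientation is carried as Euler
#' angles in degrees (pitch = sagittal trunk inclination, forward lean
#' positive; yaw = transverse-plane heading), inertial channels in m/s^2
#' and deg/s. All timestamps are seconds from recording start; sample
#' indexing is 0-based in time (`t[1]` need not be 0 but usually is).
#'
#' @param t Time stamps in seconds, strictly increasing, near-uniform.
#' @param fs Sampling rate in Hz.
#' @param pitch,yaw Orientation angles in degrees (required, finite).
#' @param roll Optional roll angle in degrees.
#' @param acc_x,acc_y,acc_z Optional accelerometer channels in m/s^2;
#'   `acc_z` is the vertical/longitudinal channel used for step counting.
#' @param gyr_x,gyr_y,gyr_z Optional gyroscope channels in deg/s;
#'   `gyr_z` is the transverse (turn-rate) channel.
#' @param subject_meta Free-form named list of labels (id, age group, ...).
#' @return An object of class `imu_recording`.
#' @seealso [read_recording()] to ingest delimited text files.
#' @export
imu_recording <- function(t, fs, pitch, yaw, roll = NULL,
                          acc_x = NULL, acc_y = NULL, acc_z = NULL,
                          gyr_x = NULL, gyr_y = NULL, gyr_z = NULL,
                          subject_meta = list()) {
  rec <- list(t = as.numeric(t), fs = as.numeric(fs),
              pitch = as.numeric(pitch), yaw = as.numeric(yaw),
              roll = if (is.null(roll)) NULL else as.numeric(roll),
              acc_x = if (is.null(acc_x)) NULL else as.numeric(acc_x),
              acc_y = if (is.null(acc_y)) NULL else as.numeric(acc_y),
              acc_z = if (is.null(acc_z)) NULL else as.numeric(acc_z),
              gyr_x = if (is.null(gyr_x)) NULL else as.numeric(gyr_x),
              gyr_y = if (is.null(gyr_y)) NULL else as.numeric(gyr_y),
              gyr_z = if (is.null(gyr_z)) NULL else as.numeric(gyr_z),
              subject_meta = subject_meta)
  class(rec) <- "imu_recording"
  validate_imu_recording(rec)
}

validate_imu_recording <- function(rec) {
  n <- length(rec$t)
  if (n < 2L)
    stop_tugseg("recording needs at least 2 samples", "data_error")
  if (rec$fs <= 0)
    stop_tugseg("sampling rate must be positive", "data_error")
  if (any(diff(rec$t) <= 0))
    stop_tugseg("time stamps must be strictly increasing", "data_error")
  dt <- 1 / rec$fs
  if (max(abs(diff(rec$t) - dt)) > 0.25 * dt)
    stop_tugseg("time stamps deviate from the stated sampling rate; resample first",
                "data_error")
  for (ch in c("pitch", "yaw", "roll", "acc_x", "acc_y", "acc_z",
               "gyr_x", "gyr_y", "gyr_z")) {
    v <- rec[[ch]]
    if (is.null(v)) next
    if (length(v) != n)
      stop_tugseg(sprintf("channel %s has length %d, expected %d",
                          ch, length(v), n), "data_error")
    if (ch %in% c("pitch", "yaw") && any(!is.finite(v)))
      stop_tugseg(sprintf("channel %s contains non-finite values", ch),
                  "data_error")
  }
  rec
}

#' @export
print.imu_recording <- function(x, ...) {
  chans <- c("pitch", "yaw", "roll", "acc_x", "acc_y", "acc_z",
             "gyr_x", "gyr_y", "gyr_z")
  present <- chans[!vapply(x[chans], is.null, logical(1))]
  cat(sprintf("IMU recording: %d samples at %g Hz (%.2f s)\n",
              length(x$t), x$fs, x$t[length(x$t)] - x$t[1]))
  cat("  channels:", paste(present, collapse = ", "), "\n")
  if (length(x$subject_meta))
    cat("  meta:", paste(names(x$subject_meta), unlist(x$subject_meta),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Default file-column names; values are the column names looked up in the
# file header, names are the internal channel names.
default_column_map <- function() {
  list(time = "time", pitch = "pitch", yaw = "yaw", roll = "roll",
       qw = "qw", qx = "qx", qy = "qy", qz = "qz",
       acc_x = "acc_x", acc_y = "acc_y", acc_z = "acc_z",
       gyr_x = "gyr_x", gyr_y = "gyr_y", gyr_z = "gyr_z")
}

#' Read an IMU recording from delimited text
#'
#' Ingests a CSV/TSV file with a header row. The file must contain a time
#' column plus either Euler orientation columns (pitch, yaw in degrees) or
#' unit-quaternion columns (qw, qx, qy, qz); quaternions are converted to
#' Euler angles with [quaternion_to_euler()] when Euler columns are
#' absent. All channels are resampled to `config$target_fs` by linear
#' interpolation (the identity when the file is already on that grid).
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Named list overriding the default file column names
#'   (internal names: time, pitch, yaw, roll, qw..qz, acc_x..gyr_z).
#' @param config An [algorithm_config()]; only `target_fs` is used here.
#' @return An [imu_recording()].
#' @export
read_recording <- function(path, column_map = NULL,
                           config = algorithm_config()) {
  if (!file.exists(path))
    stop_tugseg(sprintf("file not found: %s", path), "io_error")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  cmap <- default_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map

  pick <- function(ch) {
    col <- cmap[[ch]]
    if (!is.null(col) && col %in% names(df)) as.numeric(df[[col]]) else NULL
  }
  t_raw <- pick("time")
  if (is.null(t_raw))
    stop_tugseg(sprintf("missing required column: %s", cmap$time),
                "schema_error")
  if (length(t_raw) < 2L)
    stop_tugseg("fewer than 2 samples in file", "data_error")
  if (any(diff(t_raw) <= 0))
    stop_tugseg("time column is not strictly increasing", "data_error")

  pitch <- pick("pitch"); yaw <- pick("yaw"); roll <- pick("roll")
  if (is.null(pitch) || is.null(yaw)) {
    q <- lapply(c("qw", "qx", "qy", "qz"), pick)
    if (any(vapply(q, is.null, logical(1)))) {
      missing_euler <- c(cmap$pitch, cmap$yaw)[c(is.null(pitch), is.null(yaw))]
      stop_tugseg(sprintf(
        "missing required column(s): %s (and no complete quaternion columns)",
        paste(missing_euler, collapse = ", ")), "schema_error")
    }
    eul <- quaternion_to_euler(q[[1]], q[[2]], q[[3]], q[[4]])
    yaw <- eul$yaw; pitch <- eul$pitch; roll <- eul$roll
  }
  if (any(!is.finite(pitch)) || any(!is.finite(yaw)))
    stop_tugseg("pitch/yaw contain non-finite values", "data_error")

  fs <- config$target_fs
  t_new <- seq(t_raw[1], t_raw[length(t_raw)], by = 1 / fs)
  identity_grid <- length(t_new) == length(t_raw) &&
    max(abs(t_new - t_raw)) < 1e-9
  res <- function(v) {
    if (is.null(v)) return(NULL)
    if (identity_grid) return(v)
    stats::approx(t_raw, v, xout = t_new, rule = 2)$y
  }
  imu_recording(t = if (identity_grid) t_raw else t_new, fs = fs,
                pitch = res(pitch), yaw = res(yaw), roll = res(roll),
                acc_x = res(pick("acc_x")), acc_y = res(pick("acc_y")),
                acc_z = res(pick("acc_z")),
                gyr_x = res(pick("gyr_x")), gyr_y = res(pick("gyr_y")),
                gyr_z = res(pick("gyr_z")))
}

#' Convert unit quaternions to intrinsic Z-Y-X Euler angles
#'
#' Uses the aerospace (yaw-pitch-roll) sequence: yaw about the vertical
#' axis, then pitch, then roll. Inputs are normalised before conversion.
#'
#' @param w,x,y,z Quaternion components (vectors of equal length).
#' @return A list with components `yaw`, `pitch`, `roll` in degrees,
#'   with yaw in (-180, 180] and pitch in [-90, 90].
#' @examples
#' quaternion_to_euler(cos(pi / 4), 0, 0, sin(pi / 4)) # 90 deg yaw
#' @export
quaternion_to_euler <- function(w, x, y, z) {
  nrm <- sqrt(w^2 + x^2 + y^2 + z^2)
  if (any(nrm < 1e-12))
    stop_tugseg("quaternion has (near-)zero norm", "value_error")
  w <- w / nrm; x <- x / nrm; y <- y / nrm; z <- z / nrm
  deg <- 180 / pi
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2)) * deg
  sp <- pmin(1, pmax(-1, 2 * (w * y - z * x)))
  pitch <- asin(sp) * deg
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2)) * deg
  # map yaw exactly -180 to +180 for a closed-open convention
  yaw[yaw <= -180] <- yaw[yaw <= -180] + 360
  list(yaw = yaw, pitch = pitch, roll = roll)
}

#' Write a structured JSON analysis report
#'
#' Serialises a segmentation, its features and the fall-risk assessment
#' (plus the configuration that produced them) to JSON. Event times are
#' sample-aligned, so the 3-decimal second formatting used in the file is
#' lossless at 100 Hz; [read_report()] round-trips all numeric fields.
#'
#' @param segmentation A `tug_segmentation` from [assemble_segments()].
#' @param features A `subtask_features` from [extract_features()].
#' @param risk A `risk_assessment` from [classify_risk()].
#' @param path Output file path; its directory must exist.
#' @param config The [algorithm_config()] used (embedded in the report).
#' @return Invisibly, the report list that was written.
#' @export
write_report <- function(segmentation, features, risk, path,
                         config = algorithm_config()) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_tugseg(sprintf("output directory does not exist: %s", dir),
                "io_error")
  r3 <- function(v) round(as.numeric(v), 3)
  seg_list <- lapply(segmentation$intervals, function(iv)
    list(start = r3(iv[1]), end = r3(iv[2]), duration = r3(iv[2] - iv[1])))
  report <- list(
    schema_version = "1.0",
    segmentation = c(seg_list, list(
      presit_stance_gap = r3(segmentation$gap),
      total_time = r3(segmentation$total_time))),
    features = unclass(features),
    risk = list(category = risk$category,
                total_time = r3(risk$total_time),
                thresholds_used = as.numeric(risk$thresholds_used)),
    flags = as.list(segmentation$flags),
    config = unclass(config)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(report)
}

#' Read back a JSON analysis report
#'
#' @param path Path to a report written by [write_report()].
#' @return The report as a nested list.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop_tugseg(sprintf("report not found: %s", path), "io_error")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Per-sample sub-task annotation
#'
#' Labels every sample of a recording with the sub-task (or gap) interval
#' it falls in, for export alongside the raw signals.
#'
#' @param recording An [imu_recording()].
#' @param segmentation A `tug_segmentation` covering the recording.
#' @return A data.frame with columns `sample` (0-based), `time`, `label`.
#' @export
annotate_recording <- function(recording, segmentation) {
  lab <- rep("idle", length(recording$t))
  for (nm in names(segmentation$intervals)) {
    iv <- segmentation$intervals[[nm]]
    lab[recording$t >= iv[1] & recording$t <= iv[2]] <- nm
  }
  g <- segmentation$gap_interval
  if (!is.null(g) && g[2] > g[1])
    lab[recording$t > g[1] & recording$t < g[2]] <- "presit_stance"
  data.frame(sample = seq_along(recording$t) - 1L,
             time = recording$t, label = lab)
}
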