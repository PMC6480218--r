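#' Paired reference (video) and IMU total times
#'
#' Loads the packaged per-subject total-time measurements of the two
#' validation groups: 25 healthy young adults and 12 older adults (the
#' latter with risk-of-falling labels from both methods). Reference times
#' come from frame-by-frame video analysis averaged over two raters; test
#' times from the IMU segmentation.
#'
#' @param group `"young"` or `"older"`.
#' @return A data.frame with columns `subject`, `height_cm`, `weight_kg`,
#'   `age_yr`, `sex`, `video_time_s`, `imu_time_s`, and for the older
#'   group `video_rof`, `imu_rof` (labels: no / low / high).
#' @export
tug_reference_times <- function(group = c("young", "older")) {
  group <- match.arg(group)
  f <- system.file("extdata",
                   sprintf("tug_total_times_%s.csv", group),
                   package = "tugseg", mustWork = TRUE)
  utils::read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
}

#' Pearson product-moment correlation
#'
#' Thin, validated wrapper around [stats::cor()]: requires at least three
#' pairs and nonzero variance in both arguments.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    stop_tugseg("length mismatch", "value_error")
  if (length(x) < 3L)
    stop_tugseg("need at least 3 pairs", "value_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_tugseg("zero variance", "value_error")
  stats::cor(x, y)
}

#' Bland-Altman method-agreement statistics
#'
#' Differences are `d = x - y` (reference minus test), so a positive bias
#' means the test method under-reads. Limits of agreement are
#' `bias +/- 1.96 * sd(d)` with the sample (n - 1) standard deviation.
#'
#' @param x Reference measurements.
#' @param y Test measurements, same length.
#' @return An `agreement_stats` list: `pearson_r` (NA for n < 3 or
#'   degenerate input), `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `mean_abs_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    stop_tugseg("length mismatch", "value_error")
  if (length(x) < 2L)
    stop_tugseg("need at least 2 pairs", "value_error")
  d <- x - y
  bias <- mean(d)
  sdd <- stats::sd(d)
  r <- if (length(x) >= 3L && stats::sd(x) > 0 && stats::sd(y) > 0)
    stats::cor(x, y) else NA_real_
  structure(list(pearson_r = r, bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 mean_abs_diff = mean(abs(d)), n = length(x)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "Agreement (n = %d): r = %.4f, bias = %.3f s (sd %.3f), LoA [%.3f, %.3f]\n",
    x$n, x$pearson_r, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Risk-category concordance between two raters/methods
#'
#' @param reference,test Character vectors of risk labels (no/low/high),
#'   equal length.
#' @return Percent agreement, rounded to the nearest integer.
#' @export
risk_agreement <- function(reference, test) {
  if (length(reference) != length(test))
    stop_tugseg("length mismatch", "value_error")
  if (!length(reference) || any(is.na(reference)) || any(is.na(test)))
    stop_tugseg("missing labels", "value_error")
  round(100 * mean(reference == test))
}

#' Signed segmentation errors against ground truth
#'
#' @param truth A `tug_ground_truth` from [simulate_tug()].
#' @param est A `tug_segmentation` from the pipeline.
#' @return A list with `boundary` (named vector of the 8 signed boundary
#'   errors, truth minus estimate, seconds) and `duration` (the 6 signed
#'   sub-task duration errors).
#' @export
segmentation_error <- function(truth, est) {
  bt <- truth$boundaries
  be <- est$boundaries[names(bt)]
  boundary <- bt - be
  tru_dur <- c(standing = bt[["standing_f"]] - bt[["standing_i"]],
               first_walk = bt[["turn1_i"]] - bt[["standing_f"]],
               turn_3m = bt[["turn1_f"]] - bt[["turn1_i"]],
               second_walk = bt[["turn2_i"]] - bt[["turn1_f"]],
               presit_turn = bt[["turn2_f"]] - bt[["turn2_i"]],
               sitting = bt[["sitting_f"]] - bt[["sitting_i"]])
  est_dur <- vapply(est$intervals, function(iv) iv[2] - iv[1], numeric(1))
  list(boundary = boundary, duration = tru_dur - est_dur[names(tru_dur)])
}

#' Closure benchmark: segmentation error over random scenarios
#'
#' Simulates `n` population-typical trials with exact ground truth, runs
#' the full pipeline on each and collects the signed boundary and
#' duration errors, in the shape of a per-sub-task error summary table.
#'
#' @param n Number of scenarios.
#' @param seed Integer seed; per-scenario seeds are derived from it.
#' @param population `"young"` or `"older"`.
#' @param config An [algorithm_config()].
#' @return A list with `boundary_errors` (n x 8 matrix), `duration_errors`
#'   (n x 6 matrix), `summary` (mean/sd per boundary), `median_abs_error`
#'   and `max_abs_error` over all boundary errors, and `n_failed`
#'   (scenarios where a detector raised an error).
#' @export
segmentation_benchmark <- function(n = 100, seed = 1,
                                   population = c("young", "older"),
                                   config = algorithm_config()) {
  population <- match.arg(population)
  bnames <- c("standing_i", "standing_f", "turn1_i", "turn1_f",
              "turn2_i", "turn2_f", "sitting_i", "sitting_f")
  dnames <- c("standing", "first_walk", "turn_3m", "second_walk",
              "presit_turn", "sitting")
  be <- matrix(NA_real_, n, 8, dimnames = list(NULL, bnames))
  de <- matrix(NA_real_, n, 6, dimnames = list(NULL, dnames))
  failed <- 0L
  scen_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  for (i in seq_len(n)) {
    sc <- random_scenario(scen_seeds[i], population)
    sim <- simulate_tug(sc)
    res <- tryCatch(run_pipeline(sim$recording, config),
                    tugseg_error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      next
    }
    err <- segmentation_error(sim$truth, res$segmentation)
    be[i, ] <- err$boundary[bnames]
    de[i, ] <- err$duration[dnames]
  }
  ok <- stats::complete.cases(be)
  abs_all <- abs(be[ok, , drop = FALSE])
  list(boundary_errors = be, duration_errors = de,
       summary = data.frame(
         boundary = bnames,
         mean_error = colMeans(be[ok, , drop = FALSE]),
         sd_error = apply(be[ok, , drop = FALSE], 2, stats::sd),
         row.names = NULL),
       median_abs_error = stats::median(abs_all),
       max_abs_error = max(abs_all),
       n_failed = failed)
}
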