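# Internal helpers shared across modules.

# Classed conditions so callers can distinguish schema/data/detection/...
# failures programmatically (and the CLI can map them to exit codes).
stop_tugseg <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("tugseg_", class), "tugseg_error"),
                      call = call))
}

# Run an expression with a fixed RNG state, restoring the caller's state
# afterwards so simulation helpers do not clobber the global stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Truncated-normal draw by rejection; bounds are hard limits.
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# Local maxima with prominence and minimum-distance suppression.
# Returns a data.frame of kept peaks ordered by index. A peak's
# prominence is its height above the higher of the two deepest valleys
# separating it from the nearest higher sample on each side (signal
# edges count as boundaries). Suppression keeps the more prominent peak.
find_peaks <- function(x, min_prominence = 0, min_distance = 0) {
  n <- length(x)
  if (n < 3L) {
    return(data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  }
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(idx)) {
    return(data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(idx, function(i) {
    h <- x[i]
    # walk left to nearest sample higher than the peak (or the edge)
    lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (min_distance > 0 && length(idx) > 1L) {
    ord <- order(prom, decreasing = TRUE)
    sel <- logical(length(idx))
    taken <- integer(0)
    for (k in ord) {
      if (!length(taken) || all(abs(idx[k] - taken) >= min_distance)) {
        sel[k] <- TRUE
        taken <- c(taken, idx[k])
      }
    }
    idx <- idx[sel]; prom <- prom[sel]
  }
  o <- order(idx)
  data.frame(index = idx[o], value = x[idx[o]], prominence = prom[o])
}

# Snap a time to the recording's sample grid.
snap_time <- function(t_query, t) {
  t[which.min(abs(t - t_query))]
}

time_to_index <- function(t_query, t) {
  which.min(abs(t - t_query))
}
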