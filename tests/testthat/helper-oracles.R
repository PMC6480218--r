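# Independent oracles and small constructors used across the suite.

# rotation matrix directly from a unit quaternion
quat_rotmat <- function(w, x, y, z) {
  nrm <- sqrt(w^2 + x^2 + y^2 + z^2)
  w <- w / nrm; x <- x / nrm; y <- y / nrm; z <- z / nrm
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rotation matrix from intrinsic Z-Y-X Euler angles (degrees)
euler_zyx_rotmat <- function(yaw, pitch, roll) {
  r <- pi / 180
  cy <- cos(yaw * r); sy <- sin(yaw * r)
  cp <- cos(pitch * r); sp <- sin(pitch * r)
  cr <- cos(roll * r); sr <- sin(roll * r)
  Rz <- matrix(c(cy, -sy, 0, sy, cy, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cp, 0, sp, 0, 1, 0, -sp, 0, cp), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cr, -sr, 0, sr, cr), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# brute-force loop implementation of the forward moving average
naive_moving_average <- function(x, N) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    y[i] <- mean(x[i:min(n, i + N - 1)])
  }
  y
}

# wrap a plain values vector as a conditioned signal for detector tests
make_cond <- function(values, fs = 100, t0 = 0, unwrapped = NULL) {
  structure(list(values = values,
                 t = t0 + (seq_along(values) - 1) / fs,
                 fs = fs, scale = 1, baseline = 0, degenerate = FALSE,
                 direction = "positive", unwrapped = unwrapped),
            class = "conditioned_signal")
}

# raised-cosine bump of given amplitude on [t_on, t_off], zero elsewhere
rc_bump <- function(t, t_on, t_off, amp) {
  u <- (t - t_on) / (t_off - t_on)
  v <- amp * 0.5 * (1 - cos(2 * pi * u))
  v[u < 0 | u > 1] <- 0
  v
}

# reference trial geometry used across tests: standing [0.5, 1.7],
# turns [4.0, 5.8] and [8.6, 9.7], sitting [9.9, 11.4]
example_scenario <- function(seed = 11, ...) {
  tug_scenario(durations = c(standing = 1.2, first_walk = 2.3,
                             turn_3m = 1.8, second_walk = 2.8,
                             presit_turn = 1.1, sitting = 1.5),
               presit_gap = 0.2, lead_in = 0.5, lead_out = 1.5,
               seed = seed, ...)
}
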