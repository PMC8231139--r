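# Shared fixtures, memoized so expensive phantoms are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Small noise-free phantom covering the full sweep (20 frames, 84 px native,
# truth masks at the 2x working resolution).
phantom_small <- function() {
  memo("phantom_small", generate_sequence(
    phantom_spec(duration_s = 4, frame_interval_ms = 200,
                 native_size_px = 84L, noise_sigma = 0, seed = 42)
  ))
}

# Study-rate motion (100 ms frames over a 30 s sweep), native-resolution
# masks; used by the temporal-stability tests.
phantom_slow <- function() {
  memo("phantom_slow", generate_sequence(
    phantom_spec(duration_s = 30, frame_interval_ms = 100,
                 native_size_px = 84L, noise_sigma = 0.05, seed = 7),
    mask_scale = 1
  ))
}

# A mask with two labelled rectangles, for quick morphology/metric checks.
two_block_mask <- function() {
  m <- matrix(0L, 40, 40)
  m[10:20, 5:15] <- 3L
  m[10:20, 20:30] <- 4L
  m
}

# Forearm (radius + ulna) plus a distal block rotated to a target pose;
# used as the analytic oracle for the bounding-box wrist angle.
analytic_pose_mask <- function(theta_deg, size = 200L) {
  m <- matrix(0L, size, size)
  cx <- (86 + 116) / 2
  m[120:190, 86:100] <- 1L
  m[120:190, 102:116] <- 2L
  cf <- c(cx, (120 + 190) / 2)
  a <- theta_deg * pi / 180
  cdr <- c(cf[1] + 80 * sin(a), cf[2] - 80 * cos(a))
  ii <- round(cdr[2]) + (-8:8)
  jj <- round(cdr[1]) + (-14:14)
  m[ii, jj] <- 7L
  m[ii[1:5], jj] <- 6L
  m[ii, jj[1:4]] <- 8L
  m
}

expect_angle_equal <- function(measured, expected, tol) {
  expect_lt(abs(measured - expected), tol)
}
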