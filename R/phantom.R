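#' Parametric description of the synthetic articulated-wrist phantom
#'
#' The phantom emulates a coronal 2D+time acquisition of a wrist performing
#' continuous radial-to-ulnar abduction ("waving"). Eight bone classes are
#' modelled as superellipses: radius and ulna are fixed, the carpus (proximal
#' row scaphoid/lunate/triquetrum on a carpal arc, distal row
#' hamate/capitate/trapezium-trapezoid) rotates rigidly about the centre of
#' the forearm bounding box, so that the bounding-box wrist-angle measurement
#' of [wrist_angle()] recovers the pose exactly. The intra-row bone spacing
#' is re-laid-out each frame so the SL and LT separations along the carpal
#' arc equal the ground-truth gap functions.
#'
#' @param duration_s sequence duration in seconds (default 30). One full
#'   radial-ulnar-radial movement cycle spans the duration.
#' @param frame_interval_ms time between frames in ms (default 100, i.e.
#'   300 frames in 30 s; the underlying acquisition resolution is about
#'   95 ms, see [frame_acquisition_ms()]).
#' @param native_size_px square image matrix side in pixels (default 168).
#' @param pixel_spacing_mm pixel size in mm/px (default 1.0). The field of
#'   view `native_size_px * pixel_spacing_mm` must be at least 84 mm to hold
#'   the articulated wrist at all poses.
#' @param angle_min_deg radial extreme of the sweep, negative (default -15).
#' @param angle_max_deg ulnar extreme, positive (default +35).
#' @param injury_mode logical; if `TRUE` the default gap functions emulate a
#'   scapholunate ligament injury (SL gap about 4 mm radially, collapsing
#'   towards 1 mm in deep ulnar abduction; LT gap 0.7 mm rising above 1 mm).
#' @param sl_gap_fn,lt_gap_fn optional functions angle (deg) -> gap (mm)
#'   overriding the built-in healthy/injury defaults. Healthy defaults:
#'   SL 1.70 mm with slope -0.002 mm/deg, LT 1.30 mm with slope -0.003
#'   mm/deg.
#' @param noise_sigma SD of additive Gaussian noise on normalized intensities
#'   (default 0.05).
#' @param bone_intensity,background_intensity intensity levels before noise
#'   (defaults 1.0 and 0.15).
#' @param seed integer RNG seed for the noise stream.
#' @return object of class `carpo_phantom_spec`.
#' @seealso [generate_sequence()], [wrist_pose_at()], [gap_truth()]
#' @export
phantom_spec <- function(duration_s = 30,
                         frame_interval_ms = 100,
                         native_size_px = 168L,
                         pixel_spacing_mm = 1.0,
                         angle_min_deg = -15,
                         angle_max_deg = 35,
                         injury_mode = FALSE,
                         sl_gap_fn = NULL,
                         lt_gap_fn = NULL,
                         noise_sigma = 0.05,
                         bone_intensity = 1.0,
                         background_intensity = 0.15,
                         seed = 1L) {
  stopifnot(duration_s > 0, frame_interval_ms > 0,
            native_size_px >= 8, pixel_spacing_mm > 0,
            noise_sigma >= 0)
  if (!(angle_min_deg < 0 && 0 < angle_max_deg)) {
    stop("angle_min_deg must be negative and angle_max_deg positive")
  }
  spec <- structure(list(
    duration_s = duration_s,
    frame_interval_ms = frame_interval_ms,
    native_size_px = as.integer(native_size_px),
    pixel_spacing_mm = pixel_spacing_mm,
    angle_min_deg = angle_min_deg,
    angle_max_deg = angle_max_deg,
    injury_mode = isTRUE(injury_mode),
    sl_gap_fn = sl_gap_fn,
    lt_gap_fn = lt_gap_fn,
    noise_sigma = noise_sigma,
    bone_intensity = bone_intensity,
    background_intensity = background_intensity,
    seed = as.integer(seed)
  ), class = "carpo_phantom_spec")
  ang <- seq(angle_min_deg, angle_max_deg, length.out = 101)
  g <- gap_truth(ang, spec)
  if (any(!is.finite(c(g$sl_mm, g$lt_mm))) || any(c(g$sl_mm, g$lt_mm) <= 0)) {
    stop("gap functions must be finite and strictly positive over the motion range")
  }
  spec
}

#' Wrist pose angle at a given time
#'
#' Cosine-eased sweep from the radial extreme to the ulnar extreme over the
#' first half of the sequence and back over the second half:
#' `angle(t) = min + (max - min) * (1 - cos(2*pi*t/T)) / 2`.
#'
#' @param t time in seconds (vectorized), within `[0, duration_s]`.
#' @param spec a [phantom_spec()].
#' @return wrist angle in degrees (radial negative, ulnar positive).
#' @export
wrist_pose_at <- function(t, spec) {
  if (any(t < 0 | t > spec$duration_s)) {
    stop_carpo("t outside [0, duration_s]", "carpo_range_error")
  }
  phase <- (1 - cos(2 * pi * t / spec$duration_s)) / 2
  spec$angle_min_deg + (spec$angle_max_deg - spec$angle_min_deg) * phase
}

#' Ground-truth SL and LT gap widths at a wrist angle
#'
#' Healthy mode: near-constant gaps with a small linear dependence on wrist
#' angle (SL 1.70 mm at neutral, slope -0.002 mm/deg; LT 1.30 mm, slope
#' -0.003 mm/deg). Injury mode (piecewise linear): SL stays at about 4 mm up
#' to +10 deg and collapses linearly to 1 mm at +35 deg; LT stays at 0.7 mm
#' and rises to 1.2 mm at +35 deg.
#'
#' @param angle wrist angle in degrees (vectorized).
#' @param spec a [phantom_spec()].
#' @return list with numeric vectors `sl_mm` and `lt_mm`.
#' @export
gap_truth <- function(angle, spec) {
  sl_fn <- spec$sl_gap_fn %||% if (spec$injury_mode) {
    function(a) ifelse(a <= 10, 4.0, pmax(4.0 - 3.0 * (a - 10) / 25, 1.0))
  } else {
    function(a) 1.70 - 0.002 * a
  }
  lt_fn <- spec$lt_gap_fn %||% if (spec$injury_mode) {
    function(a) ifelse(a <= 10, 0.7, pmin(0.7 + 0.5 * (a - 10) / 25, 1.2))
  } else {
    function(a) 1.30 - 0.003 * a
  }
  list(sl_mm = sl_fn(angle), lt_mm = lt_fn(angle))
}

# Anatomy of the phantom in mm, in a frame whose origin is the rotation
# pivot (= centre of the forearm bounding box); x positive towards the ulna,
# y positive towards the fingers. Sizes approximate adult carpal proportions.
.carpo_anatomy <- list(
  radius = list(c = c(-7.5, 0), a = 5.5, b = 16, n = 3.5),
  ulna = list(c = c(8.0, 0), a = 5.0, b = 16, n = 3.5),
  arc_radius = 30, y_proximal_row = 26,
  scaphoid = list(a = 7.0, b = 4.5, n = 3),
  lunate = list(a = 5.0, b = 4.5, n = 3),
  triquetrum = list(a = 5.5, b = 4.5, n = 3),
  hamate = list(c = c(9.75, 43), a = 4.75, b = 6, n = 2.5),
  capitate = list(c = c(0, 43), a = 5.0, b = 7, n = 2.5),
  trapezium_trapezoid = list(c = c(-9.75, 43), a = 4.75, b = 6, n = 2.5),
  pivot_below_centre_mm = 13, # pivot sits this far below the frame centre
  min_fov_mm = 84
)

# Bone layout at pose `theta` (deg) with row gaps (sl, lt) in mm.
# Returns a list of bones: class id, centre (x, y-up, mm, pivot origin),
# unit long-axis vector, half-axes a, b and superellipse exponent n.
phantom_bone_layout <- function(theta, sl_mm, lt_mm) {
  an <- .carpo_anatomy
  th <- theta * pi / 180
  rot_p <- function(p) c(p[1] * cos(th) + p[2] * sin(th),
                         -p[1] * sin(th) + p[2] * cos(th))
  bones <- list(
    list(class = 1L, c = an$radius$c, ax = c(0, 1),
         a = an$radius$b, b = an$radius$a, n = an$radius$n),
    list(class = 2L, c = an$ulna$c, ax = c(0, 1),
         a = an$ulna$b, b = an$ulna$a, n = an$ulna$n)
  )
  # proximal row on the carpal arc; arc-length position s, + towards ulna
  R <- an$arc_radius
  arc_c <- c(0, an$y_proximal_row + R)
  row <- list(
    scaphoid = list(id = 3L,
                    s = -(an$lunate$a + sl_mm + an$scaphoid$a), p = an$scaphoid),
    lunate = list(id = 4L, s = 0, p = an$lunate),
    triquetrum = list(id = 5L,
                      s = an$lunate$a + lt_mm + an$triquetrum$a, p = an$triquetrum)
  )
  for (b in row) {
    psi <- b$s / R
    centre <- arc_c + R * c(sin(psi), -cos(psi))
    # proximal-row bones are rounded annulus sectors: end faces lie along
    # radii of the carpal arc, so the inter-bone gap width is nearly
    # constant across the width of the row
    bones[[length(bones) + 1L]] <- list(
      class = b$id, type = "arc", c = rot_p(centre),
      arc_c = rot_p(arc_c), ref = rot_p(c(0, -1)), psi_c = psi, R = R,
      a = b$p$a, b = b$p$b, n = b$p$n
    )
  }
  for (nm in c("hamate", "capitate", "trapezium_trapezoid")) {
    p <- an[[nm]]
    bones[[length(bones) + 1L]] <- list(
      class = CARPO_CLASSES[[nm]], c = rot_p(p$c), ax = rot_p(c(0, 1)),
      a = p$b, b = p$a, n = p$n
    )
  }
  bones
}

# Rasterize a bone layout onto a square grid of `npx` pixels with pixel
# pitch `h` mm. Pixel (i, j) (1-based, row-major, origin top-left) has its
# centre at x = (j - 0.5) * h, y = (i - 0.5) * h in image mm; the pivot sits
# at (fov/2, fov/2 + pivot offset). Classes are drawn in ascending order
# (higher class painted last; bone shapes are laid out non-overlapping).
rasterize_bone_layout <- function(bones, npx, h, fov_mm) {
  x0 <- fov_mm / 2
  cy <- fov_mm / 2 + .carpo_anatomy$pivot_below_centre_mm
  lab <- matrix(0L, npx, npx)
  for (b in bones) {
    reach <- sqrt(b$a^2 + b$b^2)
    cx_img <- x0 + b$c[1]
    cy_img <- cy - b$c[2]
    jlo <- max(1L, floor((cx_img - reach) / h))
    jhi <- min(npx, ceiling((cx_img + reach) / h) + 1L)
    ilo <- max(1L, floor((cy_img - reach) / h))
    ihi <- min(npx, ceiling((cy_img + reach) / h) + 1L)
    if (jlo > jhi || ilo > ihi) next
    xs <- ((jlo:jhi) - 0.5) * h - x0
    ys <- cy - ((ilo:ihi) - 0.5) * h
    if (identical(b$type, "arc")) {
      dx <- outer(rep(1, length(ys)), xs) - b$arc_c[1]
      dy <- outer(ys, rep(1, length(xs))) - b$arc_c[2]
      r <- sqrt(dx^2 + dy^2)
      psi <- atan2(b$ref[1] * dy - b$ref[2] * dx, b$ref[1] * dx + b$ref[2] * dy)
      u <- (psi - b$psi_c) * b$R / b$a
      v <- (r - b$R) / b$b
    } else {
      px <- outer(rep(1, length(ys)), xs) - b$c[1]
      py <- outer(ys, rep(1, length(xs))) - b$c[2]
      tx <- b$ax
      nx <- c(-tx[2], tx[1])
      u <- (px * tx[1] + py * tx[2]) / b$a
      v <- (px * nx[1] + py * nx[2]) / b$b
    }
    inside <- (abs(u)^b$n + abs(v)^b$n) <= 1
    sub <- lab[ilo:ihi, jlo:jhi]
    sub[inside] <- b$class
    lab[ilo:ihi, jlo:jhi] <- sub
  }
  lab
}

#' Generate a synthetic wrist image sequence with ground truth
#'
#' Renders the phantom described by `spec` frame by frame: the wrist pose
#' follows [wrist_pose_at()], the SL/LT separations along the carpal arc
#' follow [gap_truth()], bone shapes are rasterized with sub-pixel
#' supersampling for realistic partial-volume edges, and additive Gaussian
#' noise is applied to the intensities only. Truth label masks are rasterized
#' on a `mask_scale`-times finer grid (default 2, matching the upsampled
#' working resolution of the segmentation pipeline).
#'
#' @param spec a [phantom_spec()].
#' @param mask_scale integer; truth masks are rasterized at
#'   `mask_scale * native_size_px` (default 2).
#' @param supersample sub-pixel sampling factor for the intensity rendering
#'   (default 3).
#' @return list of class `carpo_phantom` with elements `images` (a
#'   `carpo_sequence`: array `[H, W, T]`, `pixel_spacing_mm`,
#'   `frame_interval_ms`, `timestamps_ms`) and `truth` (a `carpo_truth`:
#'   per-frame `angle_deg`, `sl_mm`, `lt_mm`, integer mask array
#'   `[Hm, Wm, T]` and `mask_spacing_mm`).
#' @export
generate_sequence <- function(spec, mask_scale = 2L, supersample = 3L) {
  stopifnot(inherits(spec, "carpo_phantom_spec"))
  fov <- spec$native_size_px * spec$pixel_spacing_mm
  if (fov < .carpo_anatomy$min_fov_mm) {
    stop_carpo(sprintf(
      "field of view %.1f mm too small for the articulated wrist (need >= %d mm)",
      fov, .carpo_anatomy$min_fov_mm
    ), "carpo_degenerate_geometry")
  }
  n <- as.integer(round(spec$duration_s * 1000 / spec$frame_interval_ms))
  t_s <- (seq_len(n) - 1) * spec$frame_interval_ms / 1000
  ang <- wrist_pose_at(t_s, spec)
  gaps <- gap_truth(ang, spec)
  if (min(gaps$sl_mm, gaps$lt_mm) < spec$pixel_spacing_mm / mask_scale) {
    stop_carpo(
      "ground-truth gap narrower than one pixel at the requested mask resolution",
      "carpo_degenerate_geometry"
    )
  }
  npx <- spec$native_size_px
  nms <- npx * as.integer(mask_scale)
  nss <- npx * as.integer(supersample)
  imgs <- array(0, dim = c(npx, npx, n))
  masks <- array(0L, dim = c(nms, nms, n))
  for (k in seq_len(n)) {
    bones <- phantom_bone_layout(ang[k], gaps$sl_mm[k], gaps$lt_mm[k])
    masks[, , k] <- rasterize_bone_layout(bones, nms, fov / nms, fov)
    fine <- rasterize_bone_layout(bones, nss, fov / nss, fov) > 0
    cov <- block_mean(fine + 0, as.integer(supersample))
    imgs[, , k] <- spec$background_intensity +
      (spec$bone_intensity - spec$background_intensity) * cov
  }
  if (spec$noise_sigma > 0) {
    imgs <- imgs + with_seed(
      spec$seed,
      array(rnorm(length(imgs), sd = spec$noise_sigma), dim = dim(imgs))
    )
  }
  structure(list(
    images = structure(list(
      data = imgs,
      pixel_spacing_mm = spec$pixel_spacing_mm,
      frame_interval_ms = spec$frame_interval_ms,
      timestamps_ms = t_s * 1000
    ), class = "carpo_sequence"),
    truth = structure(list(
      angle_deg = ang, sl_mm = gaps$sl_mm, lt_mm = gaps$lt_mm,
      masks = masks,
      mask_spacing_mm = spec$pixel_spacing_mm / mask_scale
    ), class = "carpo_truth"),
    spec = spec
  ), class = "carpo_phantom")
}

# Mean over non-overlapping f x f blocks of a square matrix.
block_mean <- function(m, f) {
  if (f == 1L) return(m)
  n <- nrow(m) / f
  dim(m) <- c(f, n, f * n)
  m <- colSums(m) / f
  dim(m) <- c(n, f, n)
  colSums(aperm(m, c(2, 1, 3))) / f
}
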