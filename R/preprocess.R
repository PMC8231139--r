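#' Construct a single image frame
#'
#' @param intensities numeric matrix of pixel intensities.
#' @param pixel_spacing_mm pixel size in mm/px.
#' @param timestamp_ms frame timestamp in ms.
#' @return object of class `carpo_frame`.
#' @export
frame <- function(intensities, pixel_spacing_mm = 1.0, timestamp_ms = NA_real_) {
  stopifnot(is.matrix(intensities), all(is.finite(intensities)))
  structure(list(intensities = intensities,
                 pixel_spacing_mm = pixel_spacing_mm,
                 timestamp_ms = timestamp_ms),
            class = "carpo_frame")
}

as_frame <- function(x) {
  if (inherits(x, "carpo_frame")) x else frame(x)
}

# Apply `fn` to the intensity matrix of a frame or bare matrix, preserving
# the input type.
map_frame <- function(x, fn, ...) {
  if (inherits(x, "carpo_frame")) {
    x$intensities <- fn(x$intensities, ...)
    x
  } else {
    fn(x, ...)
  }
}

#' Percentile intensity clipping
#'
#' Crops intensities below the `p_low`-th and above the `p_high`-th empirical
#' percentile of the frame (adaptive window fitting). Percentiles use the
#' linear-interpolation convention of [stats::quantile()] type 7. A constant
#' image is returned unchanged (the percentiles coincide).
#'
#' @param x a `carpo_frame` or numeric matrix.
#' @param p_low,p_high percentile bounds in percent (defaults 10 and 99).
#' @return clipped frame of the same type as the input.
#' @export
clip_percentiles <- function(x, p_low = 10, p_high = 99) {
  stopifnot(p_low < p_high)
  map_frame(x, function(m) {
    q <- quantile(m, probs = c(p_low, p_high) / 100, names = FALSE, type = 7)
    pmin(pmax(m, q[1]), q[2])
  })
}

#' Z-score intensity normalization
#'
#' Centers the frame to mean 0 and scales it to standard deviation 1
#' (population convention, i.e. divisor `n`). Applied per image.
#'
#' @param x a `carpo_frame` or numeric matrix.
#' @return normalized frame of the same type as the input.
#' @export
zscore <- function(x) {
  map_frame(x, function(m) {
    mu <- mean(m)
    s <- sqrt(mean((m - mu)^2))
    if (s == 0) {
      stop_carpo("cannot Z-score a constant image (zero SD)",
                 "carpo_normalization_error")
    }
    (m - mu) / s
  })
}

# Separable Gaussian smoothing with replicate borders (small discrete
# kernel), used as anti-aliasing pre-filter before interpolation.
gauss_smooth <- function(m, sigma, radius = max(1L, ceiling(2 * sigma))) {
  k <- exp(-(-radius:radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(mm) {
    H <- nrow(mm)
    out <- matrix(0, H, ncol(mm))
    for (d in -radius:radius) {
      idx <- pmin(pmax(seq_len(H) + d, 1L), H)
      out <- out + k[d + radius + 1L] * mm[idx, , drop = FALSE]
    }
    out
  }
  t(sm1(t(sm1(m))))
}

# Order-2 (quadratic Lagrange) interpolation doubling the first dimension;
# output sample k (0-based) sits at input coordinate k/2 - 1/4
# (centre-aligned 2x grid), borders replicated.
up2_dim1 <- function(m) {
  H <- nrow(m)
  i0 <- seq_len(H)
  im1 <- m[pmax(i0 - 1L, 1L), , drop = FALSE]
  ip1 <- m[pmin(i0 + 1L, H), , drop = FALSE]
  # quadratic Lagrange weights at offsets -1/4 and +1/4 from the node
  even <- 0.15625 * im1 + 0.9375 * m - 0.09375 * ip1
  odd <- -0.09375 * im1 + 0.9375 * m + 0.15625 * ip1
  out <- matrix(0, 2L * H, ncol(m))
  out[seq(1L, 2L * H, by = 2L), ] <- even
  out[seq(2L, 2L * H, by = 2L), ] <- odd
  out
}

#' Biquadratic 2x spatial upsampling
#'
#' Doubles both image dimensions by separable quadratic (order-2)
#' interpolation after a small Gaussian anti-aliasing pre-filter, halving the
#' pixel spacing (e.g. 168x168 at 1.0 mm/px becomes 336x336 at 0.5 mm/px).
#'
#' @param x a `carpo_frame` or numeric matrix.
#' @param aa_sigma SD of the Gaussian pre-filter in pixels (default 0.5).
#' @return upsampled frame; for a `carpo_frame` input, `pixel_spacing_mm` is
#'   halved.
#' @export
upsample2x <- function(x, aa_sigma = 0.5) {
  up <- function(m) {
    if (aa_sigma > 0) m <- gauss_smooth(m, aa_sigma)
    t(up2_dim1(t(up2_dim1(m))))
  }
  if (inherits(x, "carpo_frame")) {
    x$intensities <- up(x$intensities)
    x$pixel_spacing_mm <- x$pixel_spacing_mm / 2
    x
  } else {
    up(x)
  }
}

#' Standard inference-time preprocessing of one frame
#'
#' Percentile clipping, Z-score normalization and biquadratic 2x upsampling,
#' in that order.
#' @param x a `carpo_frame` or numeric matrix.
#' @inheritParams clip_percentiles
#' @return preprocessed frame.
#' @export
preprocess_frame <- function(x, p_low = 10, p_high = 99) {
  upsample2x(zscore(clip_percentiles(x, p_low, p_high)))
}

#' Scale a polygon annotation
#'
#' Multiplies every vertex coordinate by `factor` (e.g. 2 when masks
#' accompany a 2x-upsampled image). Topology is unchanged.
#'
#' @param ann named list mapping class ids ("1".."8") to n x 2 matrices of
#'   (x, y) vertex coordinates in pixel units (0-based, x = column,
#'   y = row, origin top-left, integer coordinates at pixel centres).
#' @param factor scale factor (default 2).
#' @return scaled annotation.
#' @export
scale_annotation <- function(ann, factor = 2) {
  lapply(ann, function(v) v * factor)
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, xv, yv) {
  n <- length(xv)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((yv[i] > py) != (yv[j] > py)) &
      (px < (xv[j] - xv[i]) * (py - yv[i]) / (yv[j] - yv[i]) + xv[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon annotation to a label mask
#'
#' A pixel is assigned to a class when its centre lies inside the class
#' polygon (even-odd rule). Where polygons overlap, the higher class index is
#' drawn last and wins.
#'
#' @param ann annotation as in [scale_annotation()].
#' @param shape integer vector `c(H, W)` of the target mask.
#' @return integer label matrix `H x W`, 0 = background.
#' @export
rasterize_annotation <- function(ann, shape) {
  H <- shape[1]; W <- shape[2]
  lab <- matrix(0L, H, W)
  if (length(ann) == 0) return(lab)
  ids <- sort(as.integer(names(ann)))
  if (any(is.na(ids)) || any(ids < 1 | ids > 8)) {
    stop("annotation classes must be in 1..8")
  }
  for (id in ids) {
    v <- ann[[as.character(id)]]
    if (any(v[, 1] < -0.5 | v[, 1] > W - 0.5 | v[, 2] < -0.5 | v[, 2] > H - 0.5)) {
      stop_carpo("polygon vertex outside frame bounds", "carpo_bounds_error")
    }
    jlo <- max(1L, floor(min(v[, 1])) + 1L)
    jhi <- min(W, ceiling(max(v[, 1])) + 1L)
    ilo <- max(1L, floor(min(v[, 2])) + 1L)
    ihi <- min(H, ceiling(max(v[, 2])) + 1L)
    jj <- jlo:jhi; ii <- ilo:ihi
    px <- rep(jj - 1L, each = length(ii))
    py <- rep(ii - 1L, times = length(jj))
    ins <- points_in_polygon(px, py, v[, 1], v[, 2])
    sub <- lab[ii, jj]
    sub[ins] <- id
    lab[ii, jj] <- sub
  }
  lab
}

#' Augmentation configuration
#'
#' Ranges follow the training protocol: Gaussian noise with SD drawn from
#' `noise_sigma_range`, mirroring along the x axis, shifting along x by up to
#' `shift_frac_x` of the width, in-plane rotation within
#' `rotation_deg_range`, and zooming by up to `zoom_frac` in and out.
#' Geometric transforms are applied identically to image and mask with
#' nearest-neighbour resampling; noise applies to the image only.
#'
#' @param noise_sigma_range length-2 range of the noise SD (default
#'   `c(0, 0.2)`).
#' @param mirror_x logical; allow mirroring (drawn with probability 0.5).
#' @param shift_frac_x maximal horizontal shift as a fraction of image width
#'   (default 0.10).
#' @param rotation_deg_range length-2 range of rotation angles in degrees
#'   (default `c(-15, 15)`).
#' @param zoom_frac maximal zoom in/out fraction (default 0.10).
#' @param fill image fill value for pixels mapped from outside the frame;
#'   `NULL` (default) uses the median intensity of the frame (the background
#'   mode after Z-scoring). Masks are always filled with background (0).
#' @param seed optional integer; when given, parameter draws are made under
#'   this seed, otherwise the current RNG stream is used.
#' @return object of class `carpo_augment_config`.
#' @export
augment_config <- function(noise_sigma_range = c(0, 0.2),
                           mirror_x = TRUE,
                           shift_frac_x = 0.10,
                           rotation_deg_range = c(-15, 15),
                           zoom_frac = 0.10,
                           fill = NULL,
                           seed = NULL) {
  stopifnot(length(noise_sigma_range) == 2, diff(noise_sigma_range) >= 0,
            noise_sigma_range[1] >= 0, shift_frac_x >= 0,
            length(rotation_deg_range) == 2, diff(rotation_deg_range) >= 0,
            zoom_frac >= 0, zoom_frac < 1)
  structure(list(noise_sigma_range = noise_sigma_range,
                 mirror_x = isTRUE(mirror_x),
                 shift_frac_x = shift_frac_x,
                 rotation_deg_range = rotation_deg_range,
                 zoom_frac = zoom_frac, fill = fill, seed = seed),
            class = "carpo_augment_config")
}

# Nearest-neighbour resampling under the inverse of an affine map
# p' = A (p - c) + c + t given in (x, y) pixel units.
affine_nn <- function(m, A, tx, fill) {
  H <- nrow(m); W <- ncol(m)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xg <- rep(seq_len(W), each = H) - cx - tx[1]
  yg <- rep(seq_len(H), times = W) - cy - tx[2]
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  xs <- round(( A[2, 2] * xg - A[1, 2] * yg) / det + cx)
  ys <- round((-A[2, 1] * xg + A[1, 1] * yg) / det + cy)
  ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
  out <- matrix(fill, H, W)
  out[ok] <- m[cbind(ys[ok], xs[ok])]
  out
}

#' Apply a random augmentation to an image/mask pair
#'
#' Draws transform parameters within the configured ranges, composes mirror,
#' zoom, rotation and horizontal shift into one affine map applied with
#' nearest-neighbour resampling to both image and mask, then adds Gaussian
#' noise to the image only. When every drawn parameter is the identity, the
#' inputs are returned untouched (no resampling).
#'
#' @param x a `carpo_frame` or numeric matrix.
#' @param mask integer label matrix congruent with the image.
#' @param cfg an [augment_config()].
#' @return list with elements `frame` and `mask`.
#' @export
augment <- function(x, mask, cfg = augment_config()) {
  img <- if (inherits(x, "carpo_frame")) x$intensities else x
  stopifnot(is.matrix(img), all(dim(img) == dim(mask)))
  draw <- function() {
    list(
      sigma = runif(1, cfg$noise_sigma_range[1], cfg$noise_sigma_range[2]),
      mirror = cfg$mirror_x && runif(1) < 0.5,
      shift = runif(1, -cfg$shift_frac_x, cfg$shift_frac_x) * ncol(img),
      rot = runif(1, cfg$rotation_deg_range[1], cfg$rotation_deg_range[2]),
      zoom = runif(1, 1 - cfg$zoom_frac, 1 + cfg$zoom_frac)
    )
  }
  p <- if (is.null(cfg$seed)) draw() else with_seed(cfg$seed, draw())
  geom_identity <- !p$mirror && p$shift == 0 && p$rot == 0 && p$zoom == 1
  if (!geom_identity) {
    a <- p$rot * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    A <- R %*% diag(c(p$zoom, p$zoom)) %*% diag(c(if (p$mirror) -1 else 1, 1))
    fill <- cfg$fill %||% median(img)
    img <- affine_nn(img, A, c(p$shift, 0), fill)
    mask <- affine_nn(mask, A, c(p$shift, 0), 0L)
  }
  if (p$sigma > 0) {
    img <- img + matrix(rnorm(length(img), sd = p$sigma), nrow(img))
  }
  out_frame <- if (inherits(x, "carpo_frame")) {
    x$intensities <- img
    x
  } else {
    img
  }
  list(frame = out_frame, mask = mask)
}
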