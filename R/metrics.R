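#' Fuse the proximal carpal row into one region
#'
#' Takes the union of the scaphoid, lunate and triquetrum masks and closes
#' it morphologically with a disc large enough to bridge the inter-bone
#' gaps, yielding a single connected region through which the carpal-arc
#' centerline can be routed. The closing radius is escalated from
#' `close_radius_px` up to `max_radius_px` until the union is connected.
#'
#' @param mask integer label mask.
#' @param close_radius_px initial closing radius in pixels (default 5,
#'   bridging gaps up to about 5 mm at 0.5 mm/px).
#' @param max_radius_px largest radius tried before giving up (default 12).
#' @return binary matrix (0/1) of the fused region.
#' @export
fuse_proximal_row <- function(mask, close_radius_px = 5L, max_radius_px = 12L) {
  present <- intersect(PROXIMAL_ROW, unique(as.integer(mask)))
  if (length(present) < 2) {
    stop_carpo("need at least two proximal-row bones to fuse",
               "carpo_fusion_error")
  }
  u <- (mask %in% PROXIMAL_ROW) + 0
  dim(u) <- dim(mask)
  for (r in close_radius_px:max_radius_px) {
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    closed <- EBImage::closing(u, brush)
    lab <- EBImage::bwlabel(closed)
    if (max(lab) == 1) return(closed)
  }
  stop_carpo("proximal-row bones too far apart to bridge at max radius",
             "carpo_fusion_error")
}

# Minimum-area (rotated) bounding rectangle of a point set via rotating
# calipers over the convex hull. Points are an n x 2 matrix of (x, y).
min_area_rect <- function(pts) {
  h <- chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  best <- NULL
  for (i in seq_len(nh)) {
    e <- hp[i %% nh + 1, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hp %*% u
    pv <- hp %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    if (is.null(best) || area < best$area) {
      centre <- (min(pu) + du / 2) * u + (min(pv) + dv / 2) * v
      if (du >= dv) {
        best <- list(area = area, centre = centre, long_axis = u,
                     length = du, width = dv)
      } else {
        best <- list(area = area, centre = centre, long_axis = v,
                     length = dv, width = du)
      }
    }
  }
  best
}

mask_points <- function(mask, classes) {
  idx <- which(matrix(mask %in% classes, nrow(mask), ncol(mask)),
               arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

#' Extract the carpal-arc centerline of a fused proximal row
#'
#' Skeletonizes the fused region (Zhang-Suen thinning), keeps the longest
#' geodesic path through the skeleton, and smooths it with cubic smoothing
#' splines in arc-length parameterization. The result is an ordered
#' sub-pixel polyline; when `orient_to` (e.g. the scaphoid centroid) is
#' given, the curve is oriented to start at the end nearest to it.
#'
#' @param fused binary matrix from [fuse_proximal_row()].
#' @param orient_to optional `c(x, y)` point fixing the starting end.
#' @param step resampling step along the curve in pixels (default 0.25).
#' @param df spline degrees of freedom; `NULL` (default) scales with path
#'   length.
#' @return matrix with columns `x`, `y` (pixel units, 1-based centres).
#' @export
carpal_centerline <- function(fused, orient_to = NULL, step = 0.25, df = NULL) {
  skel <- cpp_thin(matrix(as.integer(fused > 0), nrow(fused), ncol(fused)))
  path <- cpp_skeleton_longest_path(skel)
  if (nrow(path) < 5) {
    stop_carpo("skeleton degenerates to a point", "carpo_centerline_error")
  }
  xy <- cbind(x = path[, 2], y = path[, 1])
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  if (is.null(df)) df <- max(5, min(12, round(nrow(xy) / 6)))
  fx <- smooth.spline(s, xy[, 1], df = df)
  fy <- smooth.spline(s, xy[, 2], df = df)
  ss <- seq(0, max(s), by = step)
  out <- cbind(x = predict(fx, ss)$y, y = predict(fy, ss)$y)
  # the medial axis stops about half a region-width short of the ends;
  # extend along the end tangents to the region boundary
  fmat <- (fused > 0) + 0
  dim(fmat) <- dim(fused)
  extend <- function(pts) {
    n <- nrow(pts)
    m <- min(40, n)
    Q <- pts[(n - m + 1):n, , drop = FALSE]
    p <- pts[n, ]
    # follow the local curvature: algebraic circle fit of the end segment,
    # falling back to the straight tangent for (near-)straight regions
    next_pt <- NULL
    sol <- tryCatch(qr.solve(cbind(Q, 1), -(Q[, 1]^2 + Q[, 2]^2)),
                    error = function(e) NULL)
    if (!is.null(sol)) {
      cx <- -sol[1] / 2
      cy <- -sol[2] / 2
      Rf <- sqrt(max(cx^2 + cy^2 - sol[3], 0))
      if (is.finite(Rf) && Rf > 2 && Rf < 500) {
        phi_end <- atan2(p[2] - cy, p[1] - cx)
        phi_prev <- atan2(Q[1, 2] - cy, Q[1, 1] - cx)
        dphi <- atan2(sin(phi_end - phi_prev), cos(phi_end - phi_prev))
        sgn <- if (dphi >= 0) 1 else -1
        next_pt <- function(k) {
          phi <- phi_end + sgn * k * step / Rf
          c(cx + Rf * cos(phi), cy + Rf * sin(phi))
        }
      }
    }
    if (is.null(next_pt)) {
      tangent <- p - pts[max(1, n - 8), ]
      tangent <- tangent / sqrt(sum(tangent^2))
      next_pt <- function(k) p + k * step * tangent
    }
    ext <- NULL
    for (k in seq_len(ceiling(20 / step))) {
      q <- next_pt(k)
      if (q[1] < 1 || q[1] > ncol(fused) || q[2] < 1 || q[2] > nrow(fused)) break
      if (bilinear_at(fmat, q[1], q[2]) < 0.5) break
      ext <- rbind(ext, q)
    }
    if (is.null(ext)) pts else rbind(pts, unname(ext))
  }
  out <- extend(out)
  out <- extend(out[rev(seq_len(nrow(out))), , drop = FALSE])
  out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  colnames(out) <- c("x", "y")
  if (!is.null(orient_to)) {
    d_start <- sum((out[1, ] - orient_to)^2)
    d_end <- sum((out[nrow(out), ] - orient_to)^2)
    if (d_end < d_start) out <- out[rev(seq_len(nrow(out))), ]
  }
  out
}

# Bilinear interpolation of a matrix at sub-pixel (x, y) positions
# (1-based pixel-centre coordinates).
bilinear_at <- function(m, x, y) {
  H <- nrow(m); W <- ncol(m)
  x <- pmin(pmax(x, 1), W)
  y <- pmin(pmax(y, 1), H)
  x0 <- pmin(floor(x), W - 1L); y0 <- pmin(floor(y), H - 1L)
  fx <- x - x0; fy <- y - y0
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    m[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# Longest run of TRUE in a logical vector; NULL if none.
longest_run <- function(v) {
  r <- rle(v)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  k <- runs[which.max(r$lengths[runs])]
  c(starts[k], ends[k])
}

# Sub-pixel 0.5-level crossing of bone membership values along the curve,
# between samples i (inside) and j (outside).
crossing_point <- function(curve, vals, i, j) {
  if (j < 1 || j > nrow(curve)) return(curve[i, ])
  vi <- vals[i]; vj <- vals[j]
  t <- if (vi == vj) 0.5 else (vi - 0.5) / (vi - vj)
  curve[i, ] + t * (curve[j, ] - curve[i, ])
}

#' SL and LT gap widths along the centerline
#'
#' Walks the carpal-arc centerline through the per-bone masks: the SL gap is
#' the Euclidean distance between the point where the curve leaves the
#' scaphoid (its ulnar cortex) and the point where it enters the lunate
#' (radial cortex); the LT gap is the analogous lunate-triquetrum distance.
#' Cortex crossings are located at sub-pixel precision by bilinear
#' interpolation of the binary masks along the curve.
#'
#' @param centerline polyline from [carpal_centerline()].
#' @param mask integer label mask (scaphoid 3, lunate 4, triquetrum 5).
#' @param spacing_mm pixel size of `mask` in mm/px.
#' @param smooth_sigma SD (pixels) of the Gaussian applied to each binary
#'   bone mask before locating the 0.5-level cortex crossings; the smoothed
#'   coverage field localizes the rasterized cortex with sub-pixel accuracy
#'   (default 1.3, 0 disables).
#' @return list with `sl_mm`, `lt_mm` (NA when invalid) and logical
#'   `valid_sl`, `valid_lt`.
#' @export
gap_widths <- function(centerline, mask, spacing_mm, smooth_sigma = 1.3) {
  runs <- list()
  vals <- list()
  for (cl in PROXIMAL_ROW) {
    b <- (mask == cl) + 0
    dim(b) <- dim(mask)
    if (smooth_sigma > 0) b <- gauss_smooth(b, smooth_sigma)
    v <- bilinear_at(b, centerline[, 1], centerline[, 2])
    vals[[as.character(cl)]] <- v
    runs[[as.character(cl)]] <- longest_run(v >= 0.5)
  }
  res <- list(sl_mm = NA_real_, lt_mm = NA_real_,
              valid_sl = FALSE, valid_lt = FALSE)
  sc <- runs[["3"]]; lu <- runs[["4"]]; tq <- runs[["5"]]
  # orient radial -> ulnar: the scaphoid must come first
  if (!is.null(sc) && !is.null(tq) && sc[1] > tq[1]) {
    n <- nrow(centerline)
    centerline <- centerline[rev(seq_len(n)), , drop = FALSE]
    vals <- lapply(vals, rev)
    flip <- function(r) if (is.null(r)) NULL else c(n - r[2] + 1L, n - r[1] + 1L)
    sc <- flip(sc); lu <- flip(lu); tq <- flip(tq)
  }
  if (!is.null(sc) && !is.null(lu) && sc[2] < lu[1]) {
    p_exit <- crossing_point(centerline, vals[["3"]], sc[2], sc[2] + 1L)
    p_entry <- crossing_point(centerline, vals[["4"]], lu[1], lu[1] - 1L)
    res$sl_mm <- sqrt(sum((p_exit - p_entry)^2)) * spacing_mm
    res$valid_sl <- TRUE
  }
  if (!is.null(lu) && !is.null(tq) && lu[2] < tq[1]) {
    p_exit <- crossing_point(centerline, vals[["4"]], lu[2], lu[2] + 1L)
    p_entry <- crossing_point(centerline, vals[["5"]], tq[1], tq[1] - 1L)
    res$lt_mm <- sqrt(sum((p_exit - p_entry)^2)) * spacing_mm
    res$valid_lt <- TRUE
  }
  if (!is.null(sc) && !is.null(lu) && sc[2] >= lu[1] && sc[1] <= lu[2]) {
    # overlapping runs cannot happen for disjoint masks; bones touching
    # along the curve give coincident crossings and a zero gap
    res$sl_mm <- 0; res$valid_sl <- TRUE
  }
  if (!is.null(lu) && !is.null(tq) && lu[2] >= tq[1] && lu[1] <= tq[2]) {
    res$lt_mm <- 0; res$valid_lt <- TRUE
  }
  res
}

#' Wrist angle from bounding boxes
#'
#' Computes the minimum-area (rotated) bounding rectangles of the forearm
#' group (radius + ulna) and of the distal carpal row (hamate + capitate +
#' trapezium/trapezoid). The wrist angle is the signed angle between the
#' vector joining the two box centres and the long axis of the forearm box;
#' deviation towards the radius side is negative, towards the ulna side
#' positive (the sides are identified from the radius and ulna centroids).
#'
#' @param mask integer label mask.
#' @return list with `angle_deg` (NA when invalid) and `valid`.
#' @export
wrist_angle <- function(mask) {
  fa <- mask_points(mask, FOREARM)
  dr <- mask_points(mask, DISTAL_ROW)
  rad <- mask_points(mask, 1L)
  uln <- mask_points(mask, 2L)
  if (nrow(fa) < 3 || nrow(dr) < 3 || nrow(rad) == 0 || nrow(uln) == 0) {
    return(list(angle_deg = NA_real_, valid = FALSE))
  }
  bf <- min_area_rect(fa)
  bd <- min_area_rect(dr)
  d <- bd$centre - bf$centre
  u <- bf$long_axis
  if (sum(u * d) < 0) u <- -u
  n <- c(-u[2], u[1])
  w_radial <- colMeans(rad) - colMeans(uln)
  if (sum(n * w_radial) > 0) n <- -n # make n point to the ulnar side
  ang <- atan2(sum(d * n), sum(d * u)) * 180 / pi
  list(angle_deg = ang, valid = TRUE)
}

#' Per-frame wrist metrics for a mask sequence
#'
#' Fuses the proximal row, extracts the carpal-arc centerline, measures the
#' SL and LT gap widths and the bounding-box wrist angle for every frame.
#' Frames on which a step fails are flagged invalid, never dropped.
#'
#' @param masks list of integer label masks or 3D array `[H, W, T]`.
#' @param spacing_mm pixel size of the masks in mm/px.
#' @param frame_interval_ms optional frame interval to fill `time_ms`.
#' @param close_radius_px passed to [fuse_proximal_row()].
#' @return data.frame: frame, time_ms, wrist_angle_deg, sl_gap_mm,
#'   lt_gap_mm, valid_sl, valid_lt, valid_angle.
#' @export
quantify_sequence <- function(masks, spacing_mm, frame_interval_ms = NA_real_,
                              close_radius_px = 5L) {
  if (!is.list(masks)) {
    masks <- lapply(seq_len(dim(masks)[3]), function(t) masks[, , t])
  }
  rows <- lapply(seq_along(masks), function(k) {
    m <- masks[[k]]
    g <- list(sl_mm = NA_real_, lt_mm = NA_real_,
              valid_sl = FALSE, valid_lt = FALSE)
    have_all <- all(PROXIMAL_ROW %in% unique(as.integer(m)))
    if (have_all) {
      g <- tryCatch({
        fused <- fuse_proximal_row(m, close_radius_px = close_radius_px)
        sc <- mask_points(m, 3L)
        cl <- carpal_centerline(fused, orient_to = colMeans(sc))
        gap_widths(cl, m, spacing_mm)
      }, carpo_error = function(e) g)
    }
    a <- wrist_angle(m)
    data.frame(frame = k,
               time_ms = if (is.na(frame_interval_ms)) NA_real_ else
                 (k - 1) * frame_interval_ms,
               wrist_angle_deg = a$angle_deg,
               sl_gap_mm = g$sl_mm, lt_gap_mm = g$lt_mm,
               valid_sl = g$valid_sl, valid_lt = g$valid_lt,
               valid_angle = a$valid)
  })
  do.call(rbind, rows)
}

#' Angle-binned gap-width summaries
#'
#' Groups the per-frame SL and LT gap widths into wrist-angle bins of
#' `bin_deg` degrees (aligned to multiples of the bin width) and reports the
#' per-bin mean and SD. Empty bins are omitted.
#'
#' @param metrics data.frame from [quantify_sequence()] (or any frame with
#'   columns `wrist_angle_deg`, `sl_gap_mm`, `lt_gap_mm`).
#' @param bin_deg bin width in degrees (default 5).
#' @return data.frame: bin_centre_deg, n, sl_mean_mm, sl_sd_mm, lt_mean_mm,
#'   lt_sd_mm.
#' @export
bin_by_angle <- function(metrics, bin_deg = 5) {
  ok <- is.finite(metrics$wrist_angle_deg)
  m <- metrics[ok, , drop = FALSE]
  if (nrow(m) == 0) stop("no frames with a valid wrist angle")
  lo <- floor(min(m$wrist_angle_deg) / bin_deg) * bin_deg
  hi <- ceiling(max(m$wrist_angle_deg) / bin_deg) * bin_deg
  if (hi == lo) hi <- lo + bin_deg
  breaks <- seq(lo, hi, by = bin_deg)
  bin <- cut(m$wrist_angle_deg, breaks = breaks, include.lowest = TRUE,
             right = FALSE)
  agg <- function(v) {
    mean_v <- tapply(v, bin, function(z) mean(z, na.rm = TRUE))
    sd_v <- tapply(v, bin, function(z) sd(z, na.rm = TRUE))
    list(mean = mean_v, sd = sd_v)
  }
  sl <- agg(m$sl_gap_mm)
  lt <- agg(m$lt_gap_mm)
  n <- tapply(rep(1, nrow(m)), bin, sum)
  centres <- breaks[-length(breaks)] + bin_deg / 2
  keep <- !is.na(n)
  data.frame(bin_centre_deg = centres[keep],
             n = as.integer(n[keep]),
             sl_mean_mm = as.numeric(sl$mean[keep]),
             sl_sd_mm = as.numeric(sl$sd[keep]),
             lt_mean_mm = as.numeric(lt$mean[keep]),
             lt_sd_mm = as.numeric(lt$sd[keep]))
}
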