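test_that("proximal-row fusion bridges gaps into one region", {
  m <- two_block_mask()
  m[10:20, 35:39] <- 5L # 4 px gap to the lunate block
  fused <- fuse_proximal_row(m, close_radius_px = 3)
  expect_equal(max(EBImage::bwlabel(fused)), 1)
  expect_gte(sum(fused), sum(m > 0))
  # two rectangles 3 px apart bridged by a radius-2 disc
  m2 <- matrix(0L, 30, 30)
  m2[10:20, 5:12] <- 3L
  m2[10:20, 16:25] <- 4L
  fused2 <- fuse_proximal_row(m2, close_radius_px = 2)
  expect_equal(max(EBImage::bwlabel(fused2)), 1)
  # fewer than two proximal bones present -> fusion error
  m3 <- matrix(0L, 20, 20)
  m3[5:10, 5:10] <- 4L
  expect_error(fuse_proximal_row(m3), class = "carpo_fusion_error")
  # far-apart bones cannot be bridged
  m4 <- matrix(0L, 90, 90)
  m4[5:10, 5:10] <- 3L
  m4[80:85, 80:85] <- 4L
  expect_error(fuse_proximal_row(m4, close_radius_px = 2, max_radius_px = 4),
               class = "carpo_fusion_error")
})

test_that("the centerline of a rectangle is its midline", {
  m <- matrix(0L, 40, 80)
  m[16:25, 11:70] <- 1L
  cl <- carpal_centerline(m)
  len <- sum(sqrt(rowSums(diff(cl)^2)))
  expect_lt(abs(len - 60), 2)
  expect_true(all(abs(cl[, 2] - 20.5) <= 1))
})

test_that("the centerline of an annulus sector follows the mid-radius", {
  H <- 80; W <- 80
  yy <- outer(1:H, rep(1, W))
  xx <- outer(rep(1, H), 1:W)
  r <- sqrt((xx - 40)^2 + (yy - 70)^2)
  a <- atan2(-(yy - 70), xx - 40) * 180 / pi
  ann <- (r >= 20 & r <= 30 & a >= 30 & a <= 150) + 0L
  cl <- carpal_centerline(ann)
  n <- nrow(cl)
  mid <- cl[round(n * 0.1):round(n * 0.9), ] # sector ends have no mid-radius
  radii <- sqrt((mid[, 1] - 40)^2 + (mid[, 2] - 70)^2)
  expect_true(all(abs(radii - 25) <= 1))
})

test_that("centerline orientation follows the requested starting end", {
  m <- matrix(0L, 40, 80)
  m[16:25, 11:70] <- 1L
  left_first <- carpal_centerline(m, orient_to = c(11, 20))
  right_first <- carpal_centerline(m, orient_to = c(70, 20))
  expect_lt(left_first[1, 1], left_first[nrow(left_first), 1])
  expect_gt(right_first[1, 1], right_first[nrow(right_first), 1])
  expect_error(carpal_centerline(matrix(0L, 10, 10)),
               class = "carpo_centerline_error")
})

test_that("gap widths scale with pixel spacing and vanish for touching bones", {
  m <- matrix(0L, 40, 60)
  m[16:25, 5:20] <- 3L
  m[16:25, 25:40] <- 4L # 4 px gap
  m[16:25, 41:55] <- 5L # touching the lunate
  fused <- fuse_proximal_row(m, close_radius_px = 3)
  cl <- carpal_centerline(fused, orient_to = c(5, 20))
  g1 <- gap_widths(cl, m, spacing_mm = 1)
  g2 <- gap_widths(cl, m, spacing_mm = 2)
  expect_true(g1$valid_sl && g1$valid_lt)
  expect_equal(g2$sl_mm, 2 * g1$sl_mm, tolerance = 1e-9)
  expect_lt(abs(g1$sl_mm - 4), 1)
  expect_lt(g1$lt_mm, 0.6) # adjacent blocks: near-zero gap
})

test_that("gaps and angle recover phantom truth across the sweep", {
  ph <- phantom_small()
  met <- quantify_sequence(ph$truth$masks, ph$truth$mask_spacing_mm,
                           frame_interval_ms = 200)
  expect_true(all(met$valid_sl & met$valid_lt & met$valid_angle))
  expect_lt(max(abs(met$sl_gap_mm - ph$truth$sl_mm)), 0.5)
  expect_lt(max(abs(met$lt_gap_mm - ph$truth$lt_mm)), 0.5)
  expect_lt(max(abs(met$wrist_angle_deg - ph$truth$angle_deg)), 2)
  expect_equal(met$time_ms, (seq_len(nrow(met)) - 1) * 200)
})

test_that("gap measurement is invariant under exact rotation", {
  ph <- phantom_small()
  k <- 6
  mk <- ph$truth$masks[, , k]
  measure <- function(m) {
    fused <- fuse_proximal_row(m)
    cl <- carpal_centerline(fused,
                            orient_to = colMeans(carpo:::mask_points(m, 3L)))
    gap_widths(cl, m, ph$truth$mask_spacing_mm)
  }
  g0 <- measure(mk)
  rot90 <- t(mk)[, rev(seq_len(nrow(mk)))] # exact 90 degree rotation
  g1 <- measure(rot90)
  expect_lt(abs(g0$sl_mm - g1$sl_mm), 0.2)
  expect_lt(abs(g0$lt_mm - g1$lt_mm), 0.2)
})

test_that("bounding-box wrist angle matches analytic poses and symmetry", {
  for (th in c(-20, -10, 0, 12, 25)) {
    w <- wrist_angle(analytic_pose_mask(th))
    expect_true(w$valid)
    expect_angle_equal(w$angle_deg, th, 2)
  }
  # mirroring about the forearm axis negates the angle
  m <- analytic_pose_mask(15)
  mm <- m[, rev(seq_len(ncol(m)))]
  # mirroring swaps the radius/ulna sides; relabel to keep anatomy valid
  mm2 <- mm
  mm2[mm == 1L] <- 2L
  mm2[mm == 2L] <- 1L
  w <- wrist_angle(m)
  wm <- wrist_angle(mm2)
  expect_equal(wm$angle_deg, -w$angle_deg, tolerance = 1e-6)
  # missing group -> invalid
  m0 <- analytic_pose_mask(0)
  m0[m0 %in% c(6L, 7L, 8L)] <- 0L
  expect_false(wrist_angle(m0)$valid)
})

test_that("quantification flags invalid frames instead of dropping them", {
  blank <- array(0L, dim = c(20, 20, 3))
  met <- quantify_sequence(blank, 0.5)
  expect_equal(nrow(met), 3)
  expect_true(all(!met$valid_sl & !met$valid_lt & !met$valid_angle))
  expect_true(all(is.na(met$sl_gap_mm)))
})

test_that("angle binning matches a brute-force group-by", {
  set.seed(17)
  n <- 200
  metrics <- data.frame(
    wrist_angle_deg = runif(n, -15, 35),
    sl_gap_mm = rnorm(n, 1.7, 0.1),
    lt_gap_mm = rnorm(n, 1.3, 0.1)
  )
  b <- bin_by_angle(metrics, bin_deg = 5)
  expect_equal(nrow(b), 10)
  oracle_bin <- floor(metrics$wrist_angle_deg / 5) * 5 + 2.5
  for (r in seq_len(nrow(b))) {
    sel <- oracle_bin == b$bin_centre_deg[r]
    expect_equal(b$n[r], sum(sel))
    expect_equal(b$sl_mean_mm[r], mean(metrics$sl_gap_mm[sel]))
    expect_equal(b$lt_sd_mm[r], sd(metrics$lt_gap_mm[sel]))
  }
  # constant gaps: every bin mean equals the constant with zero SD
  const <- data.frame(wrist_angle_deg = seq(-14, 34, by = 1),
                      sl_gap_mm = 1.5, lt_gap_mm = 1.0)
  bc <- bin_by_angle(const)
  expect_true(all(bc$sl_mean_mm == 1.5))
  expect_true(all(bc$sl_sd_mm == 0))
})
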