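test_that("CRF with zero pairwise weights is the identity", {
  set.seed(1)
  sc <- softmax_scores(array(rnorm(8 * 8 * 4), dim = c(8, 8, 4)))
  dim(sc) <- c(8, 8, 4)
  img <- matrix(rnorm(64), 8)
  cfg <- crf_config(iterations = 3, w_appearance = 0, w_smoothness = 0)
  out <- crf_refine(sc, img, cfg)
  expect_equal(out, sc, tolerance = 1e-9)
  expect_error(crf_refine(sc * 2, img, cfg), "normalized")
})

test_that("one mean-field iteration matches a dense brute-force oracle", {
  set.seed(7)
  H <- 10; W <- 10; C <- 3
  img <- matrix(rnorm(H * W), H, W)
  Q0 <- softmax_scores(array(rnorm(H * W * C), dim = c(H, W, C)))
  dim(Q0) <- c(H, W, C)
  cfg <- crf_config(iterations = 1, appearance_sd_px = 2,
                    appearance_sd_intensity = 0.8, smoothness_sd_px = 1.5,
                    w_appearance = 2, w_smoothness = 1)
  # oracle: explicit loop over all pixel pairs with the truncated kernels
  kmass <- function(sd, r) {
    off <- -r:r
    sum(exp(-outer(off^2, off^2, "+") / (2 * sd^2))) - 1
  }
  r_app <- ceiling(2 * cfg$appearance_sd_px)
  r_sm <- ceiling(2 * cfg$smoothness_sd_px)
  wa_n <- cfg$w_appearance / kmass(cfg$appearance_sd_px, r_app)
  ws_n <- cfg$w_smoothness / kmass(cfg$smoothness_sd_px, r_sm)
  U <- -log(pmax(Q0, 1e-12))
  msg <- array(0, dim = c(H, W, C))
  for (i in 1:H) for (j in 1:W) for (ii in 1:H) for (jj in 1:W) {
    if (i == ii && j == jj) next
    d2 <- (i - ii)^2 + (j - jj)^2
    wa <- 0
    if (abs(i - ii) <= r_app && abs(j - jj) <= r_app) {
      wa <- exp(-d2 / (2 * cfg$appearance_sd_px^2) -
                  (img[i, j] - img[ii, jj])^2 /
                  (2 * cfg$appearance_sd_intensity^2))
      if (wa < 1e-12) wa <- 0
    }
    ws <- 0
    if (abs(i - ii) <= r_sm && abs(j - jj) <= r_sm) {
      ws <- exp(-d2 / (2 * cfg$smoothness_sd_px^2))
      if (ws < 1e-12) ws <- 0
    }
    msg[i, j, ] <- msg[i, j, ] + (wa_n * wa + ws_n * ws) * Q0[ii, jj, ]
  }
  pen <- array(apply(msg, c(1, 2), sum), dim = c(H, W, C)) - msg
  lq <- -U - pen
  ref <- exp(lq - array(apply(lq, c(1, 2), max), dim = c(H, W, C)))
  ref <- ref / array(apply(ref, c(1, 2), sum), dim = c(H, W, C))
  out <- crf_refine(Q0, img, cfg)
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("an isolated label island in uniform intensity is absorbed", {
  sc <- array(0, dim = c(9, 9, 3))
  sc[, , 2] <- 0.9
  sc[, , 1] <- 0.05
  sc[, , 3] <- 0.05
  sc[5, 5, ] <- c(0.05, 0.05, 0.9)
  out <- crf_refine(sc, matrix(1, 9, 9),
                    crf_config(iterations = 2, appearance_sd_px = 2,
                               smoothness_sd_px = 1.5))
  expect_equal(labels_from_scores(out)[5, 5], 1L)
  sums <- rowSums(matrix(out, 81, 3))
  expect_equal(sums, rep(1, 81), tolerance = 1e-9)
})

test_that("temporal weights are symmetric, centre-peaked, and sum to 5", {
  cfg <- temporal_config()
  expect_equal(sum(cfg$weights), 5)
  expect_equal(unname(cfg$weights[1]), unname(cfg$weights[5]))
  expect_equal(unname(cfg$weights[2]), unname(cfg$weights[4]))
  expect_equal(unname(which.max(cfg$weights)), 3L)
  expect_equal(cfg$window, 5L)
})

test_that("temporal stabilization keeps persistent pixels, drops flicker", {
  cfg <- temporal_config()
  base <- matrix(0L, 6, 6)
  base[2:4, 2:4] <- 3L
  seq5 <- replicate(5, base, simplify = FALSE)
  out <- temporal_stabilize(seq5, cfg)
  # persistent pixels: cumulative allocation 5, mean 1 >= 0.6
  expect_identical(out[[3]], base)
  # never-assigned pixels stay background
  expect_true(all(out[[3]][base == 0] == 0L))
  # a centre-frame-only flicker has mean w0/5 < 0.6 and is removed
  flick <- seq5
  flick[[3]][6, 6] <- 5L
  out2 <- temporal_stabilize(flick, cfg)
  expect_equal(out2[[3]][6, 6], 0L)
  expect_lt(unname(cfg$weights["0"]) / 5, 0.6)
  # a single-frame dropout is filled back in, not turned into a hole
  drop1 <- seq5
  drop1[[3]][3, 3] <- 0L
  out3 <- temporal_stabilize(drop1, cfg)
  expect_equal(out3[[3]][3, 3], 3L)
})

test_that("temporal voting equals a direct weighted-sum oracle", {
  set.seed(11)
  cfg <- temporal_config()
  H <- 5; W <- 4; TT <- 9
  arr <- array(sample(0:3, H * W * TT, TRUE), dim = c(H, W, TT))
  out <- temporal_stabilize(arr, cfg)
  for (t in c(1, 2, 5, 9)) {
    for (i in 1:H) for (j in 1:W) {
      best <- 0L; best_mean <- 0
      for (cl in 1:3) {
        num <- 0; den_w <- 0; len <- 0
        for (k in -2:2) {
          if (t + k >= 1 && t + k <= TT) {
            w <- cfg$weights[as.character(k)]
            num <- num + w * (arr[i, j, t + k] == cl)
            den_w <- den_w + w
            len <- len + 1
          }
        }
        m <- num / den_w # truncated-window renormalization
        if (m >= cfg$tau && m > best_mean) { best <- cl; best_mean <- m }
      }
      expect_equal(out[i, j, t], best)
    }
  }
})

test_that("temporal stage is translation-equivariant in time", {
  set.seed(12)
  arr <- array(sample(0:2, 4 * 4 * 12, TRUE), dim = c(4, 4, 12))
  out <- temporal_stabilize(arr)
  shifted <- temporal_stabilize(arr[, , 3:12])
  # interior frames (away from both boundaries) agree under the shift
  expect_identical(out[, , 5:10], shifted[, , 3:8])
})

test_that("single-frame sequences reduce to centre-weight thresholding", {
  m <- matrix(c(0L, 2L, 2L, 0L), 2, 2)
  out <- temporal_stabilize(list(m))
  expect_identical(out[[1]], m)
})

test_that("stabilization reverts isolated single-frame flips", {
  ph <- phantom_slow()
  masks <- lapply(41:80, function(t) ph$truth$masks[, , t])
  set.seed(31)
  flicked <- masks
  n_flip <- 0
  flips <- list()
  for (t in 3:(length(masks) - 2)) {
    idx <- sample(length(masks[[t]]), round(0.01 * length(masks[[t]])))
    old <- flicked[[t]][idx]
    flicked[[t]][idx] <- (old + sample(1:8, length(idx), TRUE)) %% 9L
    flips[[t]] <- idx
    n_flip <- n_flip + length(idx)
  }
  out <- temporal_stabilize(flicked)
  reverted <- 0
  for (t in 3:(length(masks) - 2)) {
    idx <- flips[[t]]
    reverted <- reverted + sum(out[[t]][idx] == masks[[t]][idx])
  }
  expect_gte(reverted / n_flip, 0.95)
})

test_that("morphological cleanup smooths, fills, and keeps one component", {
  # idempotent on shapes whose corners admit the cross element
  disc <- matrix(0L, 20, 20)
  disc[(row(disc) - 10)^2 + (col(disc) - 10)^2 <= 36] <- 2L
  expect_identical(morphological_cleanup(disc), disc)
  # on a sharp-cornered square, opening clips exactly the four corners
  sq <- matrix(0L, 20, 20)
  sq[5:14, 5:14] <- 2L
  sq_open <- sq
  sq_open[cbind(c(5, 5, 14, 14), c(5, 14, 5, 14))] <- 0L
  expect_identical(morphological_cleanup(sq), sq_open)
  speck <- sq
  speck[18, 18] <- 2L
  expect_identical(morphological_cleanup(speck), sq_open)
  holed <- disc
  holed[9, 9] <- 0L
  expect_identical(morphological_cleanup(holed), disc)
  # multi-class: exactly one 4-connected component per class survives
  m <- matrix(0L, 30, 30)
  m[3:10, 3:10] <- 1L
  m[3:5, 20:22] <- 1L
  m[15:25, 12:20] <- 5L
  m[28, 28] <- 5L
  out <- morphological_cleanup(m)
  for (cl in c(1L, 5L)) {
    expect_equal(max(EBImage::bwlabel((out == cl) + 0)), 1)
  }
})

test_that("pipeline composition honours stage toggles and alignment", {
  set.seed(13)
  scores <- lapply(1:4, function(t) {
    s <- softmax_scores(array(rnorm(16 * 16 * 4, sd = 3), dim = c(16, 16, 4)))
    array(s, dim = c(16, 16, 4))
  })
  frames <- lapply(1:4, function(t) matrix(rnorm(256), 16))
  expect_error(run_postprocess(scores, frames[1:2]), "per score")
  bypass <- run_postprocess(scores, frames, crf = FALSE, temporal = FALSE)
  direct <- lapply(lapply(scores, labels_from_scores), morphological_cleanup)
  expect_identical(bypass, direct)
  full <- run_postprocess(scores, frames,
                          crf_cfg = crf_config(iterations = 2,
                                               appearance_sd_px = 2))
  expect_equal(length(full), 4)
  rerun <- run_postprocess(scores, frames,
                           crf_cfg = crf_config(iterations = 2,
                                                appearance_sd_px = 2))
  expect_identical(full, rerun) # purity
})
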