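test_that("network output is shape-preserving with 9 score channels", {
  toy <- build_unet(unet_spec(depth = 1, base_channels = 4), seed = 1)
  x <- array(rnorm(64), dim = c(8, 8, 1, 1))
  out <- unet_forward(toy, x)
  expect_equal(dim(out$logits), c(8, 8, 9, 1))
  # full-resolution frame: 336 x 336 in, 336 x 336 x 9 out
  red <- build_unet(unet_spec(depth = 2, base_channels = 4), seed = 1)
  big <- array(rnorm(336^2), dim = c(336, 336, 1, 1))
  expect_equal(dim(unet_forward(red, big)$logits), c(336, 336, 9, 1))
  expect_error(unet_forward(toy, array(0, dim = c(9, 9, 1, 1))), "divisible")
})

test_that("default architecture ends in 64 feature channels before the head", {
  spec <- unet_spec()
  expect_equal(spec$base_channels, 64L)
  expect_equal(spec$out_channels, 9L)
  m <- build_unet(unet_spec(depth = 1, base_channels = 64), seed = 1)
  expect_equal(dim(m$params$head_w), c(64L, 9L))
})

test_that("parameter count equals the hand-computed layer sum", {
  spec <- unet_spec(depth = 1, base_channels = 4, n_classes = 2,
                    in_channels = 1)
  m <- build_unet(spec, seed = 1)
  conv_p <- function(cin, cout) 9 * cin * cout + cout + 2 * cout # w + b + bn
  expected <- conv_p(1, 4) + conv_p(4, 4) +      # encoder level
    conv_p(4, 8) + conv_p(8, 8) +                # bottleneck
    2 * 2 * 8 * 4 +                              # upconv
    conv_p(8, 4) + conv_p(4, 4) +                # decoder level
    4 * 3 + 3                                    # 1x1 head
  expect_equal(n_params(m), expected)
})

test_that("soft Dice loss reproduces closed-form values", {
  tgt <- matrix(1L, 6, 6)
  onehot <- array(0, dim = c(6, 6, 9))
  onehot[, , 2] <- 1
  expect_lt(dice_loss(onehot, tgt), 1e-5)
  uniform <- array(1 / 9, dim = c(6, 6, 9))
  expect_equal(dice_loss(uniform, tgt), 1 - 2 * (1 / 9) / (1 / 9 + 1),
               tolerance = 1e-6)
  disjoint <- array(0, dim = c(6, 6, 9))
  disjoint[, , 3] <- 1 # predicts class 2 everywhere, target is class 1
  expect_gt(dice_loss(disjoint, tgt), 1 - 1e-5)
})

test_that("Hausdorff surrogate weights errors by squared distance", {
  tgt <- matrix(0L, 16, 16)
  tgt[6:10, 6:10] <- 1L
  perfect <- array(0, dim = c(16, 16, 9))
  perfect[, , 1] <- 1
  perfect[6:10, 6:10, 1] <- 0
  perfect[6:10, 6:10, 2] <- 1
  expect_equal(hausdorff_loss(perfect, tgt), 0)
  add_fp <- function(i, j) {
    p <- perfect
    p[i, j, 1] <- 0
    p[i, j, 2] <- 1
    p
  }
  l_near <- hausdorff_loss(add_fp(11, 8), tgt)  # distance 1 from the block
  l_far <- hausdorff_loss(add_fp(14, 8), tgt)   # distance 4
  expect_equal(l_far / l_near, 16, tolerance = 1e-6)
  # moving a false positive farther never decreases the loss
  ds <- vapply(11:16, function(i) hausdorff_loss(add_fp(i, 8), tgt), numeric(1))
  expect_true(all(diff(ds) >= 0))
})

test_that("combined loss vanishes only at the exact one-hot target", {
  tgt <- matrix(0L, 8, 8)
  tgt[3:5, 3:5] <- 2L
  onehot <- array(0, dim = c(8, 8, 9))
  onehot[, , 1] <- 1
  onehot[3:5, 3:5, 1] <- 0
  onehot[3:5, 3:5, 3] <- 1
  expect_equal(seg_loss(onehot, tgt), 0)
  soft <- onehot * 0.9 + 0.1 / 9
  expect_gt(seg_loss(soft, tgt), 0)
})

test_that("softmax scores normalize and argmax matches a direct maximum", {
  set.seed(8)
  logits <- array(rnorm(10 * 12 * 9), dim = c(10, 12, 9))
  p <- softmax_scores(logits)
  sums <- apply(p, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, 120), tolerance = 1e-12)
  lab <- labels_from_scores(p)
  oracle <- matrix(0L, 10, 12)
  for (i in 1:10) for (j in 1:12) {
    oracle[i, j] <- which.max(logits[i, j, ]) - 1L
  }
  expect_identical(lab, oracle)
})

test_that("prediction is stateless across duplicate frames", {
  m <- build_unet(unet_spec(depth = 1, base_channels = 4), seed = 2)
  fr <- matrix(rnorm(16 * 16), 16)
  arr <- array(c(fr, fr, fr), dim = c(16, 16, 3))
  out <- predict_sequence(m, arr)
  expect_equal(length(out$masks), 3)
  expect_identical(out$masks[[1]], out$masks[[2]])
  expect_identical(out$scores[[1]], out$scores[[3]])
})

test_that("backpropagation matches a numerical directional derivative", {
  set.seed(3)
  spec <- unet_spec(depth = 2, base_channels = 3, n_classes = 2)
  model <- build_unet(spec, seed = 5)
  x <- array(rnorm(64), dim = c(8, 8, 1, 1))
  tgt <- matrix(sample(0:2, 64, TRUE), 8, 8)
  dice_grad <- function(pr) {
    d <- dim(pr)
    dt <- carpo:::.dice_terms(array(pr, d[1:3]), tgt, want_grad = TRUE)
    Pm <- matrix(pr, d[1] * d[2], d[3])
    dl <- Pm * (dt$dP - rowSums(dt$dP * Pm))
    list(loss = dt$loss, dlogits = array(dl, dim = d))
  }
  loss_of <- function(model) {
    fw <- unet_forward(model, x, train = TRUE)
    dice_grad(softmax_scores(fw$logits))$loss
  }
  fw <- unet_forward(model, x, train = TRUE)
  lg <- dice_grad(softmax_scores(fw$logits))
  gr <- unet_backward(fw$model, fw$cache, lg$dlogits)
  set.seed(9)
  dirs <- lapply(model$params, function(p) {
    array(rnorm(length(p)), dim = if (is.null(dim(p))) length(p) else dim(p))
  })
  eps <- 3e-5
  m2 <- model
  m3 <- model
  for (nm in names(model$params)) {
    m2$params[[nm]] <- m2$params[[nm]] + eps * dirs[[nm]]
    m3$params[[nm]] <- m3$params[[nm]] - eps * dirs[[nm]]
  }
  num <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
  ana <- sum(mapply(function(g, d) sum(g * d), gr[names(model$params)], dirs))
  expect_equal(ana, num, tolerance = 0.02)
})
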