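#' U-Net architecture specification
#'
#' A classic symmetric U-Net: each encoder level applies two 3x3
#' convolutions, each followed by batch normalization and a rectified linear
#' unit; downsampling is 2x2 max-pooling with stride 2; the decoder is
#' symmetric with 2x2 transposed convolutions and skip concatenations, and a
#' 1x1 convolution maps the final features (width `base_channels`) to the
#' class scores. The network scores `n_classes` foreground classes plus one
#' background channel with a per-pixel softmax, so every pixel carries a
#' label.
#'
#' @param depth number of pooling steps (encoder levels below the top);
#'   default 4, giving channel progression 64-128-256-512(-1024).
#' @param base_channels feature channels at the first level (default 64; the
#'   final feature width before the 1x1 head equals this).
#' @param n_classes number of foreground classes (default 8).
#' @param in_channels input channels (default 1).
#' @return object of class `carpo_unet_spec`.
#' @export
unet_spec <- function(depth = 4L, base_channels = 64L, n_classes = 8L,
                      in_channels = 1L) {
  stopifnot(depth >= 1, base_channels >= 1, n_classes >= 1, in_channels >= 1)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(n_classes) + 1L),
            class = "carpo_unet_spec")
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Build an untrained U-Net model
#'
#' Allocates He-initialized weights for the architecture described by `spec`.
#'
#' @param spec a [unet_spec()].
#' @param seed RNG seed for the weight initialization.
#' @return object of class `carpo_unet` with elements `spec`, `params`
#'   (named list of arrays) and `bn` (running batch-norm statistics).
#' @export
build_unet <- function(spec = unet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "carpo_unet_spec"))
  ch <- spec$base_channels * 2^(0:spec$depth)
  params <- list()
  bn <- list()
  add_conv <- function(name, cin, cout) {
    params[[paste0(name, "_w")]] <<- he_init(c(3, 3, cin, cout), 9 * cin)
    params[[paste0(name, "_b")]] <<- numeric(cout)
    params[[paste0(name, "_g")]] <<- rep(1, cout)
    params[[paste0(name, "_be")]] <<- numeric(cout)
    bn[[name]] <<- list(mean = numeric(cout), var = rep(1, cout))
  }
  with_seed(seed, {
    cin <- spec$in_channels
    for (l in seq_len(spec$depth)) {
      add_conv(sprintf("enc%d_c1", l), cin, ch[l])
      add_conv(sprintf("enc%d_c2", l), ch[l], ch[l])
      cin <- ch[l]
    }
    add_conv("bott_c1", cin, ch[spec$depth + 1])
    add_conv("bott_c2", ch[spec$depth + 1], ch[spec$depth + 1])
    for (l in rev(seq_len(spec$depth))) {
      params[[sprintf("up%d_w", l)]] <-
        he_init(c(2, 2, ch[l + 1], ch[l]), 4 * ch[l + 1])
      add_conv(sprintf("dec%d_c1", l), 2 * ch[l], ch[l])
      add_conv(sprintf("dec%d_c2", l), ch[l], ch[l])
    }
    params[["head_w"]] <- he_init(c(ch[1], spec$out_channels), ch[1])
    # bias the initial prediction towards background: with foreground-only
    # losses, a class that blankets the image at the start sees vanishing
    # Dice gradients, so training begins from an all-background state
    params[["head_b"]] <- c(2, numeric(spec$n_classes))
  })
  structure(list(spec = spec, params = params, bn = bn),
            class = "carpo_unet")
}

#' Number of trainable parameters of a model
#' @param model a `carpo_unet`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# ---- batch normalization ---------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_fwd <- function(x, g, be, state, train) {
  d <- dim(x)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dim(x) <- c(HW, C, N)
  if (train) {
    cm <- colMeans(x)                       # C x N
    mu <- if (N > 1) rowMeans(cm) else as.vector(cm)
    cm2 <- colMeans(x * x)
    vr <- (if (N > 1) rowMeans(cm2) else as.vector(cm2)) - mu^2
    state$mean <- BN_MOMENTUM * state$mean + (1 - BN_MOMENTUM) * mu
    state$var <- BN_MOMENTUM * state$var + (1 - BN_MOMENTUM) * vr
  } else {
    mu <- state$mean
    vr <- state$var
  }
  inv <- 1 / sqrt(vr + BN_EPS)
  s <- g * inv
  tshift <- be - s * mu
  y <- x * rep(s, each = HW) + rep(tshift, each = HW)
  dim(y) <- d
  list(y = y, state = state,
       cache = if (train) list(x = x, mu = mu, inv = inv, g = g, dims = d))
}

bn_bwd <- function(dy, cache) {
  d <- cache$dims
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  dim(dy) <- c(HW, C, N)
  xhat <- (cache$x - rep(cache$mu, each = HW)) * rep(cache$inv, each = HW)
  sum_c <- function(a) {
    cs <- colSums(a)
    if (N > 1) rowSums(cs) else as.vector(cs)
  }
  dbe <- sum_c(dy)
  dg <- sum_c(dy * xhat)
  n_eff <- HW * N
  dx <- rep(cache$g * cache$inv, each = HW) *
    (dy - rep(dbe / n_eff, each = HW) - xhat * rep(dg / n_eff, each = HW))
  dim(dx) <- d
  list(dx = dx, dg = dg, dbe = dbe)
}

# ---- forward / backward ----------------------------------------------------

conv_block_fwd <- function(x, model, name, train) {
  p <- model$params
  st <- model$bn
  z1 <- cpp_conv3_fwd(x, p[[paste0(name, "_c1_w")]], p[[paste0(name, "_c1_b")]])
  b1 <- bn_fwd(z1, p[[paste0(name, "_c1_g")]], p[[paste0(name, "_c1_be")]],
               st[[paste0(name, "_c1")]], train)
  a1 <- b1$y * (b1$y > 0)
  z2 <- cpp_conv3_fwd(a1, p[[paste0(name, "_c2_w")]], p[[paste0(name, "_c2_b")]])
  b2 <- bn_fwd(z2, p[[paste0(name, "_c2_g")]], p[[paste0(name, "_c2_be")]],
               st[[paste0(name, "_c2")]], train)
  a2 <- b2$y * (b2$y > 0)
  list(out = a2,
       bn_state = list(c1 = b1$state, c2 = b2$state),
       cache = list(x = x, bn1 = b1$cache, a1 = a1, bn2 = b2$cache, a2 = a2))
}

conv_block_bwd <- function(dout, model, name, cache, grads) {
  p <- model$params
  dz2 <- dout * (cache$a2 > 0)
  bb2 <- bn_bwd(dz2, cache$bn2)
  cw2 <- cpp_conv3_bwd(cache$a1, p[[paste0(name, "_c2_w")]], bb2$dx)
  dz1 <- cw2$dx * (cache$a1 > 0)
  bb1 <- bn_bwd(dz1, cache$bn1)
  cw1 <- cpp_conv3_bwd(cache$x, p[[paste0(name, "_c1_w")]], bb1$dx)
  grads[[paste0(name, "_c2_w")]] <- cw2$dw
  grads[[paste0(name, "_c2_b")]] <- cw2$db
  grads[[paste0(name, "_c2_g")]] <- bb2$dg
  grads[[paste0(name, "_c2_be")]] <- bb2$dbe
  grads[[paste0(name, "_c1_w")]] <- cw1$dw
  grads[[paste0(name, "_c1_b")]] <- cw1$db
  grads[[paste0(name, "_c1_g")]] <- bb1$dg
  grads[[paste0(name, "_c1_be")]] <- bb1$dbe
  list(dx = cw1$dx, grads = grads)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' U-Net forward pass
#'
#' @param model a `carpo_unet`.
#' @param x input array `[H, W, in_channels, N]`; `H` and `W` must be
#'   divisible by `2^depth`.
#' @param train logical; training mode uses batch statistics for
#'   normalization (and updates the running statistics), evaluation mode uses
#'   the running statistics.
#' @return list with `logits` (`[H, W, C, N]`, C = n_classes + 1), the
#'   possibly updated `model`, and (in training mode) a `cache` for
#'   [unet_backward()].
#' @export
unet_forward <- function(model, x, train = FALSE) {
  spec <- model$spec
  d <- dim(x)
  if (length(d) == 2) {
    dim(x) <- c(d, 1L, 1L)
    d <- dim(x)
  }
  if (d[1] %% 2^spec$depth != 0 || d[2] %% 2^spec$depth != 0) {
    stop(sprintf("input size %dx%d not divisible by 2^depth = %d",
                 d[1], d[2], 2^spec$depth))
  }
  cache <- list(enc = vector("list", spec$depth),
                pool = vector("list", spec$depth),
                dec = vector("list", spec$depth),
                up_in = vector("list", spec$depth))
  cur <- x
  for (l in seq_len(spec$depth)) {
    blk <- conv_block_fwd(cur, model, sprintf("enc%d", l), train)
    model$bn[[sprintf("enc%d_c1", l)]] <- blk$bn_state$c1
    model$bn[[sprintf("enc%d_c2", l)]] <- blk$bn_state$c2
    cache$enc[[l]] <- blk$cache
    pl <- cpp_maxpool2_fwd(blk$out)
    cache$pool[[l]] <- pl$idx
    cur <- pl$y
  }
  blk <- conv_block_fwd(cur, model, "bott", train)
  model$bn[["bott_c1"]] <- blk$bn_state$c1
  model$bn[["bott_c2"]] <- blk$bn_state$c2
  cache$bott <- blk$cache
  cur <- blk$out
  for (l in rev(seq_len(spec$depth))) {
    cache$up_in[[l]] <- cur
    up <- cpp_upconv2_fwd(cur, model$params[[sprintf("up%d_w", l)]])
    cat_in <- concat_ch(cache$enc[[l]]$a2, up)
    blk <- conv_block_fwd(cat_in, model, sprintf("dec%d", l), train)
    model$bn[[sprintf("dec%d_c1", l)]] <- blk$bn_state$c1
    model$bn[[sprintf("dec%d_c2", l)]] <- blk$bn_state$c2
    cache$dec[[l]] <- blk$cache
    cache$dec[[l]]$cat_in <- cat_in
    cur <- blk$out
  }
  # 1x1 head
  dd <- dim(cur)
  HW <- dd[1] * dd[2]
  N <- dd[4]
  logits <- array(0, dim = c(dd[1], dd[2], spec$out_channels, N))
  wh <- model$params$head_w
  bh <- model$params$head_b
  for (n in seq_len(N)) {
    xm <- cur[, , , n]
    dim(xm) <- c(HW, dd[3])
    ym <- xm %*% wh
    ym <- sweep(ym, 2, bh, "+")
    logits[, , , n] <- ym
  }
  cache$head_in <- cur
  list(logits = logits, model = model,
       cache = if (train) cache else NULL)
}

#' U-Net backward pass
#'
#' Backpropagates a gradient with respect to the logits through the network.
#'
#' @param model a `carpo_unet`.
#' @param cache forward cache from [unet_forward()] with `train = TRUE`.
#' @param dlogits gradient array congruent with the logits.
#' @return named list of parameter gradients.
#' @export
unet_backward <- function(model, cache, dlogits) {
  spec <- model$spec
  grads <- list()
  cur <- cache$head_in
  dd <- dim(cur)
  HW <- dd[1] * dd[2]
  N <- dd[4]
  dW <- matrix(0, dd[3], spec$out_channels)
  db <- numeric(spec$out_channels)
  dcur <- array(0, dim = dd)
  wh <- model$params$head_w
  for (n in seq_len(N)) {
    xm <- cur[, , , n]; dim(xm) <- c(HW, dd[3])
    dy <- dlogits[, , , n]; dim(dy) <- c(HW, spec$out_channels)
    dW <- dW + crossprod(xm, dy)
    db <- db + colSums(dy)
    dxm <- tcrossprod(dy, wh)
    dim(dxm) <- c(dd[1], dd[2], dd[3])
    dcur[, , , n] <- dxm
  }
  grads$head_w <- dW
  grads$head_b <- db
  # decoder, shallow to deep; collect skip gradients for the encoder sweep
  dskip <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    bb <- conv_block_bwd(dcur, model, sprintf("dec%d", l), cache$dec[[l]], grads)
    grads <- bb$grads
    dcat <- bb$dx
    c_enc <- dim(cache$enc[[l]]$a2)[3]
    dskip[[l]] <- dcat[, , seq_len(c_enc), , drop = FALSE]
    dup <- dcat[, , c_enc + seq_len(dim(dcat)[3] - c_enc), , drop = FALSE]
    ub <- cpp_upconv2_bwd(cache$up_in[[l]], model$params[[sprintf("up%d_w", l)]], dup)
    grads[[sprintf("up%d_w", l)]] <- ub$dw
    dcur <- ub$dx # gradient at the output of dec_{l+1} (or the bottleneck)
  }
  bbot <- conv_block_bwd(dcur, model, "bott", cache$bott, grads)
  grads <- bbot$grads
  dpool <- bbot$dx
  # encoder, deep to shallow
  for (l in rev(seq_len(spec$depth))) {
    dunpooled <- cpp_maxpool2_bwd(
      dpool, cache$pool[[l]],
      dim(cache$enc[[l]]$a2)[1], dim(cache$enc[[l]]$a2)[2]
    )
    denc <- dskip[[l]] + dunpooled
    be <- conv_block_bwd(denc, model, sprintf("enc%d", l), cache$enc[[l]], grads)
    grads <- be$grads
    dpool <- be$dx
  }
  grads
}

#' Per-pixel softmax over the class channel
#' @param logits array `[H, W, C, N]` (or `[H, W, C]`).
#' @return array of probabilities summing to 1 over the class channel.
#' @export
softmax_scores <- function(logits) {
  d <- dim(logits)
  if (length(d) == 3) d <- c(d, 1L)
  x <- logits
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  mx <- x[, 1, ]
  for (c in seq_len(d[3])[-1]) mx <- pmax(mx, x[, c, ])
  s <- 0
  for (c in seq_len(d[3])) {
    x[, c, ] <- exp(x[, c, ] - mx)
    s <- s + x[, c, ]
  }
  for (c in seq_len(d[3])) x[, c, ] <- x[, c, ] / s
  dim(x) <- dim(logits)
  x
}

#' Hard labels from class scores
#'
#' Per-pixel argmax over the class channel; channel 1 is background (label
#' 0), channel `c + 1` is class `c`.
#' @param scores array `[H, W, C]` of (soft or hard) class scores.
#' @return integer label matrix.
#' @export
labels_from_scores <- function(scores) {
  d <- dim(scores)
  m <- scores
  dim(m) <- c(d[1] * d[2], d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1], d[2])
}

#' Segment an image sequence frame by frame
#'
#' Runs the network independently on every (preprocessed) frame and returns
#' normalized per-class scores and argmax label masks. Temporal coupling is
#' deliberately left to the post-processing stage.
#'
#' @param model a trained `carpo_unet`.
#' @param seq a `carpo_sequence` or 3D array `[H, W, T]` of preprocessed
#'   frames.
#' @param batch_size frames per forward pass (default 4).
#' @return list with `scores` (list of `[H, W, C]` arrays) and `masks`
#'   (list of integer label matrices).
#' @export
predict_sequence <- function(model, seq, batch_size = 4L) {
  x <- if (inherits(seq, "carpo_sequence")) seq$data else seq
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  TT <- dim(x)[3]
  scores <- vector("list", TT)
  masks <- vector("list", TT)
  for (start in seq(1L, TT, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, TT)
    xb <- array(x[, , idx], dim = c(dim(x)[1], dim(x)[2], 1L, length(idx)))
    fw <- unet_forward(model, xb, train = FALSE)
    pr <- softmax_scores(fw$logits)
    for (k in seq_along(idx)) {
      sc <- pr[, , , k]
      dim(sc) <- dim(pr)[1:3]
      scores[[idx[k]]] <- sc
      masks[[idx[k]]] <- labels_from_scores(sc)
    }
  }
  list(scores = scores, masks = masks)
}
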