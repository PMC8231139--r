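#' Training configuration
#'
#' Defaults follow the full-scale training protocol: Adam with initial
#' learning rate 0.1, weight decay 1e-8, 500 epochs at batch size 4, and a
#' multi-step schedule multiplying the rate by `gamma = 0.1` at epochs 10,
#' 50, 100, 150 and 250. The initial rate of 0.1 is aggressive and is kept
#' for fidelity to that protocol; `lr = 1e-3` with no milestones is the
#' documented stable alternative for small CPU runs.
#'
#' @param lr initial learning rate (default 0.1).
#' @param weight_decay L2 weight decay (default 1e-8).
#' @param epochs training epochs (default 500).
#' @param batch_size samples per step (default 4).
#' @param milestones strictly increasing epochs (all `< epochs`) at which
#'   the learning rate is multiplied by `gamma`.
#' @param gamma multiplicative learning-rate decay (default 0.1).
#' @param seed RNG seed controlling shuffling and augmentation draws.
#' @param val_every validate (mean foreground Dice on `val_set`) every this
#'   many epochs (default 5); `0` disables intermediate validation.
#' @return object of class `carpo_train_config`.
#' @export
train_config <- function(lr = 0.1, weight_decay = 1e-8, epochs = 500L,
                         batch_size = 4L,
                         milestones = c(10L, 50L, 100L, 150L, 250L),
                         gamma = 0.1, seed = 1L, val_every = 5L) {
  stopifnot(lr > 0, weight_decay >= 0, epochs >= 0, batch_size >= 1,
            gamma > 0)
  if (length(milestones) &&
      (is.unsorted(milestones, strictly = TRUE) || any(milestones >= max(epochs, 1)))) {
    stop("milestones must be strictly increasing and smaller than epochs")
  }
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 milestones = as.integer(milestones), gamma = gamma,
                 seed = as.integer(seed), val_every = as.integer(val_every)),
            class = "carpo_train_config")
}

#' Learning rate at a given epoch under the multi-step schedule
#'
#' `lr * gamma^k` where `k` is the number of milestones at or before
#' `epoch`; the sequence is non-increasing and piecewise constant with drops
#' exactly at the milestones.
#' @param epoch epoch number (1-based, vectorized).
#' @param cfg a [train_config()].
#' @return learning rate(s).
#' @export
lr_at_epoch <- function(epoch, cfg) {
  k <- vapply(epoch, function(e) sum(cfg$milestones <= e), numeric(1))
  cfg$lr * cfg$gamma^k
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a U-Net on image/mask pairs
#'
#' Minimizes the summed Dice and Hausdorff-distance loss with Adam under the
#' multi-step learning-rate schedule. Augmentation, when configured, is
#' applied online (fresh draws every epoch) to image and mask jointly.
#'
#' @param train_set,val_set lists of samples, each a `list(image = matrix,
#'   mask = integer matrix)`; images are expected preprocessed (see
#'   [preprocess_frame()]). `val_set` may be empty.
#' @param spec a [unet_spec()]; ignored when `model` is supplied.
#' @param cfg a [train_config()].
#' @param augment_cfg optional [augment_config()] for online augmentation;
#'   `NULL` disables augmentation.
#' @param model optional pre-built `carpo_unet` to continue training.
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained `carpo_unet`) and `history`
#'   (data.frame: epoch, lr, train_loss, val_dice). With `epochs = 0` the
#'   untrained model and an empty history are returned.
#' @export
train_unet <- function(train_set, val_set = list(), spec = unet_spec(),
                       cfg = train_config(), augment_cfg = NULL,
                       model = NULL, verbose = FALSE) {
  stopifnot(length(train_set) > 0)
  if (is.null(model)) model <- build_unet(spec, seed = cfg$seed)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_dice = numeric())
  if (cfg$epochs == 0) {
    return(list(model = model, history = history))
  }
  opt <- adam_init(model$params)
  n <- length(train_set)
  # fixed targets (no augmentation): cache their distance transforms
  dt_cache <- if (is.null(augment_cfg)) {
    lapply(train_set, function(s) {
      .target_dt(s$mask, model$spec$out_channels)
    })
  }
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(epoch, cfg)
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        imgs <- vector("list", length(idx))
        tgts <- vector("list", length(idx))
        for (k in seq_along(idx)) {
          s <- train_set[[idx[k]]]
          if (!is.null(augment_cfg)) {
            a <- augment(s$image, s$mask, augment_cfg)
            imgs[[k]] <- a$frame
            tgts[[k]] <- a$mask
          } else {
            imgs[[k]] <- s$image
            tgts[[k]] <- s$mask
          }
        }
        H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
        xb <- array(0, dim = c(H, W, 1, length(idx)))
        for (k in seq_along(idx)) xb[, , 1, k] <- imgs[[k]]
        fw <- unet_forward(model, xb, train = TRUE)
        model <- fw$model
        probs <- softmax_scores(fw$logits)
        lg <- .batch_loss_grad(probs, tgts, dt_targets = dt_cache[idx])
        if (!is.finite(lg$loss)) {
          stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
        }
        grads <- unet_backward(model, fw$cache, lg$dlogits)
        up <- adam_step(model$params, grads, opt, lr, cfg$weight_decay)
        model$params <- up$params
        opt <- up$state
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1
      }
      val_dice <- NA_real_
      if (length(val_set) &&
          ((cfg$val_every > 0 && epoch %% cfg$val_every == 0) ||
           epoch == cfg$epochs)) {
        val_dice <- validate_dice(model, val_set)
      }
      history[nrow(history) + 1L, ] <-
        list(epoch, lr, ep_loss / nb, val_dice)
      if (verbose) {
        message(sprintf("epoch %3d lr %.2g loss %.4f val dice %s",
                        epoch, lr, ep_loss / nb,
                        ifelse(is.na(val_dice), "-", sprintf("%.3f", val_dice))))
      }
    }
  })
  list(model = model, history = history)
}

# Mean foreground Dice of a model over a sample list.
validate_dice <- function(model, samples) {
  ds <- vapply(samples, function(s) {
    pr <- predict_sequence(model, array(s$image, dim = c(dim(s$image), 1L)))
    tab <- evaluate_segmentation(pr$masks, list(s$mask))
    tab$mean_dsc[tab$class == "overall"]
  }, numeric(1))
  mean(ds)
}
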