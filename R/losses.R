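DICE_SMOOTH <- 1e-6

# One-hot encode a label mask into [HW, C] with channel 1 = background.
onehot_mask <- function(mask, n_channels) {
  lab <- as.integer(mask)
  out <- matrix(0, length(lab), n_channels)
  out[cbind(seq_along(lab), lab + 1L)] <- 1
  out
}

#' Soft Dice loss
#'
#' One minus the soft Dice coefficient
#' `(2 * sum(p*t) + s) / (sum(p) + sum(t) + s)` with smoothing constant
#' `s = 1e-6`, averaged over the foreground classes present in the target
#' (background and absent classes are excluded). Zero iff the scores are the
#' one-hot encoding of the target.
#'
#' @param scores array `[H, W, C]` of per-pixel class scores (C = foreground
#'   classes + 1 background channel; need not be normalized to be evaluated,
#'   but training passes softmax output).
#' @param target integer label matrix.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(scores, target) {
  .dice_terms(scores, target)$loss
}

.dice_terms <- function(scores, target, want_grad = FALSE) {
  d <- dim(scores)
  stopifnot(length(d) == 3, all(dim(target) == d[1:2]))
  HW <- d[1] * d[2]
  P <- scores
  dim(P) <- c(HW, d[3])
  TH <- onehot_mask(target, d[3])
  present <- which(colSums(TH) > 0)
  present <- present[present != 1L] # foreground only
  dP <- if (want_grad) matrix(0, HW, d[3]) else NULL
  if (length(present) == 0) {
    return(list(loss = 0, dP = dP))
  }
  loss <- 0
  for (c in present) {
    I <- sum(P[, c] * TH[, c])
    S <- sum(P[, c]) + sum(TH[, c])
    D <- (2 * I + DICE_SMOOTH) / (S + DICE_SMOOTH)
    loss <- loss + (1 - D)
    if (want_grad) {
      dP[, c] <- -(2 * TH[, c] * (S + DICE_SMOOTH) - (2 * I + DICE_SMOOTH)) /
        (S + DICE_SMOOTH)^2 / length(present)
    }
  }
  list(loss = loss / length(present), dP = dP)
}

#' Distance-transform Hausdorff loss
#'
#' Differentiable surrogate of the Hausdorff distance: per foreground class
#' present in the target, the squared score error `(p - t)^2` is weighted by
#' the sum of the squared Euclidean distance transforms of the target mask
#' and of the hard (argmax) prediction, normalized by the squared image
#' diagonal, and averaged over pixels and present classes. A mislabeled
#' pixel at distance `d` from the target therefore contributes
#' proportionally to `d^2`; the loss is zero iff the scores equal the
#' one-hot target.
#'
#' @inheritParams dice_loss
#' @return scalar loss, `>= 0`.
#' @export
hausdorff_loss <- function(scores, target) {
  .hausdorff_terms(scores, target)$loss
}

.hausdorff_terms <- function(scores, target, want_grad = FALSE,
                             pred_mask = NULL, dt_target = NULL) {
  d <- dim(scores)
  stopifnot(length(d) == 3, all(dim(target) == d[1:2]))
  HW <- d[1] * d[2]
  diag2 <- d[1]^2 + d[2]^2
  P <- scores
  dim(P) <- c(HW, d[3])
  if (is.null(pred_mask)) pred_mask <- labels_from_scores(scores)
  TH <- onehot_mask(target, d[3])
  present <- which(colSums(TH) > 0)
  present <- present[present != 1L]
  dP <- if (want_grad) matrix(0, HW, d[3]) else NULL
  if (length(present) == 0) {
    return(list(loss = 0, dP = dP))
  }
  loss <- 0
  for (c in present) {
    tb <- matrix(TH[, c], d[1], d[2])
    dt_t <- dt_target[[c]] %||% EBImage::distmap(1 - tb)
    pb <- pred_mask == (c - 1L)
    dt_p <- if (any(pb)) EBImage::distmap(1 - pb) else sqrt(diag2)
    w <- (as.numeric(dt_t)^2 + as.numeric(dt_p)^2) / diag2
    diffc <- P[, c] - TH[, c]
    loss <- loss + sum(diffc^2 * w) / HW
    if (want_grad) {
      dP[, c] <- 2 * diffc * w / HW / length(present)
    }
  }
  list(loss = loss / length(present), dP = dP)
}

#' Combined segmentation loss
#'
#' Unweighted sum of [dice_loss()] and [hausdorff_loss()]; zero iff the
#' scores equal the one-hot target.
#' @inheritParams dice_loss
#' @return scalar loss.
#' @export
seg_loss <- function(scores, target) {
  dice_loss(scores, target) + hausdorff_loss(scores, target)
}

# Precompute per-class target distance transforms for .hausdorff_terms
# (used to cache fixed targets across epochs).
.target_dt <- function(target, n_channels) {
  lapply(seq_len(n_channels), function(c) {
    if (c == 1L || !any(target == c - 1L)) return(NULL)
    EBImage::distmap(1 - (target == c - 1L))
  })
}

# Loss and gradient with respect to the logits for one batch.
# probs: [H, W, C, N]; targets: list of label matrices.
.batch_loss_grad <- function(probs, targets, dt_targets = NULL) {
  d <- dim(probs)
  N <- d[4]
  dlogits <- array(0, dim = d)
  total <- 0
  for (n in seq_len(N)) {
    pr <- probs[, , , n]
    dim(pr) <- d[1:3]
    dt <- .dice_terms(pr, targets[[n]], want_grad = TRUE)
    ht <- .hausdorff_terms(pr, targets[[n]], want_grad = TRUE,
                           dt_target = dt_targets[[n]])
    total <- total + dt$loss + ht$loss
    dP <- (dt$dP + ht$dP) / N
    # backprop through the softmax: dl = P * (dP - sum_c dP * P)
    Pm <- pr
    dim(Pm) <- c(d[1] * d[2], d[3])
    inner <- rowSums(dP * Pm)
    dl <- Pm * (dP - inner)
    dim(dl) <- d[1:3]
    dlogits[, , , n] <- dl
  }
  list(loss = total / N, dlogits = dlogits)
}
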