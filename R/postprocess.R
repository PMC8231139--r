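#' CRF configuration
#'
#' Parameters of the fully connected CRF refined by mean-field approximation
#' with two Gaussian pairwise kernels (convolutional approximation): an
#' appearance kernel over pixel position and intensity and a smoothness
#' kernel over position only, with Potts label compatibility.
#'
#' @param iterations mean-field iterations (default 5).
#' @param appearance_sd_px spatial SD of the appearance kernel in pixels
#'   (default 8).
#' @param appearance_sd_intensity intensity SD of the appearance kernel, in
#'   Z-score units (default 0.5).
#' @param smoothness_sd_px spatial SD of the smoothness kernel (default 3).
#' @param w_appearance,w_smoothness kernel mixing weights (defaults 2 and 1).
#'   Messages are normalized by the spatial kernel mass, so the weights are
#'   on the scale of the unary log-odds: a unanimous neighbourhood
#'   contributes at most `w` to a label's potential.
#' @return object of class `carpo_crf_config`.
#' @export
crf_config <- function(iterations = 5L, appearance_sd_px = 8,
                       appearance_sd_intensity = 0.5,
                       smoothness_sd_px = 3,
                       w_appearance = 2, w_smoothness = 1) {
  stopifnot(iterations >= 1, appearance_sd_px > 0,
            appearance_sd_intensity > 0, smoothness_sd_px > 0)
  structure(list(iterations = as.integer(iterations),
                 appearance_sd_px = appearance_sd_px,
                 appearance_sd_intensity = appearance_sd_intensity,
                 smoothness_sd_px = smoothness_sd_px,
                 w_appearance = w_appearance, w_smoothness = w_smoothness),
            class = "carpo_crf_config")
}

#' Mean-field CRF refinement of class scores
#'
#' Combines the per-pixel class scores with low-level image information:
#' unary potentials are the negative log scores, and each mean-field
#' iteration passes messages through a truncated Gaussian appearance kernel
#' (position + intensity) and a Gaussian smoothness kernel (position only)
#' under Potts compatibility, renormalizing per pixel.
#'
#' @param scores array `[H, W, C]` of normalized per-pixel class scores.
#' @param img the corresponding (Z-scored) intensity image.
#' @param cfg a [crf_config()].
#' @return refined score array, normalized per pixel.
#' @export
crf_refine <- function(scores, img, cfg = crf_config()) {
  d <- dim(scores)
  stopifnot(length(d) == 3, all(dim(img) == d[1:2]))
  sums <- rowSums(matrix(scores, d[1] * d[2], d[3]))
  if (max(abs(sums - 1)) > 1e-6) {
    stop("scores must be normalized per pixel (softmax output)")
  }
  unary <- -log(pmax(scores, 1e-12))
  Q <- scores
  r_app <- ceiling(2 * cfg$appearance_sd_px)
  r_sm <- ceiling(2 * cfg$smoothness_sd_px)
  # spatial kernel masses (centre excluded) used to normalize the messages
  kmass <- function(sd, r) {
    off <- -r:r
    sum(exp(-outer(off^2, off^2, "+") / (2 * sd^2))) - 1
  }
  m_app <- kmass(cfg$appearance_sd_px, r_app)
  m_sm <- kmass(cfg$smoothness_sd_px, r_sm)
  for (it in seq_len(cfg$iterations)) {
    msg <- 0
    if (cfg$w_appearance > 0) {
      f <- cpp_crf_filter(Q, img, cfg$appearance_sd_px,
                          cfg$appearance_sd_intensity, TRUE, r_app)
      msg <- msg + (cfg$w_appearance / m_app) * f
    }
    if (cfg$w_smoothness > 0) {
      f <- cpp_crf_filter(Q, img, cfg$smoothness_sd_px, 1, FALSE, r_sm)
      msg <- msg + (cfg$w_smoothness / m_sm) * f
    }
    # Potts: penalty for label l is the filtered mass of all other labels
    if (!identical(msg, 0)) {
      tot <- array(rowSums(matrix(msg, d[1] * d[2], d[3])), dim = d[1:2])
      pen <- array(as.numeric(tot), dim = d) - msg
    } else {
      pen <- 0
    }
    logq <- -unary - pen
    mx <- apply(logq, c(1, 2), max)
    Q <- exp(logq - array(as.numeric(mx), dim = d))
    z <- array(rowSums(matrix(Q, d[1] * d[2], d[3])), dim = d[1:2])
    Q <- Q / array(as.numeric(z), dim = d)
  }
  Q
}

#' Temporal stabilization configuration
#'
#' A five-frame window (two frames before and two after the current frame)
#' with Gaussian weights over the temporal offset, discretized at offsets
#' -2..2 and normalized to sum to the window length (5) so the cumulative
#' allocation of a pixel assigned to a class at every time point equals 5;
#' the mean allocation (cumulative / window length) is compared against the
#' threshold `tau`.
#'
#' The default width `sigma_t = 1.2` makes the stages' two canonical
#' behaviours hold simultaneously under `tau = 0.6`: a pixel assigned in
#' only the centre frame (flicker) scores 0.34 and is removed, while a
#' pixel missing from only the centre frame (single-frame dropout) scores
#' 0.66 and survives; a sharper Gaussian (e.g. 1.0) would punch single-frame
#' holes into otherwise stable segmentations.
#'
#' @param sigma_t Gaussian width in frames (default 1.2).
#' @param tau acceptance threshold on the mean allocation (default 0.6).
#' @return object of class `carpo_temporal_config` with the discretized
#'   `weights` (named by offset).
#' @export
temporal_config <- function(sigma_t = 1.2, tau = 0.6) {
  stopifnot(sigma_t > 0, tau > 0, tau < 1)
  off <- -2:2
  w <- exp(-off^2 / (2 * sigma_t^2))
  w <- w * length(off) / sum(w)
  structure(list(window = 5L, offsets = off,
                 weights = setNames(w, off),
                 sigma_t = sigma_t, tau = tau),
            class = "carpo_temporal_config")
}

#' Temporal label stabilization of a mask sequence
#'
#' For every frame, class and pixel, the binary class allocations of the
#' five-frame neighbourhood are combined with the Gaussian weights of
#' `cfg`; a pixel keeps a class when the weighted mean allocation reaches
#' `tau`, otherwise it becomes background. The calculation is performed
#' separately per image and class; when several classes pass the threshold
#' the one with the highest mean wins. At the sequence boundaries the window
#' is truncated and its weights renormalized to sum to the truncated length.
#'
#' @param masks list of integer label matrices or 3D array `[H, W, T]`.
#' @param cfg a [temporal_config()].
#' @return stabilized masks in the same form as the input.
#' @export
temporal_stabilize <- function(masks, cfg = temporal_config()) {
  as_list <- is.list(masks)
  arr <- if (as_list) {
    if (length(masks) == 0) stop("empty mask sequence")
    array(unlist(masks), dim = c(dim(masks[[1]]), length(masks)))
  } else {
    masks
  }
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  H <- dim(arr)[1]; W <- dim(arr)[2]; TT <- dim(arr)[3]
  classes <- sort(unique(as.integer(arr)))
  classes <- classes[classes > 0]
  best_mean <- array(0, dim = c(H, W, TT))
  out <- array(0L, dim = c(H, W, TT))
  # per-frame effective weight sums under boundary truncation
  wsum <- vapply(seq_len(TT), function(t) {
    k <- cfg$offsets
    ok <- t + k >= 1 & t + k <= TT
    sum(cfg$weights[ok])
  }, numeric(1))
  wlen <- vapply(seq_len(TT), function(t) {
    sum(t + cfg$offsets >= 1 & t + cfg$offsets <= TT)
  }, numeric(1))
  for (cl in classes) {
    alloc <- array(as.numeric(arr == cl), dim = dim(arr))
    cum <- array(0, dim = dim(arr))
    for (i in seq_along(cfg$offsets)) {
      k <- cfg$offsets[i]
      src <- seq_len(TT) + k
      ok <- src >= 1 & src <= TT
      cum[, , which(ok)] <- cum[, , which(ok), drop = FALSE] +
        cfg$weights[i] * alloc[, , src[ok], drop = FALSE]
    }
    # renormalize truncated windows to sum to the truncated length
    for (t in seq_len(TT)) {
      mean_t <- cum[, , t] * (wlen[t] / wsum[t]) / wlen[t]
      sel <- mean_t >= cfg$tau & mean_t > best_mean[, , t]
      o <- out[, , t]
      b <- best_mean[, , t]
      o[sel] <- cl
      b[sel] <- mean_t[sel]
      out[, , t] <- o
      best_mean[, , t] <- b
    }
  }
  if (as_list) {
    lapply(seq_len(TT), function(t) matrix(out[, , t], H, W))
  } else {
    out
  }
}

#' Morphology configuration
#'
#' @param element structuring element matrix; default the 5-pixel cross
#'   (centre plus 4-neighbours).
#' @param connectivity connectivity for the largest-component rule (4,
#'   fixed).
#' @return object of class `carpo_morph_config`.
#' @export
morph_config <- function(element = cross_element(), connectivity = 4L) {
  stopifnot(all(element %in% c(0, 1)), connectivity == 4L)
  structure(list(element = element, connectivity = 4L),
            class = "carpo_morph_config")
}

#' The 5-pixel cross structuring element
#' @return 3x3 binary matrix with centre and 4-neighbours set.
#' @export
cross_element <- function() {
  matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
}

#' Morphological cleanup of a label mask
#'
#' Per class: binary opening then closing with the 5-pixel cross to smooth
#' segmentation edges and fill holes, then retention of only the largest
#' 4-connected component; all other pixels become background. Classes are
#' written in ascending order (higher class wins where closing makes two
#' classes touch).
#'
#' @param mask integer label matrix.
#' @param cfg a [morph_config()].
#' @return cleaned integer label matrix.
#' @export
morphological_cleanup <- function(mask, cfg = morph_config()) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (cl in sort(unique(as.integer(mask)))) {
    if (cl == 0) next
    b <- (mask == cl) + 0
    b <- EBImage::closing(EBImage::opening(b, cfg$element), cfg$element)
    if (!any(b > 0)) next
    lab <- EBImage::bwlabel(b)
    sizes <- tabulate(lab[lab > 0])
    keep <- which.max(sizes)
    out[lab == keep] <- cl
  }
  out
}

#' Full post-processing pipeline for a segmented sequence
#'
#' Applies, in order: mean-field CRF refinement of the per-frame scores,
#' argmax labelling, Gaussian-weighted temporal stabilization, and
#' morphological cleanup with largest-component selection.
#'
#' @param scores list of `[H, W, C]` score arrays (one per frame).
#' @param frames list of intensity matrices (or 3D array) aligned with
#'   `scores`; required when `crf = TRUE`.
#' @param crf,temporal logical stage toggles.
#' @param crf_cfg,temporal_cfg,morph_cfg stage configurations.
#' @return list of cleaned integer label masks.
#' @export
run_postprocess <- function(scores, frames = NULL,
                            crf = TRUE, temporal = TRUE,
                            crf_cfg = crf_config(),
                            temporal_cfg = temporal_config(),
                            morph_cfg = morph_config()) {
  if (!is.null(frames) && !is.list(frames)) {
    frames <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  }
  if (crf) {
    if (is.null(frames) || length(frames) != length(scores)) {
      stop("CRF refinement needs one intensity frame per score stack")
    }
    scores <- lapply(seq_along(scores), function(t) {
      crf_refine(scores[[t]], frames[[t]], crf_cfg)
    })
  }
  masks <- lapply(scores, labels_from_scores)
  if (temporal) {
    masks <- temporal_stabilize(masks, temporal_cfg)
  }
  lapply(masks, morphological_cleanup, cfg = morph_cfg)
}
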