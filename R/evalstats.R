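#' Dice similarity coefficient for one class
#'
#' `2|A n B| / (|A| + |B|)` of the binary class masks; ranges from 0 (no
#' overlap) to 1 (complete overlap). When the class is absent from both
#' masks the DSC is defined as 1 (perfect agreement on absence).
#'
#' @param a,b congruent integer label masks.
#' @param class_id class to compare.
#' @return DSC in `[0, 1]`.
#' @export
dice_similarity <- function(a, b, class_id) {
  stopifnot(all(dim(a) == dim(b)))
  ba <- a == class_id
  bb <- b == class_id
  denom <- sum(ba) + sum(bb)
  if (denom == 0) return(1)
  2 * sum(ba & bb) / denom
}

#' Bland-Altman agreement statistics
#'
#' For paired measurements the differences `d = x - y` are summarized by
#' their mean, SD, and the limits of agreement `mean +/- 1.96 * SD`.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return object of class `carpo_bland_altman`: `mean_difference`,
#'   `sd_difference`, `limits_of_agreement` (length 2), `n`, plus the means
#'   and differences for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("paired series must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least two finite pairs")
  d <- x - y
  md <- mean(d)
  sdd <- sd(d)
  structure(list(mean_difference = md, sd_difference = sdd,
                 limits_of_agreement = c(md - 1.96 * sdd, md + 1.96 * sdd),
                 n = length(d), means = (x + y) / 2, differences = d),
            class = "carpo_bland_altman")
}

#' @export
print.carpo_bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman agreement (n = %d)\n  mean difference %.4f, SD %.4f\n  limits of agreement [%.4f, %.4f]\n",
    x$n, x$mean_difference, x$sd_difference,
    x$limits_of_agreement[1], x$limits_of_agreement[2]))
  invisible(x)
}

#' @export
plot.carpo_bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "mean of pair", ylab = "difference", ...)
  graphics::abline(h = x$mean_difference, col = "red")
  graphics::abline(h = x$limits_of_agreement, col = "grey40", lty = 2)
  invisible(x)
}

#' Subject-level train/test split
#'
#' Partitions subjects (not wrists or images) so both wrists of a subject
#' fall on the same side of the split, and reports the resulting image
#' counts (`subjects x wrists_per_subject x frames_per_wrist`).
#'
#' @param n_subjects total subjects (default 28).
#' @param n_train_subjects subjects assigned to training (default 21).
#' @param wrists_per_subject wrists per subject (default 2, bilateral).
#' @param frames_per_wrist annotated frames per wrist (default 15).
#' @param seed RNG seed for the subject sampling.
#' @return list with `train_subjects`, `test_subjects`, `n_train_images`,
#'   `n_test_images`.
#' @export
subject_split <- function(n_subjects = 28L, n_train_subjects = 21L,
                          wrists_per_subject = 2L, frames_per_wrist = 15L,
                          seed = 1L) {
  if (n_train_subjects > n_subjects || n_train_subjects < 0) {
    stop("impossible split: n_train_subjects must be in 0..n_subjects")
  }
  train <- if (n_train_subjects == 0) integer(0) else
    with_seed(seed, sort(sample.int(n_subjects, n_train_subjects)))
  test <- setdiff(seq_len(n_subjects), train)
  per_subject <- wrists_per_subject * frames_per_wrist
  list(train_subjects = train, test_subjects = test,
       n_train_images = length(train) * per_subject,
       n_test_images = length(test) * per_subject)
}

#' Equal-interval frame selection from a movement cycle
#'
#' Selects `n` frame indices at equal temporal spacing spanning the first to
#' the last frame of a cycle of `len` frames (indices rounded to the nearest
#' frame; strictly increasing because the spacing is at least one frame).
#'
#' @param len number of frames in the cycle (or a sequence/list whose length
#'   is used).
#' @param n frames to select (default 15).
#' @return integer vector of `n` 1-based frame indices.
#' @export
select_cycle_frames <- function(len, n = 15L) {
  if (inherits(len, "carpo_sequence")) len <- dim(len$data)[3]
  if (is.list(len)) len <- length(len)
  len <- as.integer(len)
  if (len < n) stop("cycle shorter than the number of frames to select")
  if (n == 1) return(1L)
  as.integer(round((seq_len(n) - 1) * (len - 1) / (n - 1))) + 1L
}

#' Identify one movement cycle from a wrist-angle series
#'
#' Heuristic used on phantom data: the cycle runs from the global radial
#' extreme (minimum angle) to the following ulnar extreme (maximum angle).
#' @param angles numeric vector of per-frame wrist angles (deg).
#' @return integer vector `c(first, last)` frame of the cycle.
#' @export
identify_cycle <- function(angles) {
  i0 <- which.min(angles)
  rest <- angles[i0:length(angles)]
  i1 <- i0 + which.max(rest) - 1L
  if (i1 <= i0) stop("no ulnar extreme after the radial extreme")
  c(i0, i1)
}

#' Per-class Dice evaluation of a segmented sequence
#'
#' Computes the DSC per frame and class between predicted and truth masks
#' and summarizes mean and SD per class plus an overall row (all foreground
#' classes pooled across frames).
#'
#' @param pred,truth aligned lists of label masks (or 3D arrays).
#' @param classes classes to evaluate (default 1..8).
#' @return data.frame: class, mean_dsc, sd_dsc, n_frames.
#' @export
evaluate_segmentation <- function(pred, truth, classes = 1:8) {
  tolist <- function(m) {
    if (is.list(m)) m else lapply(seq_len(dim(m)[3]), function(t) m[, , t])
  }
  pred <- tolist(pred); truth <- tolist(truth)
  if (length(pred) != length(truth)) stop("sequences must be aligned")
  per_class <- lapply(classes, function(cl) {
    vapply(seq_along(pred), function(k) {
      dice_similarity(pred[[k]], truth[[k]], cl)
    }, numeric(1))
  })
  names(per_class) <- as.character(classes)
  used <- classes[vapply(classes, function(cl) {
    any(vapply(seq_along(truth), function(k) any(truth[[k]] == cl), logical(1)))
  }, logical(1))]
  if (length(used) == 0) {
    warning("no overlapping classes between prediction and truth")
    return(data.frame(class = character(), mean_dsc = numeric(),
                      sd_dsc = numeric(), n_frames = integer()))
  }
  rows <- lapply(used, function(cl) {
    v <- per_class[[as.character(cl)]]
    data.frame(class = names(CARPO_CLASSES)[cl], mean_dsc = mean(v),
               sd_dsc = sd(v), n_frames = length(v))
  })
  all_v <- unlist(per_class[as.character(used)])
  rows[[length(rows) + 1L]] <- data.frame(
    class = "overall", mean_dsc = mean(all_v), sd_dsc = sd(all_v),
    n_frames = length(pred))
  do.call(rbind, rows)
}
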