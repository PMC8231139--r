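#' Read a 2D+time image sequence
#'
#' Supports NIfTI (`.nii`, `.nii.gz`) and multi-page TIFF (`.tif`,
#' `.tiff`). Intensity scale is irrelevant downstream (frames are Z-scored),
#' so TIFF's unit-range convention is accepted as-is.
#'
#' @param path input file.
#' @param pixel_spacing_mm pixel size; for NIfTI taken from the header when
#'   not given (default 1.0 otherwise).
#' @param frame_interval_ms frame interval metadata (default `NA`).
#' @return a `carpo_sequence`.
#' @export
read_image_sequence <- function(path, pixel_spacing_mm = NULL,
                                frame_interval_ms = NA_real_) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
    if (is.null(pixel_spacing_mm)) {
      pixel_spacing_mm <- RNifti::pixdim(img)[1]
    }
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
    pixel_spacing_mm <- pixel_spacing_mm %||% 1.0
  } else {
    stop("unsupported sequence format: ", path)
  }
  structure(list(data = arr, pixel_spacing_mm = pixel_spacing_mm,
                 frame_interval_ms = frame_interval_ms,
                 timestamps_ms = if (is.na(frame_interval_ms)) NULL else
                   (seq_len(dim(arr)[3]) - 1) * frame_interval_ms),
            class = "carpo_sequence")
}

#' Write an image sequence
#'
#' NIfTI keeps raw intensities and pixel spacing; multi-page TIFF stores
#' frames min-max scaled to the unit range (32-bit float).
#' @param seq a `carpo_sequence` or 3D array.
#' @param path output file (`.nii`, `.nii.gz`, `.tif`).
#' @return `path`, invisibly.
#' @export
write_image_sequence <- function(seq, path) {
  arr <- if (inherits(seq, "carpo_sequence")) seq$data else seq
  sp <- if (inherits(seq, "carpo_sequence")) seq$pixel_spacing_mm else 1.0
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(sp, sp, 1)
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    rng <- range(arr)
    sc <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
    tiff::writeTIFF(lapply(seq_len(dim(arr)[3]), function(t) sc[, , t]),
                    path, bits.per.sample = 32L)
  } else {
    stop("unsupported sequence format: ", path)
  }
  invisible(path)
}

#' Read / write integer label mask sequences
#'
#' NIfTI stores labels as integers; TIFF uses 8 bits per sample with labels
#' scaled by 1/255.
#' @param path mask file (`.nii`, `.nii.gz`, `.tif`).
#' @return integer array `[H, W, T]`.
#' @export
read_mask_sequence <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
    array(as.integer(round(arr)), dim = dim(arr))
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(as.integer(round(unlist(pages) * 255)),
                 dim = c(dim(pages[[1]])[1:2], length(pages)))
    arr
  } else {
    stop("unsupported mask format: ", path)
  }
}

#' @rdname read_mask_sequence
#' @param masks list of label matrices or integer array `[H, W, T]`.
#' @export
write_mask_sequence <- function(masks, path) {
  arr <- if (is.list(masks)) {
    array(unlist(masks), dim = c(dim(masks[[1]]), length(masks)))
  } else {
    masks
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(arr), dim = dim(arr))),
                       path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(lapply(seq_len(dim(arr)[3]), function(t) arr[, , t] / 255),
                    path, bits.per.sample = 8L)
  } else {
    stop("unsupported mask format: ", path)
  }
  invisible(path)
}

#' Read / write polygon annotations
#'
#' JSON files mapping class ids to vertex lists: `{"3": [[x, y], ...], ...}`
#' with 0-based pixel-centre coordinates.
#' @param path JSON file.
#' @return named list of n x 2 vertex matrices.
#' @export
read_annotation <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  lapply(raw, function(v) {
    m <- matrix(as.numeric(unlist(v)), ncol = 2, byrow = !is.matrix(v))
    if (is.matrix(v)) m <- v
    colnames(m) <- c("x", "y")
    m
  })
}

#' @rdname read_annotation
#' @param ann annotation list.
#' @export
write_annotation <- function(ann, path) {
  jsonlite::write_json(lapply(ann, unname), path, digits = NA)
  invisible(path)
}

#' Write per-frame metrics to CSV
#' @param metrics data.frame from [quantify_sequence()].
#' @param path output CSV.
#' @export
write_metrics_csv <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Write phantom ground-truth metrics to CSV
#' @param phantom a `carpo_phantom` from [generate_sequence()].
#' @param path output CSV (columns frame, time_ms, angle_deg, sl_mm, lt_mm).
#' @export
write_truth_csv <- function(phantom, path) {
  tr <- phantom$truth
  n <- length(tr$angle_deg)
  write.csv(data.frame(frame = seq_len(n),
                       time_ms = phantom$images$timestamps_ms,
                       angle_deg = tr$angle_deg,
                       sl_mm = tr$sl_mm, lt_mm = tr$lt_mm),
            path, row.names = FALSE)
  invisible(path)
}
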