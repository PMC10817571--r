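#' Crop and resize an ultrasound frame (and optionally its mask)
#'
#' Frames are resampled bilinearly; masks use nearest-neighbour resampling
#' so they remain exactly binary. Frame intensities are rounded back to
#' 8-bit integers, which keeps constant images constant.
#'
#' @param frame numeric matrix of 8-bit intensities.
#' @param crop_box optional crop `c(row, col, height, width)` (1-based,
#'   inclusive origin) applied before resizing; used to remove the scanner
#'   UI frame from raw exports. `NULL` keeps the full frame.
#' @param target output side length in pixels (square), default 256.
#' @param kind `"frame"` (bilinear) or `"mask"` (nearest neighbour).
#' @return A `target` x `target` matrix; integer 0-255 for frames, 0/1 for
#'   masks.
#' @export
crop_and_resize <- function(frame, crop_box = NULL, target = 256L,
                            kind = c("frame", "mask")) {
  kind <- match.arg(kind)
  if (!is.matrix(frame)) nt_stop("`frame` must be a matrix", "nervetrace_type_error")
  if (!is.null(crop_box)) {
    cb <- as.integer(crop_box)
    if (length(cb) != 4) {
      nt_stop("crop_box must be c(row, col, height, width)", "nervetrace_geometry_error")
    }
    if (cb[1] < 1 || cb[2] < 1 || cb[3] < 1 || cb[4] < 1 ||
        cb[1] + cb[3] - 1 > nrow(frame) || cb[2] + cb[4] - 1 > ncol(frame)) {
      nt_stop("crop_box exceeds frame bounds", "nervetrace_geometry_error")
    }
    frame <- frame[cb[1]:(cb[1] + cb[3] - 1), cb[2]:(cb[2] + cb[4] - 1), drop = FALSE]
  }
  target <- as.integer(target)
  if (nrow(frame) == target && ncol(frame) == target) {
    if (kind == "mask") assert_mask(frame, "frame")
    storage.mode(frame) <- "integer"
    return(frame)
  }
  if (kind == "mask") {
    assert_mask(frame, "frame")
    out <- eb_op(frame, function(im)
      EBImage::resize(im, w = target, h = target, filter = "none"))
    return(matrix(as.integer(out != 0), target, target))
  }
  out <- eb_op(frame, function(im)
    EBImage::resize(im, w = target, h = target, filter = "bilinear"))
  matrix(as.integer(round(pmin(pmax(out, 0), 255))), target, target)
}

#' Crop and resize a frame/mask pair identically
#'
#' @inheritParams crop_and_resize
#' @param mask binary matrix paired with `frame`.
#' @return List with resized `frame` and `mask`.
#' @export
crop_and_resize_pair <- function(frame, mask, crop_box = NULL, target = 256L) {
  list(frame = crop_and_resize(frame, crop_box, target, "frame"),
       mask = crop_and_resize(mask, crop_box, target, "mask"))
}

#' Randomly partition image identifiers into train/validation/test sets
#'
#' Sizes follow the study proportions 3/4 : 1/12 : 1/6, computed as
#' `round(3n/4)` for training, then `round(n/12)` for validation, with the
#' remainder used for testing; 600 identifiers therefore split 450/50/100.
#'
#' @param ids vector of image identifiers (length >= 12).
#' @param seed integer seed for the permutation.
#' @return An object of class `dataset_split` with elements `train`,
#'   `validation`, `test`, `proportions` and `seed`.
#' @export
split_dataset <- function(ids, seed = 1L) {
  n <- length(ids)
  if (n < 12) nt_stop("need at least 12 ids to split", "nervetrace_size_error")
  if (anyDuplicated(ids)) nt_stop("ids must be unique", "nervetrace_config_error")
  n_train <- round(3 * n / 4)
  n_val <- round(n / 12)
  n_test <- n - n_train - n_val
  perm <- with_seed(seed, sample(ids))
  structure(
    list(train = perm[seq_len(n_train)],
         validation = perm[n_train + seq_len(n_val)],
         test = perm[n_train + n_val + seq_len(n_test)],
         proportions = c(train = 3 / 4, validation = 1 / 12, test = 1 / 6),
         seed = as.integer(seed)),
    class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

flip_matrix <- function(m, type) {
  switch(type,
         v = m[nrow(m):1, , drop = FALSE],
         h = m[, ncol(m):1, drop = FALSE],
         hv = m[nrow(m):1, ncol(m):1, drop = FALSE],
         nt_stop("unknown flip type", "nervetrace_config_error"))
}

#' Double a training set by adding one randomly flipped copy per image
#'
#' Each image receives exactly one additional copy, flipped vertically,
#' horizontally, or both (chosen at random per image); frame and mask are
#' flipped together. 450 input pairs therefore become 900.
#'
#' @param pairs list of lists, each carrying at least `frame` and `mask`.
#' @param seed integer seed for the per-image flip choice.
#' @return A list of `2 * length(pairs)` pairs: the originals followed by
#'   the flipped copies (each tagged with a `flip` element).
#' @export
augment_flips <- function(pairs, seed = 1L) {
  if (!length(pairs)) nt_stop("no training pairs to augment", "nervetrace_size_error")
  types <- with_seed(seed,
    sample(c("v", "h", "hv"), length(pairs), replace = TRUE))
  flipped <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    p$frame <- flip_matrix(p$frame, types[i])
    p$mask <- flip_matrix(p$mask, types[i])
    p$flip <- types[i]
    if (!is.null(p$id)) p$id <- paste0(p$id, "_", types[i])
    p
  })
  c(pairs, flipped)
}
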