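# Image and table I/O. Frames are 8-bit grayscale matrices (row, col);
# masks are 0/1 matrices stored as 0/255 PNG.

#' Read a grayscale ultrasound frame from PNG or TIFF
#' @param path file path ending in .png, .tif or .tiff.
#' @return Integer matrix of 0-255 intensities (first channel of a
#'   multi-channel file).
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                nt_stop("unsupported image format (use PNG or TIFF)",
                        "nervetrace_io_error"))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Write a grayscale frame to PNG or TIFF
#' @param frame integer matrix of 0-255 intensities.
#' @param path output path; the extension selects the format.
#' @export
write_frame <- function(frame, path) {
  ext <- tolower(tools::file_ext(path))
  v <- pmin(pmax(frame, 0), 255) / 255
  switch(ext,
         png = png::writePNG(v, path),
         tif = ,
         tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
         nt_stop("unsupported image format (use PNG or TIFF)",
                 "nervetrace_io_error"))
  invisible(path)
}

#' Read a binary mask from a 0/255 PNG
#' @param path PNG path.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(img > 0.5), nrow(img), ncol(img))
}

#' Write a binary mask as a 0/255 PNG
#' @param mask 0/1 matrix.
#' @param path PNG path.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask + 0, path)
  invisible(path)
}

#' Tabulate phantom specs (one row per image)
#' @param dataset a list from [generate_dataset()] (or a list of
#'   `phantom_spec`s).
#' @return A data frame with one row per spec and all generating fields.
#' @export
specs_to_df <- function(dataset) {
  do.call(rbind, lapply(dataset, function(el) {
    sp <- if (inherits(el, "phantom_spec")) el else el$spec
    data.frame(id = if (!is.null(el$id)) el$id else NA_character_,
               stratum = if (!is.null(el$stratum)) el$stratum else NA_character_,
               frame_rows = sp$frame_size[1], frame_cols = sp$frame_size[2],
               center_row = sp$center[1], center_col = sp$center[2],
               semi_a = sp$semi_axes[1], semi_b = sp$semi_axes[2],
               rotation = sp$rotation, rim_thickness = sp$rim_thickness,
               interior_level = sp$interior_level,
               background_level = sp$background_level,
               rim_level = sp$rim_level, blur_sigma = sp$blur_sigma,
               speckle_shape = sp$speckle_shape, seed = sp$seed)
  }))
}

#' Write a phantom dataset to disk (frames, masks, spec table)
#' @param dataset list from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"tiff"` for the frames.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (el in dataset) {
    write_frame(el$frame, file.path(dir, paste0(el$id, ".", format)))
    write_mask(el$mask, file.path(dir, paste0(el$id, "_mask.png")))
  }
  utils::write.csv(specs_to_df(dataset), file.path(dir, "specs.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a train/validation/test split manifest
#' @param split a `dataset_split`.
#' @param path CSV path.
#' @export
write_split_manifest <- function(split, path) {
  df <- data.frame(
    id = c(split$train, split$validation, split$test),
    partition = rep(c("train", "validation", "test"),
                    c(length(split$train), length(split$validation),
                      length(split$test))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
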