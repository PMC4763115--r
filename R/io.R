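#' Read an 8-bit grayscale seed scan
#'
#' Reads a PNG (or TIFF, if the `tiff` package is installed) image and
#' returns an integer matrix of gray values 0-255 (rows = image rows).
#' Colour images are converted by channel averaging.
#'
#' @param path image file path (`.png`, `.tif`/`.tiff`).
#' @return integer matrix, 0 (black) to 255 (white).
#' @export
read_seed_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("reading TIFF requires the 'tiff' package")
    a <- tiff::readTIFF(path)
  } else {
    a <- png::readPNG(path)
  }
  if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' Write an 8-bit grayscale image
#'
#' @param image integer matrix of gray values 0-255 (e.g. from
#'   [render_scene()]), or a `seed_scene` object.
#' @param path output path; format chosen by extension (`.png` default,
#'   `.tif`/`.tiff` with the `tiff` package).
#' @return `path`, invisibly.
#' @export
write_seed_image <- function(image, path) {
  if (inherits(image, "seed_scene")) image <- image$image
  a <- image / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      abort("writing TIFF requires the 'tiff' package")
    tiff::writeTIFF(a, path, bits.per.sample = 8L)
  } else {
    png::writePNG(a, path)
  }
  invisible(path)
}
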