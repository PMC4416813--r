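#' Calibrated micrograph image
#'
#' Bundles a pixel array with its physical calibration. Pixel values are
#' stored as doubles in \[0, 1\]; coordinates throughout the package are
#' (row, col), 0-based, origin at the top-left pixel, matching the
#' convention of the contour and seed CSV formats.
#'
#' @param pixels numeric matrix (grayscale) or h x w x 3 array (RGB) of
#'   finite values.
#' @param pixel_size physical size of one pixel in micrometres per pixel
#'   (must be a single positive finite number). The calibration is always
#'   supplied explicitly; it is never read from image metadata.
#' @return an object of class `calibrated_image` with elements `pixels`
#'   (always a 3-d array, third dim 1 or 3) and `pixel_size`.
#' @export
calibrated_image <- function(pixels, pixel_size) {
  if (!is.numeric(pixels)) stop("`pixels` must be numeric")
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  d <- dim(pixels)
  if (length(d) != 3L || !(d[3] %in% c(1L, 3L)))
    stop("`pixels` must be a matrix or an array with 1 or 3 channels")
  if (d[1] < 3L || d[2] < 3L) stop("image must have at least 3x3 pixels")
  if (!all(is.finite(pixels))) stop("image contains non-finite pixel values")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %d channel(s), %.4g um/px\n",
              d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Read a calibrated image from a PNG or TIFF file
#'
#' The file type is decided by extension (`.png`, `.tif`, `.tiff`). An alpha
#' channel, if present, is dropped. Grayscale stays single-channel.
#'
#' @param path file path.
#' @param pixel_size calibration in micrometres per pixel; required, never
#'   inferred from metadata.
#' @return a [calibrated_image].
#' @export
read_image <- function(path, pixel_size) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF): ", path)
  )
  if (length(dim(px)) == 3L && dim(px)[3] %in% c(2L, 4L))
    px <- px[, , seq_len(dim(px)[3] - 1L), drop = FALSE]  # drop alpha
  if (length(dim(px)) == 3L && dim(px)[3] == 1L)
    px <- px[, , 1L]
  calibrated_image(px, pixel_size)
}

#' Write a calibrated image to PNG or TIFF
#'
#' @param image a [calibrated_image] or numeric matrix/array in \[0, 1\].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  px <- pmin(pmax(px, 0), 1)
  if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1L]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(px, path),
    tif  = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    stop("unsupported image format '.", ext, "': ", path)
  )
  invisible(path)
}

# grayscale view used where a single luminance channel is wanted
as_gray <- function(image) {
  px <- image$pixels
  if (dim(px)[3] == 1L) return(px[, , 1L])
  0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
}
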