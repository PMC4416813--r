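#' Fill the interior of a closed contour
#'
#' Rasterizes a closed, simple pixel contour to a logical mask marking the
#' boundary pixels plus every pixel enclosed by the boundary (even-odd
#' rule). The result has no 4-connected holes. Boundary pixels count as
#' inside: the drawn boundary lies on the tubule's outer edge.
#'
#' @param ct a closed [contour()].
#' @param image_shape integer length-2 `(rows, cols)` of the image the
#'   contour lives in; defaults to the contour's bounding box plus 2 px.
#' @return logical matrix of dimension `image_shape`.
#' @export
fill_interior <- function(ct, image_shape = NULL) {
  if (!inherits(ct, "contour")) stop("`ct` must be a contour object")
  if (!ct$closed) stop("cannot fill an open contour")
  co <- ct$coords
  if (is.null(image_shape)) image_shape <- apply(co, 2, max) + 3L
  m <- matrix(0L, image_shape[1], image_shape[2])
  m[cbind(co[, 1] + 1L, co[, 2] + 1L)] <- 1L
  filled <- EBImage::fillHull(m) > 0
  if (sum(filled) <= nrow(unique(co)))
    stop("degenerate contour: no interior pixels")
  filled
}

#' Tubular area of a closed contour
#'
#' The area is the number of pixels inside the drawn boundary (boundary
#' included), converted to square millimetres.
#'
#' @param ct a closed [contour()].
#' @param pixel_size calibration in micrometres per pixel.
#' @return area in mm^2.
#' @export
tubule_area <- function(ct, pixel_size) {
  stopifnot(is.finite(pixel_size), pixel_size > 0)
  sum(fill_interior(ct)) * pixel_size^2 * 1e-6
}

#' Tubular diameter of a closed contour
#'
#' The radius is the mean Euclidean distance from every pixel on the drawn
#' boundary to the tubule's centre of mass, taken as the centroid of the
#' filled interior; the diameter is twice that, in micrometres.
#'
#' @inheritParams tubule_area
#' @return diameter in micrometres.
#' @export
tubule_diameter <- function(ct, pixel_size) {
  stopifnot(is.finite(pixel_size), pixel_size > 0)
  mask <- fill_interior(ct)
  idx <- which(mask, arr.ind = TRUE)
  centre <- colMeans(idx)                       # 1-based pixel centres
  bd <- unique(ct$coords) + 1L
  radius <- mean(sqrt((bd[, 1] - centre[1])^2 + (bd[, 2] - centre[2])^2))
  2 * radius * pixel_size
}

#' Epithelial height between an outer contour and its lumen
#'
#' The symmetric mean nearest-boundary distance: the average over
#' outer-boundary pixels of the distance to the nearest lumen-boundary
#' pixel, averaged with the reverse direction, in micrometres. Distances
#' are taken from an exact Euclidean distance transform of one boundary
#' sampled at the other.
#'
#' @param outer closed [contour()] of the tubule boundary.
#' @param lumen closed [contour()] of the lumen boundary, or `NULL` when no
#'   lumen is visible (returns `NA` with `has_lumen = FALSE` semantics in
#'   [measure_tubules()]).
#' @param pixel_size calibration in micrometres per pixel.
#' @return epithelial height in micrometres (`NA_real_` if `lumen` is NULL).
#' @export
epithelial_height <- function(outer, lumen, pixel_size) {
  stopifnot(is.finite(pixel_size), pixel_size > 0)
  if (is.null(lumen)) return(NA_real_)
  shape <- pmax(apply(outer$coords, 2, max), apply(lumen$coords, 2, max)) + 3L
  outer_mask <- fill_interior(outer, shape)
  lum_in <- lumen$coords + 1L
  if (!all(outer_mask[lum_in]))
    stop("lumen contour is not contained in the outer contour")
  ob <- unique(outer$coords) + 1L
  lb <- unique(lum_in)
  d_ol <- mean(nearest_boundary_dist(lb, shape)[ob])
  d_lo <- mean(nearest_boundary_dist(ob, shape)[lb])
  (d_ol + d_lo) / 2 * pixel_size
}

# exact Euclidean distance transform to a pixel set (EBImage::distmap on a
# field that is zero exactly on the given pixels)
nearest_boundary_dist <- function(pix1based, shape) {
  m <- matrix(1, shape[1], shape[2])
  m[pix1based] <- 0
  as.matrix(EBImage::distmap(m, metric = "euclidean"))
}

#' Measure all endpoints of one tubule
#'
#' @param outer closed outer [contour()].
#' @param lumen closed lumen [contour()] or `NULL`.
#' @param pixel_size calibration in micrometres per pixel.
#' @param tubule_id identifier carried into the result.
#' @return one-row data.frame with columns `tubule_id`, `area_mm2`,
#'   `diameter_um`, `epithelial_height_um`, `has_lumen`, `pixel_size`.
#' @export
measure_tubules <- function(outer, lumen = NULL, pixel_size,
                            tubule_id = NA_character_) {
  area <- tubule_area(outer, pixel_size)
  diam <- tubule_diameter(outer, pixel_size)
  eh <- epithelial_height(outer, lumen, pixel_size)
  if (!is.na(eh) && !(eh > 0 && eh < diam / 2))
    warning(sprintf(
      "tubule %s: epithelial height %.3g um outside (0, diameter/2)",
      tubule_id, eh))
  data.frame(tubule_id = tubule_id, area_mm2 = area, diameter_um = diam,
             epithelial_height_um = eh, has_lumen = !is.null(lumen),
             pixel_size = pixel_size, stringsAsFactors = FALSE)
}

#' Write / read tubule measurement tables
#'
#' Measurement CSVs carry columns `animal_id`, `group`, `tubule_id`,
#' `area_mm2`, `diameter_um`, `epithelial_height_um`, `has_lumen`.
#'
#' @param df measurements data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_measurements <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
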