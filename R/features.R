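#' Edge-detector parameters
#'
#' Scales and thresholds of the three edge detectors feeding the livewire
#' cost function. All scales are in pixels.
#'
#' @param smoothing_scale standard deviation of the Gaussian pre-smoothing
#'   applied before gradient and Canny computation (>= 0; 0 disables
#'   smoothing).
#' @param canny_low,canny_high hysteresis thresholds of the Canny detector as
#'   fractions of the maximum gradient magnitude; `0 <= canny_low <
#'   canny_high <= 1`.
#' @param zero_crossing_scale standard deviation of the
#'   Laplacian-of-Gaussian filter whose sign changes mark zero-crossing
#'   edges (> 0).
#' @param zc_slope_frac minimum slope of the Laplacian across a sign change,
#'   as a fraction of the mean absolute Laplacian, for the crossing to count
#'   as an edge (suppresses crossings in flat noise; the classical
#'   edge-detector default is 0.75).
#' @return an object of class `feature_params`.
#' @export
feature_params <- function(smoothing_scale = 1.0, canny_low = 0.1,
                           canny_high = 0.2, zero_crossing_scale = 2.0,
                           zc_slope_frac = 0.75) {
  stopifnot(is.finite(smoothing_scale), smoothing_scale >= 0,
            is.finite(zero_crossing_scale), zero_crossing_scale > 0,
            is.finite(canny_low), is.finite(canny_high),
            is.finite(zc_slope_frac), zc_slope_frac >= 0)
  if (!(canny_low >= 0 && canny_low < canny_high && canny_high <= 1))
    stop("need 0 <= canny_low < canny_high <= 1")
  structure(list(smoothing_scale = smoothing_scale,
                 canny_low = canny_low, canny_high = canny_high,
                 zero_crossing_scale = zero_crossing_scale,
                 zc_slope_frac = zc_slope_frac),
            class = "feature_params")
}

## ---- small image-processing kernel (reflect padding throughout) ----------

# shift a matrix by (dr, dc), filling exposed rows/cols by 101-reflection
shift_reflect <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  ri <- ifelse(ri < 1L, 2L - ri, ifelse(ri > nr, 2L * nr - ri, ri))
  ci <- ifelse(ci < 1L, 2L - ci, ifelse(ci > nc, 2L * nc - ci, ci))
  m[ri, ci, drop = FALSE]
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with reflect padding, via shift-and-add
conv_sep <- function(m, k) {
  if (length(k) == 1L) return(m * k)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_reflect(m, i - r - 1L, 0L)
  m <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_reflect(m, 0L, i - r - 1L)
  out
}

gauss_smooth <- function(m, sigma) conv_sep(m, gaussian_kernel(sigma))

# central-difference gradient components (per unit pixel)
grad_rc <- function(m) {
  list(gr = (shift_reflect(m, 1L, 0L) - shift_reflect(m, -1L, 0L)) / 2,
       gc = (shift_reflect(m, 0L, 1L) - shift_reflect(m, 0L, -1L)) / 2)
}

# 4-neighbour discrete Laplacian
laplacian4 <- function(m) {
  shift_reflect(m, 1L, 0L) + shift_reflect(m, -1L, 0L) +
    shift_reflect(m, 0L, 1L) + shift_reflect(m, 0L, -1L) - 4 * m
}

## ---- detectors ------------------------------------------------------------

# Laplacian-of-Gaussian zero-crossing map: TRUE on edge pixels.
# A pixel is a crossing if the LoG changes sign towards a 4-neighbour, the
# pixel is the side nearer zero (ties mark both sides), and the jump across
# the crossing exceeds slope_frac * mean(|LoG|).
zero_crossing_edges <- function(gray, scale, slope_frac) {
  L <- laplacian4(gauss_smooth(gray, scale))
  thr <- slope_frac * mean(abs(L))
  edge <- matrix(FALSE, nrow(L), ncol(L))
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    Ln <- shift_reflect(L, d[1], d[2])
    cross <- (L * Ln < 0) & (abs(L) <= abs(Ln)) & (abs(L - Ln) > thr)
    edge <- edge | cross
  }
  edge
}

# Canny edge map on a (pre-smoothed) grayscale image: TRUE on edge pixels.
canny_edges <- function(gray, sigma, low_frac, high_frac) {
  g <- grad_rc(gauss_smooth(gray, sigma))
  mag <- sqrt(g$gr^2 + g$gc^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(gray), ncol(gray)))

  # quantize gradient orientation into 4 sectors (mod pi)
  a <- atan2(g$gc, g$gr)
  a <- ifelse(a < 0, a + pi, a)
  sector <- as.integer(round(a / (pi / 4))) %% 4L

  nms <- matrix(FALSE, nrow(gray), ncol(gray))
  nbr <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  for (s in 0:3) {
    d <- nbr[[s + 1L]]
    keep <- (mag >= shift_reflect(mag, d[1], d[2])) &
            (mag >= shift_reflect(mag, -d[1], -d[2]))
    nms <- nms | (keep & (sector == s))
  }
  nms <- nms & (mag > 0)

  strong <- nms & (mag >= high_frac * mmax)
  weak   <- nms & (mag >= low_frac * mmax)

  # hysteresis: grow strong set through weak pixels (8-connected) to fixpoint
  cur <- strong
  repeat {
    grown <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      grown <- grown | shift_reflect(cur, dr, dc)
    }
    grown <- grown & weak
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

## ---- feature stack --------------------------------------------------------

#' Compute the edge-feature stack driving the livewire cost
#'
#' Produces the four per-pixel edge measures combined by [link_cost()]:
#' a Laplacian zero-crossing map `f_z`, a Canny edge map `f_c` (both coded
#' 0 on an edge pixel and 1 elsewhere, so that edges are cheap), the
#' inverted min-max-normalized gradient magnitude `f_G = 1 - G/G_max`, and
#' the per-pixel edge tangent `direction` (unit vector perpendicular to the
#' gradient; the zero vector where the gradient vanishes).
#'
#' For multichannel images the gradient magnitude and direction come from
#' the multichannel vector gradient: the leading eigenvalue/eigenvector of
#' the local structure tensor summed over channels (Di Zenzo), so that color
#' edges invisible in any single channel are still detected. A
#' single-channel image degrades exactly to the ordinary gradient. The
#' binary detectors operate on the luminance channel.
#'
#' @param image a [calibrated_image] (or numeric matrix/array accepted by
#'   [calibrated_image()] with `pixel_size = 1`).
#' @param params a [feature_params] object.
#' @return an object of class `feature_stack`: list with matrices `f_z`,
#'   `f_c`, `f_G`, `dir_r`, `dir_c` all of the image shape.
#' @export
compute_feature_stack <- function(image, params = feature_params()) {
  if (!inherits(image, "calibrated_image")) image <- calibrated_image(image, 1)
  if (!inherits(params, "feature_params")) stop("`params` must be feature_params()")
  px <- image$pixels
  nch <- dim(px)[3]

  # structure tensor over channels of the smoothed image
  E <- FF <- G <- 0
  for (k in seq_len(nch)) {
    g <- grad_rc(gauss_smooth(px[, , k], params$smoothing_scale))
    E  <- E  + g$gr^2
    FF <- FF + g$gr * g$gc
    G  <- G  + g$gc^2
  }
  lam <- ((E + G) + sqrt((E - G)^2 + 4 * FF^2)) / 2
  mag <- sqrt(pmax(lam, 0))

  theta <- 0.5 * atan2(2 * FF, E - G)   # gradient orientation (mod pi)
  gr_u <- cos(theta); gc_u <- sin(theta)
  # edge tangent: perpendicular to the gradient
  dir_r <- -gc_u; dir_c <- gr_u
  zero <- mag == 0
  dir_r[zero] <- 0; dir_c[zero] <- 0

  mmax <- max(mag)
  f_G <- if (mmax == 0) matrix(1, nrow(mag), ncol(mag)) else 1 - mag / mmax

  gray <- as_gray(image)
  f_z <- 1 - zero_crossing_edges(gray, params$zero_crossing_scale,
                                 params$zc_slope_frac)
  f_c <- 1 - canny_edges(gray, params$smoothing_scale,
                         params$canny_low, params$canny_high)
  storage.mode(f_z) <- "double"
  storage.mode(f_c) <- "double"

  structure(list(f_z = f_z, f_c = f_c, f_G = f_G,
                 dir_r = dir_r, dir_c = dir_c),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d x %d px; %d zero-crossing px, %d Canny px\n",
              nrow(x$f_G), ncol(x$f_G), sum(x$f_z == 0), sum(x$f_c == 0)))
  invisible(x)
}

#' Write feature maps to disk for inspection
#'
#' Dumps `f_z`, `f_c` and `f_G` as grayscale TIFF files named
#' `<prefix>_fz.tif`, `<prefix>_fc.tif`, `<prefix>_fG.tif`.
#'
#' @param stack a `feature_stack`.
#' @param prefix output path prefix.
#' @return character vector of paths written, invisibly.
#' @export
write_feature_maps <- function(stack, prefix) {
  paths <- c(fz = paste0(prefix, "_fz.tif"),
             fc = paste0(prefix, "_fc.tif"),
             fG = paste0(prefix, "_fG.tif"))
  tiff::writeTIFF(stack$f_z, paths["fz"], bits.per.sample = 16L)
  tiff::writeTIFF(stack$f_c, paths["fc"], bits.per.sample = 16L)
  tiff::writeTIFF(stack$f_G, paths["fG"], bits.per.sample = 16L)
  invisible(paths)
}
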