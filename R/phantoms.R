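# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specification of a synthetic tubule phantom image
#'
#' Describes a stylized stained testis cross-section: bright interstitium
#' background, darker annular epithelium around a pale lumen disc, plus
#' additive pixel noise and a low-frequency texture. Region interfaces are
#' rendered with a 1-px anti-aliased blend, so the true boundary is the
#' sub-pixel location of the gradient maximum and the analytic geometry is
#' the correct ground truth for a traced contour.
#'
#' @param size integer `(rows, cols)` image size in pixels.
#' @param pixel_size calibration in micrometres per pixel.
#' @param tubules data.frame with one row per tubule: `center_r`,
#'   `center_c` (0-based pixel coordinates), `outer_um` (outer radius),
#'   `lumen_um` (lumen radius, `NA` for occluded lumen), `ellipticity`
#'   (in \[0, 1); 0 = circle; the column-axis semi-axis is shrunk by
#'   `1 - ellipticity`).
#' @param palette list of RGB triplets in \[0, 1\]: `interstitium`,
#'   `epithelium`, `lumen`.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity units; the default epithelium/interstitium luminance
#'   contrast is about 0.35).
#' @param texture_amp amplitude of the smooth low-frequency texture field.
#' @param seed integer random seed; fixed seed gives bit-identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(512L, 512L), pixel_size = 1.0,
                         tubules,
                         palette = list(interstitium = c(0.93, 0.78, 0.82),
                                        epithelium  = c(0.55, 0.35, 0.55),
                                        lumen       = c(0.96, 0.93, 0.95)),
                         noise_sd = 0.02, texture_amp = 0.02, seed = 1L) {
  size <- as.integer(size)
  stopifnot(length(size) == 2L, all(size >= 16L),
            is.finite(pixel_size), pixel_size > 0,
            is.data.frame(tubules), nrow(tubules) >= 1L,
            noise_sd >= 0, texture_amp >= 0)
  need <- c("center_r", "center_c", "outer_um")
  if (!all(need %in% names(tubules)))
    stop("`tubules` needs columns: ", paste(need, collapse = ", "))
  if (is.null(tubules$lumen_um)) tubules$lumen_um <- NA_real_
  if (is.null(tubules$ellipticity)) tubules$ellipticity <- 0
  stopifnot(all(tubules$outer_um > 0),
            all(is.na(tubules$lumen_um) | tubules$lumen_um > 0),
            all(tubules$ellipticity >= 0 & tubules$ellipticity < 1))
  if (any(!is.na(tubules$lumen_um) & tubules$lumen_um >= tubules$outer_um))
    stop("lumen radius must be smaller than outer radius")

  # semi-axes in pixels
  a <- tubules$outer_um / pixel_size
  b <- a * (1 - tubules$ellipticity)
  rmax <- pmax(a, b)
  if (any(tubules$center_r - rmax < 1 | tubules$center_r + rmax > size[1] - 2 |
          tubules$center_c - rmax < 1 | tubules$center_c + rmax > size[2] - 2))
    stop("tubule extends outside the image")
  n <- nrow(tubules)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- sqrt((tubules$center_r[i] - tubules$center_r[j])^2 +
                (tubules$center_c[i] - tubules$center_c[j])^2)
      if (d <= rmax[i] + rmax[j] + 2)
        stop(sprintf("tubules %d and %d overlap", i, j))
    }
  }
  structure(list(size = size, pixel_size = pixel_size, tubules = tubules,
                 palette = palette, noise_sd = noise_sd,
                 texture_amp = texture_amp, seed = as.integer(seed)),
            class = "phantom_spec")
}

# numeric ground truth for one tubule of a phantom_spec (micrometre units)
tubule_truth <- function(a_um, b_um, lumen_a_um, lumen_b_um) {
  area_mm2 <- pi * a_um * b_um * 1e-6
  if (a_um == b_um) {
    diameter_um <- 2 * a_um
    height_um <- if (is.na(lumen_a_um)) NA_real_ else a_um - lumen_a_um
  } else {
    # mean boundary-to-centre distance, arclength-weighted quadrature
    th <- seq(0, 2 * pi, length.out = 20001L)[-1]
    x <- a_um * cos(th); y <- b_um * sin(th)
    dx <- -a_um * sin(th); dy <- b_um * cos(th)
    wgt <- sqrt(dx^2 + dy^2)
    diameter_um <- 2 * sum(sqrt(x^2 + y^2) * wgt) / sum(wgt)
    if (is.na(lumen_a_um)) height_um <- NA_real_ else {
      xl <- lumen_a_um * cos(th); yl <- lumen_b_um * sin(th)
      near <- function(px, py, qx, qy) {
        sapply(seq_along(px), function(i)
          min(sqrt((px[i] - qx)^2 + (py[i] - qy)^2)))
      }
      s1 <- seq(1, length(th), by = 40L)  # subsample for the all-pairs min
      height_um <- (mean(near(x[s1], y[s1], xl, yl)) +
                    mean(near(xl[s1], yl[s1], x, y))) / 2
    }
  }
  c(area_mm2 = area_mm2, diameter_um = diameter_um, height_um = height_um)
}

#' Render a phantom image with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [calibrated_image], RGB) and `truth`
#'   (data.frame: `tubule_id`, analytic `area_mm2`, `diameter_um`,
#'   `epithelial_height_um`, `has_lumen`).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  rr <- matrix(seq_len(h) - 1L, h, w)
  cc <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)

  px <- array(0, dim = c(h, w, 3))
  for (k in 1:3) px[, , k] <- spec$palette$interstitium[k]

  truth <- NULL
  for (i in seq_len(nrow(spec$tubules))) {
    tb <- spec$tubules[i, ]
    a <- tb$outer_um / spec$pixel_size
    b <- a * (1 - tb$ellipticity)
    dr <- rr - tb$center_r; dc <- cc - tb$center_c
    # signed distance to the ellipse, first-order (exact for circles)
    rho <- sqrt((dr / a)^2 + (dc / b)^2)
    gn <- sqrt((dr / a^2)^2 + (dc / b^2)^2)
    sd_out <- ifelse(gn > 0, (rho - 1) / gn, -pmax(a, b))
    cov_o <- pmin(pmax(0.5 - sd_out, 0), 1)

    has_lumen <- !is.na(tb$lumen_um)
    if (has_lumen) {
      la <- tb$lumen_um / spec$pixel_size
      lb <- la * (1 - tb$ellipticity)
      rho_l <- sqrt((dr / la)^2 + (dc / lb)^2)
      gn_l <- sqrt((dr / la^2)^2 + (dc / lb^2)^2)
      sd_l <- ifelse(gn_l > 0, (rho_l - 1) / gn_l, -pmax(la, lb))
      cov_l <- pmin(pmax(0.5 - sd_l, 0), 1)
    } else cov_l <- 0

    for (k in 1:3) {
      px[, , k] <- px[, , k] * (1 - cov_o) +
        spec$palette$epithelium[k] * (cov_o - cov_l) +
        spec$palette$lumen[k] * cov_l
    }

    tt <- tubule_truth(tb$outer_um, tb$outer_um * (1 - tb$ellipticity),
                       tb$lumen_um,
                       if (has_lumen) tb$lumen_um * (1 - tb$ellipticity)
                       else NA_real_)
    truth <- rbind(truth, data.frame(
      tubule_id = sprintf("t%02d", i), area_mm2 = tt[["area_mm2"]],
      diameter_um = tt[["diameter_um"]],
      epithelial_height_um = tt[["height_um"]], has_lumen = has_lumen))
  }

  # generator-splitting: texture from seed + 1, pixel noise from seed + 2
  if (spec$texture_amp > 0) {
    tex <- with_seed(spec$seed + 1L, {
      fr <- stats::runif(2, 0.5, 2.5) / c(h, w)
      ph <- stats::runif(2, 0, 2 * pi)
      spec$texture_amp * sin(2 * pi * fr[1] * rr + ph[1]) *
        sin(2 * pi * fr[2] * cc + ph[2])
    })
    for (k in 1:3) px[, , k] <- px[, , k] + tex
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed + 2L,
                       matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
    for (k in 1:3) px[, , k] <- px[, , k] + noise
  }
  px <- pmin(pmax(px, 0), 1)
  list(image = calibrated_image(px, spec$pixel_size), truth = truth)
}

#' Place seed points on a phantom's true boundary
#'
#' Returns `n` pixel positions equally spaced in angle on the analytic
#' outer (or lumen) boundary of one tubule, rounded to the pixel grid --
#' the scripted stand-in for the user's boundary clicks.
#'
#' @param spec a [phantom_spec()].
#' @param tubule index of the tubule in `spec$tubules`.
#' @param n number of seeds.
#' @param boundary `"outer"` or `"lumen"`.
#' @return n x 2 integer matrix of 0-based (row, col) seed pixels.
#' @export
phantom_seeds <- function(spec, tubule = 1L, n = 16L, boundary = "outer") {
  tb <- spec$tubules[tubule, ]
  r_um <- if (boundary == "lumen") tb$lumen_um else tb$outer_um
  if (is.na(r_um)) stop("tubule ", tubule, " has no lumen")
  a <- r_um / spec$pixel_size
  b <- a * (1 - tb$ellipticity)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pts <- cbind(row = as.integer(round(tb$center_r + a * cos(th))),
               col = as.integer(round(tb$center_c + b * sin(th))))
  pts[!duplicated(pts), , drop = FALSE]
}

#' Lay out non-overlapping tubules on a grid
#'
#' Convenience constructor of the `tubules` table of a [phantom_spec()]:
#' places `n` tubules in a grid-like pattern (no overlap) with radii drawn
#' uniformly from the given ranges.
#'
#' @param n number of tubules.
#' @param size image size `(rows, cols)` in pixels.
#' @param pixel_size micrometres per pixel.
#' @param outer_um_range,lumen_frac_range ranges of the outer radius (um)
#'   and of the lumen/outer radius ratio.
#' @param seed integer random seed.
#' @return data.frame suitable as the `tubules` argument of [phantom_spec()].
#' @export
grid_tubules <- function(n, size = c(512L, 512L), pixel_size = 1.0,
                         outer_um_range = c(55, 110) * pixel_size,
                         lumen_frac_range = c(0.4, 0.6), seed = 1L) {
  with_seed(seed, {
    k <- ceiling(sqrt(n))
    cell_r <- size[1] / k; cell_c <- size[2] / k
    rmax_px <- max(outer_um_range) / pixel_size
    if (min(cell_r, cell_c) / 2 - 2 <= rmax_px)
      stop("tubules too large for a non-overlapping grid layout")
    idx <- seq_len(n) - 1L
    outer <- stats::runif(n, outer_um_range[1], outer_um_range[2])
    data.frame(
      center_r = (idx %/% k + 0.5) * cell_r,
      center_c = (idx %% k + 0.5) * cell_c,
      outer_um = outer,
      lumen_um = outer * stats::runif(n, lumen_frac_range[1],
                                      lumen_frac_range[2]),
      ellipticity = 0)
  })
}
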