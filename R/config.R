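#' Pipeline configuration
#'
#' Flat configuration shared by the command-line pipeline. Serializes
#' losslessly to a `key = value` text file.
#'
#' @param pixel_size micrometres per pixel; required by any command that
#'   emits physical units (no default is assumed silently).
#' @param smoothing_scale,canny_low,canny_high,zero_crossing_scale,zc_slope_frac
#'   see [feature_params()].
#' @param w_z,w_c,w_G,w_D,diagonal_scaling see [link_cost_model()].
#' @param alpha significance level for the statistics command.
#' @param seed integer random seed.
#' @param out_dir output directory.
#' @param log_level one of `"quiet"`, `"info"`, `"debug"`; log lines go to
#'   standard error, results only to files.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = NA_real_,
                            smoothing_scale = 1.0, canny_low = 0.1,
                            canny_high = 0.2, zero_crossing_scale = 2.0,
                            zc_slope_frac = 0.75,
                            w_z = 4, w_c = 4, w_G = 1, w_D = 1,
                            diagonal_scaling = TRUE,
                            alpha = 0.05, seed = 1L, out_dir = ".",
                            log_level = "info") {
  cfg <- list(pixel_size = as.numeric(pixel_size),
              smoothing_scale = as.numeric(smoothing_scale),
              canny_low = as.numeric(canny_low),
              canny_high = as.numeric(canny_high),
              zero_crossing_scale = as.numeric(zero_crossing_scale),
              zc_slope_frac = as.numeric(zc_slope_frac),
              w_z = as.numeric(w_z), w_c = as.numeric(w_c),
              w_G = as.numeric(w_G), w_D = as.numeric(w_D),
              diagonal_scaling = isTRUE(as.logical(diagonal_scaling)),
              alpha = as.numeric(alpha), seed = as.integer(seed),
              out_dir = as.character(out_dir),
              log_level = match.arg(log_level, c("quiet", "info", "debug")))
  # constructing the sub-objects validates the numeric fields
  feature_params(cfg$smoothing_scale, cfg$canny_low, cfg$canny_high,
                 cfg$zero_crossing_scale, cfg$zc_slope_frac)
  link_cost_model(cfg$w_z, cfg$w_c, cfg$w_G, cfg$w_D, cfg$diagonal_scaling)
  stopifnot(cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

config_features <- function(cfg)
  feature_params(cfg$smoothing_scale, cfg$canny_low, cfg$canny_high,
                 cfg$zero_crossing_scale, cfg$zc_slope_frac)

config_model <- function(cfg)
  link_cost_model(cfg$w_z, cfg$w_c, cfg$w_G, cfg$w_D, cfg$diagonal_scaling)

require_pixel_size <- function(cfg) {
  if (!is.finite(cfg$pixel_size) || cfg$pixel_size <= 0)
    stop("pixel_size (um/px) is required for physical measurements; ",
         "set it in the config or with --pixel-size")
  cfg$pixel_size
}

#' Write / read a pipeline configuration file
#'
#' The format is one `key = value` pair per line; unknown keys are
#' rejected. Round-trips losslessly (`read_config(write_config(cfg))` is
#' identical to `cfg`).
#'
#' @param cfg a [pipeline_config()].
#' @param path text file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    s <- if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    paste0(k, " = ", s)
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  m <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- which(vapply(m, length, integer(1)) != 3L)
  if (length(bad)) stop("malformed config line(s): ",
                        paste(lines[bad], collapse = "; "))
  kv <- stats::setNames(vapply(m, `[`, character(1), 3L),
                        vapply(m, `[`, character(1), 2L))
  args <- as.list(kv)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  num <- setdiff(known, c("out_dir", "log_level", "diagonal_scaling", "seed"))
  for (k in intersect(names(args), num)) args[[k]] <- as.numeric(args[[k]])
  if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
  if (!is.null(args$diagonal_scaling))
    args$diagonal_scaling <- as.logical(args$diagonal_scaling)
  do.call(pipeline_config, args)
}

log_msg <- function(cfg, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[cfg$log_level]] >= lv[[level]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  invisible(NULL)
}
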