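#' Pipeline command: compute and dump feature maps
#'
#' Wraps [compute_feature_stack()] for a single image file; feature maps are
#' written as TIFF next to `prefix`.
#'
#' @param image_path PNG or TIFF image file.
#' @param cfg a [pipeline_config()].
#' @param prefix output path prefix; default: image name in `cfg$out_dir`.
#' @return paths of the written maps, invisibly.
#' @export
cmd_features <- function(image_path, cfg = pipeline_config(), prefix = NULL) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path)
  ps <- if (is.finite(cfg$pixel_size)) cfg$pixel_size else 1.0
  img <- read_image(image_path, ps)
  stack <- withCallingHandlers(
    compute_feature_stack(img, config_features(cfg)),
    error = function(e) stop("while processing ", image_path, ": ",
                             conditionMessage(e)))
  if (is.null(prefix))
    prefix <- file.path(cfg$out_dir,
                        tools::file_path_sans_ext(basename(image_path)))
  log_msg(cfg, "info", "features: ", image_path)
  write_feature_maps(stack, prefix)
}

#' Pipeline command: trace tubule contours from seed lists
#'
#' Reads ordered seed points per tubule (and optional lumen seed lists),
#' traces closed livewire contours on the image, and writes a contour CSV.
#'
#' @param image_path PNG or TIFF image file.
#' @param seeds_path seed CSV (see [read_seeds()]).
#' @param out_path output contour CSV.
#' @param cfg a [pipeline_config()].
#' @return `out_path` invisibly, or `NULL` (with a warning) when the seed
#'   file holds no seeds.
#' @export
cmd_trace <- function(image_path, seeds_path, out_path,
                      cfg = pipeline_config()) {
  seeds <- read_seeds(seeds_path)
  if (!length(seeds)) {
    warning("no seeds in ", seeds_path, "; nothing traced")
    return(invisible(NULL))
  }
  ps <- if (is.finite(cfg$pixel_size)) cfg$pixel_size else 1.0
  img <- read_image(image_path, ps)
  stack <- compute_feature_stack(img, config_features(cfg))
  model <- config_model(cfg)
  contours <- lapply(seeds, function(s) {
    out <- list(outer = trace_closed_contour(s$outer, stack, model))
    if (!is.null(s$lumen))
      out$lumen <- trace_closed_contour(s$lumen, stack, model)
    out
  })
  log_msg(cfg, "info", "traced ", length(contours), " tubule(s)")
  write_contours(contours, out_path)
}

#' Pipeline command: measure contours
#'
#' Converts a contour CSV into the tubule measurement table (area in mm^2,
#' diameter and epithelial height in micrometres). Requires a calibrated
#' `pixel_size`.
#'
#' @param contours_path contour CSV (see [read_contours()]).
#' @param out_path output measurement CSV.
#' @param cfg a [pipeline_config()]; `pixel_size` must be set.
#' @param animal_id,group optional labels copied into every row.
#' @return `out_path`, invisibly.
#' @export
cmd_measure <- function(contours_path, out_path, cfg = pipeline_config(),
                        animal_id = NA_character_, group = NA_character_) {
  ps <- require_pixel_size(cfg)
  contours <- read_contours(contours_path)
  rows <- lapply(names(contours), function(id)
    measure_tubules(contours[[id]]$outer, contours[[id]]$lumen, ps, id))
  df <- do.call(rbind, rows)
  df <- cbind(animal_id = animal_id, group = group, df)
  log_msg(cfg, "info", "measured ", nrow(df), " tubule(s)")
  write_measurements(df, out_path)
}

#' Pipeline command: endpoint statistics
#'
#' Runs the study's statistical layer on a tubule measurement CSV and/or a
#' gross endpoint CSV (`animal_id`, `group`, `body_weight_kg`,
#' `testis_weight_g`, `testis_length_cm`): hierarchical ANOVA for the
#' morphometric endpoints, one-way ANOVA for the gross endpoints, Tukey
#' pairwise correction and compact letter display. An explicit group subset
#' selects the model variant (e.g. the time model over the five delay
#' groups, or the freeze model over 0 h, 6 h and 6 h + frozen).
#'
#' @param measurements_path tubule measurement CSV, or `NULL`.
#' @param gross_path gross endpoint CSV, or `NULL`.
#' @param out_prefix output prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @param cfg a [pipeline_config()].
#' @param groups optional character vector restricting the analysis to a
#'   subset of groups (model-variant flag).
#' @return the results data.frame, invisibly; also written as CSV and JSON.
#' @export
cmd_stats <- function(measurements_path = NULL, gross_path = NULL,
                      out_prefix, cfg = pipeline_config(), groups = NULL) {
  tub <- if (!is.null(measurements_path)) read_measurements(measurements_path)
  gross <- if (!is.null(gross_path))
    utils::read.csv(gross_path, stringsAsFactors = FALSE)
  res <- endpoint_results(tub, gross, alpha = cfg$alpha, groups = groups)
  utils::write.csv(res, paste0(out_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(res, paste0(out_prefix, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_msg(cfg, "info", "stats: ", nrow(res), " endpoint(s)")
  invisible(res)
}

#' Endpoint results table
#'
#' Assembles the per-endpoint results layout: one row per endpoint with
#' per-group `mean+-SE` and letters, numerator/denominator degrees of
#' freedom, F and p. Morphometric endpoints use [nested_anova()]; gross
#' endpoints use [one_way_anova()].
#'
#' @param tubules tubule measurement data.frame
#'   (`animal_id`, `group`, `tubule_id`, endpoint columns), or `NULL`.
#' @param animals gross endpoint data.frame (`animal_id`, `group`, endpoint
#'   columns), or `NULL`.
#' @param alpha significance level for the letters.
#' @param groups optional group subset (model variant).
#' @return data.frame with columns `endpoint`, one `mean_se_<group>` per
#'   group, `letters`, `num_df`, `den_df`, `F`, `p_value`.
#' @export
endpoint_results <- function(tubules = NULL, animals = NULL, alpha = 0.05,
                             groups = NULL) {
  one <- function(df, endpoint, kind) {
    tab <- data.frame(animal_id = df$animal_id, group = df$group,
                      value = df[[endpoint]], stringsAsFactors = FALSE)
    tab <- tab[!is.na(tab$value), ]
    if (!is.null(groups)) tab <- tab[tab$group %in% groups, ]
    if (length(unique(tab$group)) < 2L)
      stop("endpoint ", endpoint, ": need at least 2 groups")
    fit <- letter_display(tukey_pairwise(tubule_anova(tab, alpha, kind)))
    gr <- fit$groups
    cells <- stats::setNames(sprintf("%.4g±%.3g %s", gr$mean, gr$se,
                                     fit$letters[gr$group]),
                             paste0("mean_se_", gr$group))
    c(list(endpoint = endpoint), as.list(cells),
      list(letters = paste(fit$letters[gr$group], collapse = "/"),
           num_df = fit$num_df, den_df = fit$den_df, F = fit$F,
           p_value = fit$p_value))
  }
  rows <- list()
  if (!is.null(animals))
    for (e in intersect(c("body_weight_kg", "testis_weight_g",
                          "testis_length_cm"), names(animals)))
      rows[[e]] <- one(animals, e, "one_way")
  if (!is.null(tubules))
    for (e in intersect(c("area_mm2", "diameter_um", "epithelial_height_um"),
                        names(tubules)))
      rows[[e]] <- one(tubules, e, "nested")
  if (!length(rows)) stop("no endpoint columns found")
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Pipeline command: simulate phantoms and study tables
#'
#' Renders a phantom image (PNG plus ground-truth CSV) and simulates the
#' study tables (tubule and gross endpoint CSVs) into `cfg$out_dir`. Two
#' runs with the same config are byte-identical.
#'
#' @param cfg a [pipeline_config()]; `seed` drives all randomness.
#' @param n_tubules tubules placed on the phantom image.
#' @param design a [study_design()]; its seed is replaced by `cfg$seed`.
#' @return named character vector of output paths, invisibly.
#' @export
cmd_simulate <- function(cfg = pipeline_config(), n_tubules = 4L,
                         design = study_design()) {
  ps <- if (is.finite(cfg$pixel_size)) cfg$pixel_size else 1.0
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- phantom_spec(size = c(512L, 512L), pixel_size = ps,
                       tubules = grid_tubules(n_tubules, c(512L, 512L), ps,
                                              seed = cfg$seed),
                       seed = cfg$seed)
  ph <- render_phantom(spec)
  design$seed <- cfg$seed
  sim <- simulate_study(design)
  paths <- c(image = file.path(cfg$out_dir, "phantom.png"),
             truth = file.path(cfg$out_dir, "phantom_truth.csv"),
             tubules = file.path(cfg$out_dir, "tubules.csv"),
             animals = file.path(cfg$out_dir, "animals.csv"))
  write_image(ph$image, paths[["image"]])
  utils::write.csv(ph$truth, paths[["truth"]], row.names = FALSE)
  utils::write.csv(sim$tubules, paths[["tubules"]], row.names = FALSE)
  utils::write.csv(sim$animals, paths[["animals"]], row.names = FALSE)
  log_msg(cfg, "info", "simulated ", n_tubules, " phantom tubule(s), ",
          nrow(sim$animals), " animals")
  invisible(paths)
}
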