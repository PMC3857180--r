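# Configuration handling and the end-to-end pipeline driver.

config_template <- function() list(
  global = list(resize_factor = 0.25, intensity_min = 0,
                intensity_max = 255, seed = 1L, polarity = "dark"),
  preprocess = list(ball_radius_px = 25, ball_height = 40,
                    clahe_clip = 2.5, clahe_tiles = c(8L, 8L),
                    border_gauss_size_px = 7L, border_gauss_sigma = 2,
                    border_threshold = 128, border_gain = 0.5),
  levelset = list(lambda_in = 1, lambda_out = 1, mu_length = 650,
                  epsilon = 1, dt = 5e-4, n_iter = 200,
                  init_mode = "otsu_mask"),
  binary = list(disk_radius_px = 2, min_area_px = 500, h_merge = 4),
  detect = list(diffusion_iters = 10L, diffusion_kappa = 50,
                diffusion_dt = 0.2, r1 = 6, r2 = 9, radius_step = 1,
                score_threshold = 4, min_separation_px = 6,
                gradient_floor = 1),
  stats = list(alpha = 0.001, multiplier = 10L, lower_cut = 0.95,
               smoothing_window = 3L),
  eval = list(match_tolerance_px = 9)
)

#' Default pipeline configuration
#'
#' Nested named list with sections `global`, `preprocess`, `levelset`,
#' `binary`, `detect`, `stats`, `eval`.  The radius band defaults
#' (`r1 = 6`, `r2 = 9`, `radius_step = 1`) are the chromogenic
#' (Zscan4-like) profile; see [preset_config()] for the other marker
#' profiles.  `alpha = 0.001` and the 10x null multiplier are the
#' published analysis settings; most image-processing defaults are
#' phantom-calibrated (the published parameter table is not fully
#' legible) and are documented as such in the methods vignette.
#'
#' @return the configuration list.
#' @export
default_config <- function() config_template()

#' Per-marker parameter presets
#'
#' Named radius-band profiles mirroring the four marker columns of the
#' published parameter table: `zscan4` (6, 9, 1), `endoa` (4, 10, 1),
#' `nanog` (10, 25, 2), `pou5f1` (10, 24, 2).  The fluorescence-derived
#' profiles (`nanog`, `pou5f1`) use bright polarity.
#'
#' @param preset one of `"zscan4"`, `"endoa"`, `"nanog"`, `"pou5f1"`.
#' @return a configuration list.
#' @export
preset_config <- function(preset = c("zscan4", "endoa", "nanog", "pou5f1")) {
  preset <- match.arg(preset)
  cfg <- default_config()
  band <- switch(preset,
    zscan4 = list(r1 = 6, r2 = 9, radius_step = 1, polarity = "dark"),
    endoa  = list(r1 = 4, r2 = 10, radius_step = 1, polarity = "dark"),
    nanog  = list(r1 = 10, r2 = 25, radius_step = 2, polarity = "bright"),
    pou5f1 = list(r1 = 10, r2 = 24, radius_step = 2, polarity = "bright"))
  cfg$detect$r1 <- band$r1
  cfg$detect$r2 <- band$r2
  cfg$detect$radius_step <- band$radius_step
  cfg$detect$min_separation_px <- band$r1
  cfg$eval$match_tolerance_px <- band$r2
  cfg$global$polarity <- band$polarity
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the section/key structure against the template (unknown
#' sections or keys are rejected) and the documented parameter bounds.
#'
#' @param config a configuration list.
#' @return the validated config, invisibly; errors otherwise.
#' @export
validate_config <- function(config) {
  tmpl <- config_template()
  extra <- setdiff(names(config), names(tmpl))
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(tmpl[[sec]]))
    if (length(bad))
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
  }
  g <- config$global
  stopifnot(g$resize_factor > 0, g$resize_factor <= 1,
            g$polarity %in% c("dark", "bright"),
            g$intensity_min == 0, g$intensity_max == 255)
  d <- config$detect
  stopifnot(d$r1 > 0, d$r2 > d$r1, d$radius_step > 0,
            d$diffusion_dt <= 0.25)
  s <- config$stats
  stopifnot(s$alpha > 0, s$alpha < 1, s$multiplier >= 1,
            s$lower_cut > 0, s$lower_cut < 1,
            s$smoothing_window %% 2 == 1)
  stopifnot(config$preprocess$border_gauss_size_px >= 3,
            config$preprocess$border_gauss_size_px %% 2 == 1)
  invisible(config)
}

#' Read / write a pipeline configuration (YAML)
#'
#' `read_config()` parses and validates; unknown keys are rejected.
#' `write_config()` serializes so that a read/write round trip is the
#' identity on the validated structure.
#'
#' @param path YAML file path.
#' @return `read_config()`: the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # fill unspecified keys with defaults, keep structure strict
  tmpl <- config_template()
  for (sec in names(cfg)) {
    if (!sec %in% names(tmpl))
      stop("unknown config section: ", sec)
    for (k in names(cfg[[sec]])) tmpl[[sec]][[k]] <- cfg[[sec]][[k]]
  }
  validate_config(tmpl)
  tmpl
}

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

detect_params_from_config <- function(config) {
  d <- config$detect
  detect_params(diffusion_iters = d$diffusion_iters,
                diffusion_kappa = d$diffusion_kappa,
                diffusion_dt = d$diffusion_dt,
                r1 = d$r1, r2 = d$r2, radius_step = d$radius_step,
                polarity = config$global$polarity,
                score_threshold = d$score_threshold,
                min_separation_px = d$min_separation_px,
                gradient_floor = d$gradient_floor)
}

levelset_params_from_config <- function(config) {
  l <- config$levelset
  levelset_params(lambda_in = l$lambda_in, lambda_out = l$lambda_out,
                  mu_length = l$mu_length, epsilon = l$epsilon,
                  dt = l$dt, n_iter = l$n_iter, init_mode = l$init_mode)
}

# Simple RGB overlay: colony boundaries red, centroids blue cross,
# detections green circle.
render_overlay <- function(img, colonies, detections, path) {
  g <- clip_intensity(img) / 255
  arr <- array(rep(g, 3), dim = c(nrow(img), ncol(img), 3))
  put <- function(x, y, rgb) {
    r <- round(y) + 1; c <- round(x) + 1
    ok <- r >= 1 & r <= nrow(img) & c >= 1 & c <= ncol(img)
    for (ch in 1:3) {
      pl <- arr[, , ch]
      pl[cbind(r[ok], c[ok])] <- rgb[ch]
      arr[, , ch] <<- pl
    }
  }
  for (col in colonies) {
    put(col$boundary[, 1], col$boundary[, 2], c(1, 0, 0))
    cx <- col$centroid["x"]; cy <- col$centroid["y"]
    put(cx + (-3:3), rep(cy, 7), c(0, 0.4, 1))
    put(rep(cx, 7), cy + (-3:3), c(0, 0.4, 1))
  }
  if (nrow(detections) > 0) {
    th <- seq(0, 2 * pi, length.out = 48)
    for (i in seq_len(nrow(detections))) {
      r <- detections$radius_px[i]
      put(detections$x[i] + r * cos(th), detections$y[i] + r * sin(th),
          c(0, 1, 0))
    }
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Run the full pipeline over an image set
#'
#' For each image: preprocessing, level-set segmentation, binary cleanup,
#' watershed splitting, diffusion + Orientation Matching detection and
#' colony assignment; then one pooled location analysis over all colonies
#' of the whole set.  Writes `colonies.csv`, `detections.csv`,
#' `locations.csv`, `mutual.csv`, `report.json` and `pipeline.log` (plus
#' per-image overlay PNGs when requested) into `out_dir`.  All
#' coordinates in the CSV outputs are on the ORIGINAL image scale
#' (working-scale values rescaled by `1 / resize_factor`); normalized
#' quantities (`delta`, `mhat`) are scale-free.  A failing image is
#' skipped with a logged reason and listed in the report.
#'
#' @param image_paths character vector of image files (may be empty).
#' @param out_dir output directory (created if missing).
#' @param config a configuration list, see [default_config()].
#' @param write_overlays write per-image overlay PNGs.
#' @return the pooled `location_report` (invisibly `NULL` for an empty
#'   image set), with per-image artifacts on disk.
#' @export
run_pipeline <- function(image_paths, out_dir, config = default_config(),
                         write_overlays = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  logit <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
  }
  logit("pipeline start; seed=", config$global$seed,
        " resize_factor=", config$global$resize_factor,
        " polarity=", config$global$polarity)
  logit("config: ", jsonlite::toJSON(config, auto_unbox = TRUE))
  if (length(image_paths) == 0) {
    warning("empty image list: writing an empty report")
    report <- list(images = list(), n_colonies = 0, skipped = list())
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    logit("empty image list; exiting")
    writeLines(log_lines, log_path)
    return(invisible(NULL))
  }
  f <- config$global$resize_factor
  colonies_all <- list()
  det_all <- list()
  colony_rows <- list()
  skipped <- list()
  next_label <- 0L
  for (path in image_paths) {
    res <- tryCatch({
      img <- read_image(path, f)
      logit("image ", path, ": working size ", nrow(img), "x", ncol(img))
      pre <- preprocess_image(img, config$preprocess)
      cols <- segment_colonies(pre, levelset_params_from_config(config),
                               config$binary$disk_radius_px,
                               config$binary$min_area_px,
                               config$binary$h_merge)
      logit("image ", path, ": ", length(cols), " colonies")
      # globally unique labels across the image set
      for (i in seq_along(cols)) cols[[i]]$label <- next_label + i
      dp <- detect_params_from_config(config)
      det <- detect_cells(img, cols, dp)
      logit("image ", path, ": ", nrow(det), " detections in colonies (",
            paste(vapply(cols, function(cc)
              sum(det$colony_id == cc$label), 0L), collapse = ", "), ")")
      if (write_overlays)
        render_overlay(img, cols, det,
                       file.path(out_dir, paste0(
                         tools::file_path_sans_ext(basename(path)),
                         "_overlay.png")))
      for (cc in cols) {
        colony_rows[[length(colony_rows) + 1]] <- data.frame(
          image = basename(path), colony_id = cc$label,
          area_px = cc$area_px / f^2,
          centroid_x = cc$centroid["x"] / f,
          centroid_y = cc$centroid["y"] / f,
          major_axis_px = cc$major_axis_px / f,
          bbox_x_min = cc$bbox["x_min"] / f,
          bbox_y_min = cc$bbox["y_min"] / f,
          bbox_x_max = cc$bbox["x_max"] / f,
          bbox_y_max = cc$bbox["y_max"] / f,
          row.names = NULL)
      }
      if (nrow(det) > 0) det$image <- basename(path)
      det_all[[length(det_all) + 1]] <- det
      colonies_all <- c(colonies_all, cols)
      next_label <- next_label + length(cols)
      TRUE
    }, error = function(e) {
      logit("image ", path, " SKIPPED: ", conditionMessage(e))
      skipped[[length(skipped) + 1]] <<- list(image = path,
                                              reason = conditionMessage(e))
      FALSE
    })
  }
  detections <- if (length(det_all)) do.call(rbind, det_all) else
    data.frame(colony_id = integer(), x = numeric(), y = numeric(),
               radius_px = numeric(), score = numeric())
  report_obj <- NULL
  if (nrow(detections) > 0 && length(colonies_all) > 0) {
    s <- config$stats
    report_obj <- analyze_locations(colonies_all, detections,
                                    alpha = s$alpha,
                                    multiplier = s$multiplier,
                                    lower_cut = s$lower_cut,
                                    smoothing_window = s$smoothing_window,
                                    seed = config$global$seed)
    logit("pooled analysis: ", report_obj$label_location, " / ",
          report_obj$label_radial, " / ", report_obj$label_cluster)
  } else {
    logit("no detections inside colonies; location analysis skipped")
  }
  # CSV outputs (original scale; coordinates 0-based, x = column)
  col_df <- if (length(colony_rows)) do.call(rbind, colony_rows) else
    data.frame()
  write.csv(col_df, file.path(out_dir, "colonies.csv"), row.names = FALSE)
  det_out <- detections
  if (nrow(det_out) > 0) {
    det_out$x <- det_out$x / f
    det_out$y <- det_out$y / f
    det_out$radius_px <- det_out$radius_px / f
  }
  write.csv(det_out, file.path(out_dir, "detections.csv"),
            row.names = FALSE)
  if (!is.null(report_obj)) {
    loc <- report_obj$records
    loc$x <- loc$x / f; loc$y <- loc$y / f
    loc$d_px <- loc$d_px / f; loc$D_px <- loc$D_px / f
    write.csv(loc[, c("colony_id", "cell_id", "x", "y", "d_px", "D_px",
                      "delta")],
              file.path(out_dir, "locations.csv"), row.names = FALSE)
    mut <- do.call(rbind, lapply(colonies_all, function(cc) {
      pts <- detections[detections$colony_id == cc$label, c("x", "y")]
      if (nrow(pts) < 2) return(NULL)
      m <- mutual_distances(as.matrix(pts), cc$major_axis_px)
      m$m_px <- m$m_px / f
      cbind(colony_id = cc$label, m)
    }))
    if (is.null(mut))
      mut <- data.frame(colony_id = integer(), i = integer(),
                        j = integer(), m_px = numeric(), mhat = numeric())
    write.csv(mut, file.path(out_dir, "mutual.csv"), row.names = FALSE)
  }
  report_json <- list(
    images = as.list(basename(image_paths)),
    skipped = skipped,
    n_colonies = length(colonies_all),
    n_detections = nrow(detections),
    seed = config$global$seed,
    resize_factor = f,
    alpha = config$stats$alpha,
    truncation = c(config$stats$lower_cut, 1),
    smoothing_window = config$stats$smoothing_window)
  if (!is.null(report_obj)) {
    report_json <- c(report_json, list(
      label_location = report_obj$label_location,
      label_radial = report_obj$label_radial,
      label_cluster = report_obj$label_cluster,
      centroid_ks = list(D = report_obj$centroid_ks$statistic,
                         p_value = report_obj$centroid_ks$p_value,
                         n_real = report_obj$centroid_ks$n_a,
                         n_null = report_obj$centroid_ks$n_b),
      mutual_ks = if (is.null(report_obj$mutual_ks)) NULL else
        list(D = report_obj$mutual_ks$statistic,
             p_value = report_obj$mutual_ks$p_value,
             n_real = report_obj$mutual_ks$n_a,
             n_null = report_obj$mutual_ks$n_b),
      mean_delta_real = report_obj$mean_delta_real,
      mean_delta_null = report_obj$mean_delta_null,
      mean_mhat_real = report_obj$mean_mhat_real,
      mean_mhat_null = report_obj$mean_mhat_null,
      notes = report_obj$notes))
  }
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  logit("pipeline done")
  writeLines(log_lines, log_path)
  invisible(report_obj)
}
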