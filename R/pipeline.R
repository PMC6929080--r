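#' Default pipeline configuration
#'
#' The ten tunable parameters default to the published optimum of the
#' differential-evolution search (median 7; localization windows 7/7;
#' snake alpha 50, beta 20, edge weight 1; Canny 120/90, kernel 3; top-hat
#' kernel 21); the remaining entries control stages the tuning does not
#' touch.
#'
#' @param ... Named overrides of individual entries.
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    # tuned set
    median_k = 7L,
    loc_window_up = 7, loc_window_down = 7,
    snake_alpha = 50, snake_beta = 20, snake_edge_weight = 1,
    canny_high = 120, canny_low = 90, canny_kernel = 3L,
    tophat_kernel = 21L,
    # diffusion
    diffusion_iter = 15L, diffusion_kappa = 30, diffusion_dt = 0.2,
    # orientation / rotation
    hog_bins = 36L, rotation_deadband = 5,
    # localization extras
    initial_row_threshold = NULL, min_support_frac = 0.2,
    inner_grad_thresh = 10, max_extrapolation_cols = 30L,
    merge_dist_px = 2, merge_frac = 0.8,
    # snake schedule
    snake_max_iter = 400L, snake_move_radius = 2L, snake_conv_tol = 0.01,
    # distances
    tangent_window = 10, coarse_step = 10L, nearest_window_cols = 50,
    pixel_size_um = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config entries: ",
                            paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_config()` returns a full configuration (unknown keys are
#'   rejected, missing keys take defaults).
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, vals)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Segment the scleral lens and the cornea in an AS-OCT image
#'
#' The full segmentation chain: preprocessing (median smoothing, anisotropic
#' diffusion, rotation to horizontal, top-hat enhancement), preliminary
#' localization by edge tracing, and snake refinement of every detected
#' boundary. Curves are reported in the frame of the input image (mapped
#' back through the inverse rotation).
#'
#' @param img Grayscale matrix in `[0, 255]`, or a file path readable by
#'   [read_gray_image()].
#' @param config Pipeline parameters, see [default_config()].
#' @param refine Apply the snake refinement (default `TRUE`).
#' @return An object of class `oct_segmentation` with components `layers`
#'   (a [layer_set()] in the input frame), `layers_rotated` (working frame),
#'   `preprocessed`, `config` and the input `image`. Methods: `print`,
#'   `summary`, `plot`, `coef`, `predict`, `residuals`.
#' @export
oct_segment <- function(img, config = default_config(), refine = TRUE) {
  if (is.character(img)) img <- read_gray_image(img)
  validate_gray_image(img)
  pre <- preprocess(img, config)
  loc <- preliminary_localization(pre, config)
  layers_rot <- loc
  if (refine) {
    scfg <- snake_config(alpha = config$snake_alpha,
                         beta = config$snake_beta,
                         edge_weight = config$snake_edge_weight,
                         max_iter = config$snake_max_iter,
                         move_radius = config$snake_move_radius,
                         conv_tol = config$snake_conv_tol)
    pot <- snake_potential(pre$image)
    ref1 <- function(cu) {
      if (is.null(cu) || length(cu$cols) < 5) return(cu)
      evolve(cu, pre$image, scfg, potential = pot)
    }
    layers_rot <- layer_set(ref1(loc$scl_outer),
                            if (!is.null(loc$scl_inner)) ref1(loc$scl_inner),
                            ref1(loc$cornea),
                            confidence = loc$confidence)
    layers_rot <- .enforce_ordering(layers_rot)
  }
  layers <- layers_rot
  if (pre$applied_rotation_deg != 0) {
    tr <- rotation_transform(-pre$applied_rotation_deg, pre$dim_original)
    back <- function(cu) if (is.null(cu)) NULL else transform_curve(cu, tr, "inv")
    layers <- layer_set(back(layers_rot$scl_outer),
                        if (!is.null(layers_rot$scl_inner))
                          back(layers_rot$scl_inner),
                        back(layers_rot$cornea),
                        confidence = layers_rot$confidence)
  }
  structure(list(layers = layers, layers_rotated = layers_rot,
                 preprocessed = pre, config = config, image = img),
            class = "oct_segmentation")
}

.enforce_ordering <- function(ls) {
  sh <- intersect(ls$scl_outer$cols, ls$cornea$cols)
  if (length(sh) > 0) {
    io <- match(sh, ls$scl_outer$cols); ic <- match(sh, ls$cornea$cols)
    ls$cornea$rows[ic] <- pmax(ls$cornea$rows[ic], ls$scl_outer$rows[io])
  }
  if (!is.null(ls$scl_inner)) {
    sh <- intersect(ls$scl_inner$cols, ls$scl_outer$cols)
    ii <- match(sh, ls$scl_inner$cols); io <- match(sh, ls$scl_outer$cols)
    ls$scl_inner$rows[ii] <- pmax(ls$scl_inner$rows[ii], ls$scl_outer$rows[io])
    sh <- intersect(ls$scl_inner$cols, ls$cornea$cols)
    ii <- match(sh, ls$scl_inner$cols); ic <- match(sh, ls$cornea$cols)
    ls$scl_inner$rows[ii] <- pmin(ls$scl_inner$rows[ii], ls$cornea$rows[ic])
  }
  ls
}

#' @export
print.oct_segmentation <- function(x, ...) {
  cat(sprintf("<oct_segmentation> %dx%d image, %s, rotation %.2f deg\n",
              nrow(x$image), ncol(x$image), x$layers$region_class,
              x$preprocessed$applied_rotation_deg))
  print(x$layers)
  invisible(x)
}

#' @export
summary.oct_segmentation <- function(object, ...) {
  x <- object
  cat(sprintf("AS-OCT segmentation of a %dx%d image\n",
              nrow(x$image), ncol(x$image)))
  cat(sprintf("  region class : %s (%d visible layers, confidence %.2f)\n",
              x$layers$region_class, x$layers$layer_count,
              x$layers$confidence))
  cat(sprintf("  applied tilt : %.2f deg\n",
              x$preprocessed$applied_rotation_deg))
  for (nm in c("scl_outer", "scl_inner", "cornea")) {
    cu <- x$layers[[nm]]
    if (is.null(cu)) next
    cat(sprintf("  %-9s: cols %d..%d, rows %.1f..%.1f, %.0f%% traced\n", nm,
                min(cu$cols), max(cu$cols), min(cu$rows), max(cu$rows),
                100 * mean(cu$provenance == "traced")))
  }
  invisible(x)
}

#' @export
coef.oct_segmentation <- function(object, ...) {
  out <- do.call(rbind, lapply(c("scl_outer", "scl_inner", "cornea"),
    function(nm) {
      cu <- object$layers[[nm]]
      if (is.null(cu)) return(NULL)
      cbind(layer = nm, as.data.frame(cu))
    }))
  rownames(out) <- NULL
  out
}

#' @export
predict.oct_segmentation <- function(object, cols,
                                     layer = c("scl_inner", "scl_outer",
                                               "cornea"), ...) {
  layer <- match.arg(layer)
  cu <- object$layers[[layer]]
  if (is.null(cu)) stop("layer ", layer, " was not detected")
  curve_row_at(cu, cols, interpolate = TRUE)
}

#' @export
residuals.oct_segmentation <- function(object, truth, ...) {
  if (missing(truth)) stop("residuals need a ground_truth reference")
  out <- lapply(c("scl_outer", "scl_inner", "cornea"), function(nm) {
    pr <- object$layers[[nm]]; tr <- truth$curves[[nm]]
    if (is.null(pr) || is.null(tr)) return(NULL)
    shared <- intersect(pr$cols, tr$cols)
    if (length(shared) == 0L) return(NULL)
    data.frame(layer = nm, col = shared,
               residual = curve_row_at(pr, shared) - curve_row_at(tr, shared))
  })
  do.call(rbind, out)
}

#' @export
plot.oct_segmentation <- function(x, frame = c("original", "rotated"), ...) {
  frame <- match.arg(frame)
  img <- if (frame == "original") x$image else x$preprocessed$image
  ls <- if (frame == "original") x$layers else x$layers_rotated
  h <- nrow(img); w <- ncol(img)
  op <- graphics::par(mar = c(0, 0, 2, 0)); on.exit(graphics::par(op))
  graphics::plot(c(0, w), c(0, h), type = "n", axes = FALSE, asp = 1,
                 xlab = "", ylab = "", main = x$layers$region_class)
  graphics::rasterImage(clip255(img) / 255, 0, 0, w, h)
  colmap <- c(scl_outer = "cyan", scl_inner = "yellow", cornea = "magenta")
  for (nm in names(colmap)) {
    cu <- ls[[nm]]
    if (is.null(cu)) next
    graphics::lines(cu$cols, h - cu$rows, col = colmap[nm], lwd = 2)
  }
  invisible(x)
}

#' Measure the cornea-lens clearance of a segmentation
#'
#' @param seg An `oct_segmentation`.
#' @param config Configuration supplying the paradigm parameters (defaults
#'   to the one stored in `seg`).
#' @return A [distance_profile()] over the shared columns, in the input
#'   image frame.
#' @export
measure_vault <- function(seg, config = NULL) {
  if (!inherits(seg, "oct_segmentation")) stop("seg must be an oct_segmentation")
  if (is.null(config)) config <- seg$config
  distance_profile(seg$layers,
                   tangent_window = config$tangent_window,
                   coarse_step = config$coarse_step,
                   window_cols = config$nearest_window_cols,
                   pixel_size_um = config$pixel_size_um)
}

#' Run the whole pipeline on one image and write all artifacts
#'
#' Executes preprocess, localization, snake refinement, distance measurement
#' and heatmap rendering; writes the curves (CSV and JSON), the distance
#' profile (CSV), the heatmap (PNG) and a run manifest (JSON) into
#' `out_dir`.
#'
#' @param image_path Input PNG/TIFF path.
#' @param config_path Optional JSON configuration path.
#' @param out_dir Output directory (created if missing).
#' @param paradigm Heatmap paradigm.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(image_path, config_path = NULL, out_dir,
                         paradigm = "nearest") {
  if (!file.exists(image_path)) stop("unreadable image: ", image_path)
  config <- if (is.null(config_path)) default_config()
            else read_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    list(value = val, seconds = proc.time()[["elapsed"]] - t0)
  }
  img <- stage("read", read_gray_image(image_path))
  seg <- stage("segment", oct_segment(img$value, config))
  prof <- stage("measure", measure_vault(seg$value))
  hm <- stage("heatmap", render_heatmap(img$value, seg$value$layers,
                                        prof$value, paradigm))
  paths <- list(
    curves_csv = file.path(out_dir, "curves.csv"),
    curves_json = file.path(out_dir, "curves.json"),
    profile_csv = file.path(out_dir, "profile.csv"),
    heatmap_png = file.path(out_dir, "heatmap.png"),
    manifest_json = file.path(out_dir, "manifest.json"))
  cdf <- coef(seg$value)
  utils::write.csv(cdf, paths$curves_csv, row.names = FALSE)
  jsonlite::write_json(split(cdf[c("col", "row", "provenance")], cdf$layer),
                       paths$curves_json, digits = NA)
  utils::write.csv(as.data.frame(prof$value), paths$profile_csv,
                   row.names = FALSE)
  write_heatmap(hm$value, paths$heatmap_png)
  cfg_file <- tempfile(fileext = ".json")
  write_config(config, cfg_file)
  manifest <- list(
    input = normalizePath(image_path),
    config_md5 = unname(tools::md5sum(cfg_file)),
    region_class = seg$value$layers$region_class,
    applied_rotation_deg = seg$value$preprocessed$applied_rotation_deg,
    stage_seconds = list(read = img$seconds, segment = seg$seconds,
                         measure = prof$seconds, heatmap = hm$seconds),
    outputs = unlist(paths),
    tool_version = as.character(utils::packageVersion("octvault")))
  unlink(cfg_file)
  jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
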