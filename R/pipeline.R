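## End-to-end orchestration: image -> detector -> counts, boxes, masks.

#' Pipeline configuration
#'
#' One structured configuration governing every stage. Sub-blocks are
#' validated by their own modules; unknown keys are rejected.
#'
#' @param dish List: `margin_fraction`, `luminance_jump` (NULL = auto),
#'   `fallback` (use a full-image circle when the dish is not found).
#' @param tiling List: `tile_w`, `tile_h`, `overlap`, `merge_iou`.
#' @param segmentation List of [segment_plate()] parameters
#'   (`bilateral_diameter`, `sigma_color`, `sigma_space`, `window`,
#'   `offset_c`, `kernel_size`, `band`, `blob_params`, `size_params`).
#' @param detection_filter A [det_filter_config()].
#' @param evaluation List: `iou_min`, `mode`.
#' @param seed Integer seed recorded in reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dish = list(), tiling = list(), segmentation = list(),
                            detection_filter = det_filter_config(),
                            evaluation = list(), seed = 1L) {
  defaults <- list(
    dish = list(margin_fraction = 0.05, luminance_jump = NULL, fallback = TRUE),
    tiling = list(tile_w = 820L, tile_h = 821L, overlap = 0.25, merge_iou = 0.3),
    segmentation = list(bilateral_diameter = 9L, sigma_color = 10, sigma_space = 5,
                        window = 71L, offset_c = 4, kernel_size = 3L,
                        band = worm_area_band(), blob_params = blob_filter_params(),
                        size_params = size_filter_params()),
    evaluation = list(iou_min = 0.5, mode = "mask")
  )
  check_keys <- function(user, def, block) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) > 0L)
      stopf("pipeline_config: unknown key '%s' in block '%s'", unknown[1L], block)
    modifyList(def, user)
  }
  structure(
    list(dish = check_keys(dish, defaults$dish, "dish"),
         tiling = check_keys(tiling, defaults$tiling, "tiling"),
         segmentation = check_keys(segmentation, defaults$segmentation, "segmentation"),
         detection_filter = detection_filter,
         evaluation = check_keys(evaluation, defaults$evaluation, "evaluation"),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

## md5 of a raw numeric buffer (decoded pixels / serialized config), so
## recompression of the input file cannot change the provenance hash
buffer_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(as.numeric(x), tf)
  unname(tools::md5sum(tf))
}

plate_report <- function(detections, config, image, metrics = NULL) {
  structure(
    list(worm_count = nrow(detections), detections = detections,
         metrics = metrics,
         provenance = list(
           image_hash = buffer_md5(image),
           config_hash = buffer_md5(utf8ToInt(paste(deparse(config), collapse = ""))),
           version = as.character(utils::packageVersion("wormscope")),
           seed = config$seed
         )),
    class = "plate_report"
  )
}

#' @export
print.plate_report <- function(x, ...) {
  cat(sprintf("plate report: %d worms detected\n", x$worm_count))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

## dish geometry for an image, honoring the fallback policy
resolve_dish <- function(image, cfg) {
  geom <- tryCatch(
    detect_dish(image, luminance_jump = cfg$dish$luminance_jump,
                margin_fraction = cfg$dish$margin_fraction),
    error = function(e) {
      if (!isTRUE(cfg$dish$fallback)) stop(e)
      d <- dim(image)
      dish_geometry(d[2L] / 2, d[1L] / 2, sqrt(sum((d[1:2] / 2)^2)),
                    margin_fraction = 0)
    }
  )
  geom
}

#' Classical whole-plate worm detection
#'
#' Locates and masks the dish, tiles the image, runs the classical
#' segmentation chain per tile, maps the per-tile masks back to
#' full-image coordinates, de-duplicates across tile overlaps and
#' assigns each surviving worm an id.
#'
#' @param image Image path or 0..255 matrix/array.
#' @param config A [pipeline_config()].
#' @return A `plate_report` with `worm_count`, the `detections` table
#'   (segmentation-derived detections carry score 1) and provenance.
#' @export
run_classical <- function(image, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(image)) image <- read_image(image)
  d <- dim(image)
  geom <- resolve_dish(image, config)
  masked <- apply_dish_mask(image, geom)

  tw <- min(config$tiling$tile_w, d[2L])
  th <- min(config$tiling$tile_h, d[1L])
  grid <- plan_tiles(d[2L], d[1L], tw, th, config$tiling$overlap)

  seg <- config$segmentation
  all_dets <- list()
  for (k in seq_len(nrow(grid$offsets))) {
    off <- c(grid$offsets$x0[k], grid$offsets$y0[k])
    tile <- extract_tile(masked, off, tw, th)
    masks <- segment_plate(tile, dish = FALSE,
                           bilateral_diameter = seg$bilateral_diameter,
                           sigma_color = seg$sigma_color, sigma_space = seg$sigma_space,
                           window = seg$window, offset_c = seg$offset_c,
                           kernel_size = seg$kernel_size, band = seg$band,
                           blob_params = seg$blob_params, size_params = seg$size_params)
    if (length(masks) == 0L) next
    bb <- t(vapply(masks, mask_bbox, numeric(4)))
    dets <- detection_table(bb, score = rep(1, length(masks)),
                            label = "worm", mask = masks)
    all_dets[[length(all_dets) + 1L]] <- to_global(dets, off, d[2L], d[1L])
  }
  dets <- if (length(all_dets) == 0L) empty_detections() else {
    combined <- do.call(rbind, all_dets)
    combined$id <- seq_len(nrow(combined))
    merge_tile_detections(combined, config$tiling$merge_iou)
  }
  if (nrow(dets) > 0L) dets$id <- seq_len(nrow(dets))
  plate_report(dets, config, image)
}

#' Post-process externally produced detections into a plate report
#'
#' Applies the inference filter chain to a raw detection file (or
#' table), de-duplicates across tile overlaps when several detections
#' describe the same worm, and assigns ids.
#'
#' @param image Image path or matrix (for provenance and frame size).
#' @param detections Path to a detection JSON (see
#'   [read_detections()]) or a [detection_table()].
#' @param config A [pipeline_config()].
#' @param merge De-duplicate surviving detections across tiles.
#' @return A `plate_report`.
#' @export
run_external <- function(image, detections, config = pipeline_config(),
                         merge = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(image)) image <- read_image(image)
  if (is.character(detections)) detections <- read_detections(detections)
  dets <- filter_chain(detections, config$detection_filter)
  attrition <- attr(dets, "attrition")
  if (merge) dets <- merge_tile_detections(dets, config$tiling$merge_iou)
  if (nrow(dets) > 0L) dets$id <- seq_len(nrow(dets))
  rep <- plate_report(dets, config, image)
  rep$attrition <- attrition
  rep
}

#' Evaluate a plate report against ground truth
#'
#' @param report A `plate_report`.
#' @param truth Ground truth: a fixture directory (see
#'   [read_fixture()]), a list of logical masks, or a `synth_plate`.
#' @param config A [pipeline_config()] (evaluation block: `iou_min`,
#'   `mode`).
#' @param thresholds Optional threshold vector for the IoU sweep.
#' @return The report with `metrics`, `pr_curve` and `sweep` attached.
#' @export
run_evaluation <- function(report, truth, config = pipeline_config(),
                           thresholds = seq(0.2, 0.9, by = 0.1)) {
  gts <- if (is.character(truth)) read_fixture(truth)$masks
         else if (inherits(truth, "synth_plate")) truth$masks
         else truth
  mode <- config$evaluation$mode
  m <- match_detections(report$detections, gts,
                        iou_min = config$evaluation$iou_min, mode = mode)
  report$metrics <- precision_recall_f1(m)
  report$match <- m
  report$pr_curve <- average_precision(report$detections, gts,
                                       iou_min = config$evaluation$iou_min,
                                       mode = mode)
  report$sweep <- iou_sweep(report$detections, gts, thresholds, mode = mode)
  report
}

#' Draw detection overlays on a plate image
#'
#' Masks are tinted blue, bounding boxes outlined in red, and each worm
#' id marked at its box corner; purely cosmetic — the report itself is
#' never altered. With an empty report the image is returned unchanged.
#'
#' @param image Image path or 0..255 matrix/array.
#' @param report A `plate_report`.
#' @param path Optional output PNG path.
#' @return The annotated RGB array (0..255), invisibly if written.
#' @export
render_overlay <- function(image, report, path = NULL) {
  if (is.character(image)) image <- read_image(image)
  if (length(dim(image)) == 2L) {
    rgb <- array(0, dim = c(dim(image), 3L))
    for (ch in 1:3) rgb[, , ch] <- image
  } else rgb <- image
  dets <- report$detections
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  for (i in seq_len(nrow(dets))) {
    x0 <- max(1L, round(dets$x0[i]) + 1L); x1 <- min(w, round(dets$x1[i]))
    y0 <- max(1L, round(dets$y0[i]) + 1L); y1 <- min(h, round(dets$y1[i]))
    rgb[c(y0, y1), x0:x1, 1L] <- 255
    rgb[y0:y1, c(x0, x1), 1L] <- 255
    rgb[c(y0, y1), x0:x1, 2:3] <- 0
    rgb[y0:y1, c(x0, x1), 2:3] <- 0
  }
  for (i in seq_len(nrow(dets))) {
    if (!is.null(dets$mask) && !is.null(dets$mask[[i]])) {
      m <- dets$mask[[i]]
      plane <- rgb[, , 3L]; plane[m] <- 255; rgb[, , 3L] <- plane   # blue tint
      plane <- rgb[, , 1L]; plane[m] <- plane[m] * 0.4; rgb[, , 1L] <- plane
      plane <- rgb[, , 2L]; plane[m] <- plane[m] * 0.4; rgb[, , 2L] <- plane
    }
  }
  if (!is.null(path)) {
    write_image(rgb, path)
    return(invisible(rgb))
  }
  rgb
}
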