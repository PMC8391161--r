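## Detection-side post-processing.
##
## Consumes candidate worm detections (boxes + confidence scores +
## optional masks) — typically produced by an external instance
## segmentation network — and applies the inference filter chain:
## background removal, confidence threshold, per-class NMS, top-k cap
## and the small-box size filter. Also carries the detector training /
## inference configuration as an exportable document.

#' Build a detection table
#'
#' Detections are stored as a data.frame with one row per candidate:
#' columns `id`, `x0`, `y0`, `x1`, `y1` (0-based half-open box),
#' `score`, `label`, and a `mask` list-column of logical matrices (or
#' `NULL`s).
#'
#' @param bbox n x 4 matrix (or length-4 vector) of `(x0, y0, x1, y1)`.
#' @param score Confidence scores in `[0, 1]`.
#' @param label Class labels (`"worm"` or `"background"`).
#' @param mask Optional list of logical masks (or `NULL`s).
#' @param id Integer ids; defaults to `1:n`.
#' @return A `data.frame` detection table.
#' @export
detection_table <- function(bbox, score, label = "worm", mask = NULL, id = NULL) {
  if (is.null(dim(bbox))) bbox <- matrix(bbox, ncol = 4L, byrow = TRUE)
  n <- nrow(bbox)
  if (is.null(id)) id <- seq_len(n)
  if (length(label) == 1L) label <- rep(label, n)
  if (length(score) != n || length(label) != n || length(id) != n)
    stopf("detection_table: bbox, score, label, id lengths disagree")
  bad <- which(bbox[, 1L] >= bbox[, 3L] | bbox[, 2L] >= bbox[, 4L])
  if (length(bad) > 0L)
    stopf("detection_table: degenerate bbox (x0 >= x1 or y0 >= y1) at row %d", bad[1L])
  if (any(score < 0 | score > 1)) stopf("detection_table: scores must lie in [0, 1]")
  df <- data.frame(id = as.integer(id),
                   x0 = bbox[, 1L], y0 = bbox[, 2L], x1 = bbox[, 3L], y1 = bbox[, 4L],
                   score = as.numeric(score), label = as.character(label),
                   stringsAsFactors = FALSE)
  if (!is.null(mask)) {
    if (length(mask) != n) stopf("detection_table: mask list length disagrees")
    df$mask <- I(mask)
  }
  df
}

empty_detections <- function() {
  detection_table(matrix(numeric(0), 0L, 4L), numeric(0), character(0),
                  id = integer(0))
}

det_boxes <- function(dets) as.matrix(dets[, c("x0", "y0", "x1", "y1")])

## order detections by descending score, ties broken by lower id
order_by_score <- function(dets) {
  dets <- dets[order(-dets$score, dets$id), , drop = FALSE]
  rownames(dets) <- NULL
  dets
}

#' Greedy non-maximum suppression on bounding boxes
#'
#' Repeatedly keeps the highest-scoring remaining detection (score
#' ties broken by lower id) and suppresses every other detection whose
#' box IoU with it is at least `iou_threshold`. Output sorted by
#' descending score. Idempotent.
#'
#' @param detections A [detection_table()].
#' @param iou_threshold Suppression IoU threshold in `[0, 1]`.
#' @return The surviving detections.
#' @export
nms <- function(detections, iou_threshold) {
  n <- nrow(detections)
  if (is.null(n) || n <= 1L) return(detections)
  det <- order_by_score(detections)
  b <- det_boxes(det)
  area <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == n) break
    j <- which(alive & seq_len(n) > i)
    if (length(j) == 0L) next
    iw <- pmax(0, pmin(b[j, 3L], b[i, 3L]) - pmax(b[j, 1L], b[i, 1L]))
    ih <- pmax(0, pmin(b[j, 4L], b[i, 4L]) - pmax(b[j, 2L], b[i, 2L]))
    inter <- iw * ih
    iou <- inter / (area[i] + area[j] - inter)
    alive[j[iou >= iou_threshold]] <- FALSE
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detection filter-chain configuration
#'
#' @param score_min Minimum class confidence; default 0.92.
#' @param per_class_nms_iou Per-class NMS threshold; default 0.3.
#' @param max_detections Top-k cap on surviving detections; default 100.
#' @param size_filter A [size_filter_params()] applied to boxes.
#' @param proposal_nms_iou Proposal-stage NMS threshold carried in the
#'   configuration; default 0.5.
#' @param max_proposals Proposal cap carried in the configuration;
#'   default 1000.
#' @return A `det_filter_config` list.
#' @export
det_filter_config <- function(score_min = 0.92, per_class_nms_iou = 0.3,
                              max_detections = 100L,
                              size_filter = size_filter_params(),
                              proposal_nms_iou = 0.5, max_proposals = 1000L) {
  for (nm in c("score_min", "per_class_nms_iou", "proposal_nms_iou")) {
    v <- get(nm)
    if (v < 0 || v > 1) stopf("det_filter_config: %s must lie in [0, 1]", nm)
  }
  if (max_detections <= 0L || max_proposals <= 0L)
    stopf("det_filter_config: max_detections and max_proposals must be positive")
  structure(list(score_min = score_min, per_class_nms_iou = per_class_nms_iou,
                 max_detections = as.integer(max_detections), size_filter = size_filter,
                 proposal_nms_iou = proposal_nms_iou, max_proposals = as.integer(max_proposals)),
            class = "det_filter_config")
}

#' Inference filter chain for raw detections
#'
#' Applies, in order: (1) removal of background-labeled boxes,
#' (2) confidence threshold `score_min`, (3) per-class NMS at
#' `per_class_nms_iou`, (4) top-`max_detections` by score, (5) removal
#' of small boxes per the size filter. The per-stage survivor counts
#' are attached as the `"attrition"` attribute for auditing.
#'
#' @param detections A [detection_table()].
#' @param cfg A [det_filter_config()].
#' @return The filtered detection table, sorted by descending score.
#' @export
filter_chain <- function(detections, cfg = det_filter_config()) {
  stopifnot(inherits(cfg, "det_filter_config"))
  counts <- c(input = nrow(detections))
  det <- detections[detections$label != "background", , drop = FALSE]
  counts <- c(counts, background_removed = nrow(det))
  det <- det[det$score >= cfg$score_min, , drop = FALSE]
  counts <- c(counts, confidence = nrow(det))
  det <- nms(det, cfg$per_class_nms_iou)
  counts <- c(counts, nms = nrow(det))
  det <- order_by_score(det)
  det <- head(det, cfg$max_detections)
  counts <- c(counts, top_k = nrow(det))
  if (nrow(det) > 0L) {
    keep <- !vapply(seq_len(nrow(det)), function(i) {
      small_bbox(c(det$x0[i], det$y0[i], det$x1[i], det$y1[i]), cfg$size_filter)
    }, logical(1))
    det <- det[keep, , drop = FALSE]
  }
  counts <- c(counts, size_filter = nrow(det))
  rownames(det) <- NULL
  attr(det, "attrition") <- counts
  det
}

#' Instance-segmentation training/inference configuration
#'
#' The full hyperparameter recipe for the Mask R-CNN detector the
#' post-processing chain is designed around: square anchor box lengths
#' and aspect ratios of the region proposal network, proposal/detection
#' NMS thresholds and caps, sampled-ROI settings, optimizer schedule,
#' input warp size and backbone. Intended to be exported with
#' [emit_mrcnn_config()] and attached to an external training
#' framework; this package does not build or train the network.
#'
#' @param ... Overrides of individual fields (unknown names rejected).
#' @return An `mrcnn_config` list.
#' @export
mrcnn_config <- function(...) {
  spec <- list(
    backbone = "ResNet-101",
    anchor_scales = c(32, 64, 86, 128, 172),
    anchor_ratios = c(0.5, 1, 2),
    rpn_anchor_scale = 18,       # opaque passthrough
    rpn_nms_threshold = 0.7,
    proposal_nms_threshold = 0.5,
    max_proposals = 1000L,
    train_rois_per_image = 256L,
    roi_positive_ratio = "1:3",  # worms to background
    learning_rate = 0.001,
    momentum = 0.9,
    weight_decay = 0.0001,
    epochs = 100L,
    warp_size = c(768L, 768L),
    detection_max = 100L,
    detection_min_confidence = 0,
    per_class_nms_threshold = 0.3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown) > 0L)
    stopf("mrcnn_config: unknown field '%s'", unknown[1L])
  spec <- modifyList(spec, dots)
  class(spec) <- "mrcnn_config"
  spec
}

#' Write the detector configuration to JSON
#'
#' Round-trips losslessly through [read_mrcnn_config()].
#'
#' @param spec An [mrcnn_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
emit_mrcnn_config <- function(spec = mrcnn_config(), path) {
  stopifnot(inherits(spec, "mrcnn_config"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname emit_mrcnn_config
#' @export
read_mrcnn_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(mrcnn_config, raw)
}

#' Write detections to a JSON file
#'
#' Schema: `{"detections": [{"id", "bbox": [x0,y0,x1,y1], "score",
#' "label", "mask_file"?}]}`. Masks, when present, are written as PNG
#' files next to the JSON and referenced by relative path.
#'
#' @param detections A [detection_table()].
#' @param path Output JSON path.
#' @param write_masks Write mask PNGs for detections that carry masks.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path, write_masks = TRUE) {
  dir <- dirname(path)
  recs <- lapply(seq_len(nrow(detections)), function(i) {
    rec <- list(id = detections$id[i],
                bbox = c(detections$x0[i], detections$y0[i],
                         detections$x1[i], detections$y1[i]),
                score = detections$score[i], label = detections$label[i])
    if (write_masks && !is.null(detections$mask) && !is.null(detections$mask[[i]])) {
      mf <- sprintf("det_mask_%03d.png", detections$id[i])
      png::writePNG(detections$mask[[i]] * 1, file.path(dir, mf))
      rec$mask_file <- mf
    }
    rec
  })
  jsonlite::write_json(list(detections = recs), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and validate a detection JSON file
#'
#' Malformed entries are rejected with an error naming the entry index
#' and offending field. Masks referenced by `mask_file` are loaded from
#' paths relative to the JSON file.
#'
#' @param path Detection JSON path.
#' @return A [detection_table()].
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stopf("read_detections: no such file '%s'", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- raw$detections
  if (is.null(recs)) stopf("read_detections: missing 'detections' field")
  n <- length(recs)
  if (n == 0L) return(empty_detections())
  bbox <- matrix(NA_real_, n, 4L)
  score <- numeric(n); label <- character(n); id <- integer(n)
  masks <- vector("list", n)
  has_mask <- FALSE
  for (i in seq_len(n)) {
    r <- recs[[i]]
    for (f in c("id", "bbox", "score", "label"))
      if (is.null(r[[f]])) stopf("read_detections: entry %d missing field '%s'", i, f)
    bb <- as.numeric(unlist(r$bbox))
    if (length(bb) != 4L) stopf("read_detections: entry %d field 'bbox' must have 4 values", i)
    if (bb[1L] >= bb[3L] || bb[2L] >= bb[4L])
      stopf("read_detections: entry %d field 'bbox' is degenerate (x0 >= x1 or y0 >= y1)", i)
    if (r$score < 0 || r$score > 1)
      stopf("read_detections: entry %d field 'score' outside [0, 1]", i)
    bbox[i, ] <- bb
    score[i] <- r$score
    label[i] <- r$label
    id[i] <- r$id
    if (!is.null(r$mask_file)) {
      mp <- file.path(dirname(path), r$mask_file)
      if (!file.exists(mp)) stopf("read_detections: entry %d field 'mask_file' not found: '%s'", i, mp)
      m <- png::readPNG(mp)
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      masks[[i]] <- m > 0.5
      has_mask <- TRUE
    }
  }
  detection_table(bbox, score, label, mask = if (has_mask) masks, id = id)
}
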