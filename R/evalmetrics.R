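## Detection evaluation protocol.
##
## IoU on masks and boxes, greedy confidence-ordered matching of
## predictions to ground truths at a minimum IoU (unmatched ground
## truths count as false negatives, unmatched predictions as false
## positives), precision/recall/F1, interpolated average precision
## (area under the precision-recall curve, all-points interpolation),
## and a sweep of the minimum-IoU threshold.

#' Intersection over union of two pixel masks
#'
#' @param a,b Logical matrices in the same frame.
#' @return `|a & b| / |a | b|`. Two empty masks are an error.
#' @export
#' @examples
#' a <- matrix(FALSE, 5, 5); b <- a
#' a[1:3, 1:3] <- TRUE; b[2:4, 2:4] <- TRUE
#' mask_iou(a, b)   # 4 / 14
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stopf("mask_iou: masks live in different frames (%s vs %s)",
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  uni <- sum(a | b)
  if (uni == 0L) stopf("mask_iou: both masks are empty")
  sum(a & b) / uni
}

#' Intersection over union of two half-open bounding boxes
#'
#' @param a,b Length-4 vectors `(x0, y0, x1, y1)`, 0-based half-open.
#' @return The IoU fraction. Degenerate boxes are an error.
#' @export
box_iou <- function(a, b) {
  if (a[1L] >= a[3L] || a[2L] >= a[4L] || b[1L] >= b[3L] || b[2L] >= b[4L])
    stopf("box_iou: degenerate box (x0 >= x1 or y0 >= y1)")
  iw <- max(0, min(a[3L], b[3L]) - max(a[1L], b[1L]))
  ih <- max(0, min(a[4L], b[4L]) - max(a[2L], b[2L]))
  inter <- iw * ih
  area_a <- (a[3L] - a[1L]) * (a[4L] - a[2L])
  area_b <- (b[3L] - b[1L]) * (b[4L] - b[2L])
  inter / (area_a + area_b - inter)
}

## IoU of prediction i against every ground truth, for either mode.
pred_gt_ious <- function(det, i, gts, gt_boxes, mode) {
  if (mode == "mask" && !is.null(det$mask) && !is.null(det$mask[[i]])) {
    vapply(gts, function(g) mask_iou(det$mask[[i]], g), numeric(1))
  } else {
    bb <- c(det$x0[i], det$y0[i], det$x1[i], det$y1[i])
    vapply(gt_boxes, function(g) box_iou(bb, g), numeric(1))
  }
}

gt_boxes_of <- function(gts) lapply(gts, function(g) if (is.matrix(g) && is.logical(g)) mask_bbox(g) else g)

#' Match predictions to ground truths at a minimum IoU
#'
#' Predictions are visited in descending score order (ties broken by
#' lower id); each claims the unmatched ground truth of highest IoU,
#' provided that IoU is at least `iou_min`. Ground truths left without
#' a match are false negatives, predictions without a match false
#' positives.
#'
#' @param preds A [detection_table()].
#' @param gts List of ground-truth logical masks (mode `"mask"`), or of
#'   masks/boxes for mode `"box"` (masks are reduced to their minimal
#'   bounding boxes).
#' @param iou_min Minimum IoU for a match; default 0.5.
#' @param mode `"mask"` or `"box"` IoU.
#' @return A `match_result` with `tp`, `fp`, `fn`, the matched `pairs`
#'   (data.frame of `pred_id`, `gt`, `iou`) and `iou_min`.
#' @export
match_detections <- function(preds, gts, iou_min = 0.5, mode = c("mask", "box")) {
  mode <- match.arg(mode)
  det <- order_by_score(preds)
  n <- nrow(det)
  gt_boxes <- if (mode == "box") gt_boxes_of(gts) else NULL
  gt_taken <- rep(FALSE, length(gts))
  pairs <- data.frame(pred_id = integer(0), gt = integer(0), iou = numeric(0))
  for (i in seq_len(n)) {
    if (!any(!gt_taken)) break
    ious <- pred_gt_ious(det, i, gts, gt_boxes, mode)
    ious[gt_taken] <- -1
    j <- which.max(ious)
    if (length(j) == 1L && ious[j] >= iou_min) {
      gt_taken[j] <- TRUE
      pairs <- rbind(pairs, data.frame(pred_id = det$id[i], gt = j, iou = ious[j]))
    }
  }
  structure(
    list(tp = nrow(pairs), fp = n - nrow(pairs),
         fn = length(gts) - nrow(pairs), pairs = pairs, iou_min = iou_min),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match @ IoU >= %.2f: TP %d, FP %d, FN %d\n",
              x$iou_min, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall, F1 and mean matched-pair IoU
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, and F1 is
#' their harmonic mean. A degenerate denominator (no predictions, or no
#' ground truths) yields `NaN` for the affected metric, with a warning.
#' `avg_iou` averages the IoU over matched pairs only.
#'
#' @param m A `match_result` from [match_detections()], or `tp` count.
#' @param fp,fn Counts, when `m` is given as a count.
#' @return A `detection_metrics` list with `precision`, `recall`, `f1`,
#'   `avg_iou`, and the counts.
#' @export
#' @examples
#' precision_recall_f1(96, 4, 4)$f1   # harmonic mean of 0.96 and 0.96
precision_recall_f1 <- function(m, fp = NULL, fn = NULL) {
  if (inherits(m, "match_result")) {
    tp <- m$tp; fp <- m$fp; fn <- m$fn
    avg_iou <- if (nrow(m$pairs) > 0L) mean(m$pairs$iou) else NA_real_
  } else {
    tp <- m
    avg_iou <- NA_real_
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("precision undefined: no predictions"); NaN
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("recall undefined: no ground truths"); NaN
  }
  f1 <- if (is.finite(precision) && is.finite(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  if (!is.finite(precision) || !is.finite(recall)) f1 <- NaN
  structure(list(precision = precision, recall = recall, f1 = f1,
                 avg_iou = avg_iou, tp = tp, fp = fp, fn = fn),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("precision %.3f, recall %.3f, F1 %.3f (TP %d, FP %d, FN %d)",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  if (is.finite(x$avg_iou)) cat(sprintf(", avg matched IoU %.3f", x$avg_iou))
  cat("\n")
  invisible(x)
}

#' F1 score from a (precision, recall) pair
#'
#' The harmonic mean `2PR / (P + R)`.
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Average precision of a score-ranked detection list
#'
#' Predictions are ranked by descending score (ties broken by lower
#' id) and greedily matched at `iou_min` as in [match_detections()];
#' the cumulative TP/FP counts define the precision-recall sequence.
#' AP is the area under the all-points interpolated curve: precision at
#' recall `r` is replaced by the maximum precision at any recall
#' `>= r`, and the envelope is summed over the recall increments (the
#' curve is sampled exactly where the maximum precision drops).
#'
#' @inheritParams match_detections
#' @return A `pr_curve` with `points` (data.frame of `recall`,
#'   `precision` along the ranking) and `ap`.
#' @export
average_precision <- function(preds, gts, iou_min = 0.5, mode = c("mask", "box")) {
  mode <- match.arg(mode)
  if (length(gts) == 0L) stopf("average_precision: no ground truths")
  det <- order_by_score(preds)
  n <- nrow(det)
  gt_boxes <- if (mode == "box") gt_boxes_of(gts) else NULL
  gt_taken <- rep(FALSE, length(gts))
  tp_flag <- logical(n)
  for (i in seq_len(n)) {
    ious <- pred_gt_ious(det, i, gts, gt_boxes, mode)
    ious[gt_taken] <- -1
    j <- which.max(ious)
    if (length(j) == 1L && ious[j] >= iou_min) {
      gt_taken[j] <- TRUE
      tp_flag[i] <- TRUE
    }
  }
  tp_cum <- cumsum(tp_flag)
  fp_cum <- cumsum(!tp_flag)
  recall <- tp_cum / length(gts)
  precision <- tp_cum / (tp_cum + fp_cum)
  ## all-points interpolation: envelope = running max from the right
  envelope <- rev(cummax(rev(c(precision, 0))))[seq_len(n)]
  dr <- diff(c(0, recall))
  ap <- sum(dr * envelope)
  structure(list(points = data.frame(recall = recall, precision = precision),
                 ap = ap, iou_min = iou_min),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("PR curve (%d points), AP@%.2f IoU = %.3f\n",
              nrow(x$points), x$iou_min, x$ap))
  invisible(x)
}

#' Detection accuracy across minimum-IoU thresholds
#'
#' One row per threshold: greedy matching, precision/recall/F1 and AP,
#' recomputed at that minimum IoU.
#'
#' @inheritParams match_detections
#' @param thresholds Vector of minimum-IoU values in `(0, 1)`.
#' @return A data.frame with columns `iou_min`, `precision`, `recall`,
#'   `f1`, `ap`, `avg_iou`, `tp`, `fp`, `fn`.
#' @export
iou_sweep <- function(preds, gts, thresholds = seq(0.2, 0.9, by = 0.1),
                      mode = c("mask", "box")) {
  mode <- match.arg(mode)
  if (any(thresholds <= 0 | thresholds >= 1))
    stopf("iou_sweep: thresholds must lie in (0, 1)")
  rows <- lapply(thresholds, function(t) {
    m <- match_detections(preds, gts, iou_min = t, mode = mode)
    met <- precision_recall_f1(m)
    ap <- average_precision(preds, gts, iou_min = t, mode = mode)$ap
    data.frame(iou_min = t, precision = met$precision, recall = met$recall,
               f1 = met$f1, ap = ap, avg_iou = met$avg_iou,
               tp = m$tp, fp = m$fp, fn = m$fn)
  })
  do.call(rbind, rows)
}
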