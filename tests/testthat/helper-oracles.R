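## Independent reference implementations ("oracles") and fixture
## builders used across the test files. Oracles are deliberately
## naive — explicit loops and direct arithmetic — so they share no code
## path with the package functions they check.

## Rasterize the union of discs centered on skeleton points by testing
## every pixel against every center (brute force).
oracle_disc_union <- function(skeleton, radii, h, w) {
  mask <- matrix(FALSE, h, w)
  for (row in 1:h) {
    for (col in 1:w) {
      for (k in seq_len(nrow(skeleton))) {
        if ((col - skeleton[k, 1])^2 + (row - skeleton[k, 2])^2 <= radii[k]^2) {
          mask[row, col] <- TRUE
          break
        }
      }
    }
  }
  mask
}

## Per-pixel distance test: how many pixels of an h x w frame lie
## outside radius * (1 - margin) of (cx, cy)? (0-based pixel centers)
oracle_outside_count <- function(h, w, cx, cy, radius, margin) {
  eff <- radius * (1 - margin)
  n <- 0L
  for (row in 1:h) for (col in 1:w) {
    if (sqrt((col - 0.5 - cx)^2 + (row - 0.5 - cy)^2) > eff) n <- n + 1L
  }
  n
}

## IoU of two half-open boxes by direct area arithmetic.
oracle_box_iou <- function(a, b) {
  ix0 <- max(a[1], b[1]); iy0 <- max(a[2], b[2])
  ix1 <- min(a[3], b[3]); iy1 <- min(a[4], b[4])
  inter <- max(0, ix1 - ix0) * max(0, iy1 - iy0)
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  ab <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (aa + ab - inter)
}

## Greedy NMS with a precomputed full IoU matrix and explicit index
## bookkeeping.
oracle_nms_ids <- function(boxes, scores, ids, threshold) {
  n <- nrow(boxes)
  iou <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) iou[i, j] <- oracle_box_iou(boxes[i, ], boxes[j, ])
  }
  remaining <- seq_len(n)
  kept <- integer(0)
  while (length(remaining) > 0) {
    ## highest score, ties by lower id
    best <- remaining[order(-scores[remaining], ids[remaining])][1]
    kept <- c(kept, best)
    remaining <- setdiff(remaining, best)
    remaining <- remaining[iou[best, remaining] < threshold]
  }
  ids[kept]
}

## Greedy score-ordered matching (box IoU) with explicit loops;
## returns tp/fp/fn and per-prediction TP flags in ranked order.
oracle_match <- function(pred_boxes, scores, ids, gt_boxes, iou_min) {
  ord <- order(-scores, ids)
  taken <- rep(FALSE, nrow(gt_boxes))
  tp_flag <- logical(length(ord))
  for (r in seq_along(ord)) {
    i <- ord[r]
    best_iou <- -1; best_j <- 0
    for (j in seq_len(nrow(gt_boxes))) {
      if (taken[j]) next
      v <- oracle_box_iou(pred_boxes[i, ], gt_boxes[j, ])
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0 && best_iou >= iou_min) {
      taken[best_j] <- TRUE
      tp_flag[r] <- TRUE
    }
  }
  list(tp = sum(tp_flag), fp = length(ord) - sum(tp_flag),
       fn = nrow(gt_boxes) - sum(tp_flag), tp_flag = tp_flag)
}

## AP as the mean over ground truths of the interpolated precision at
## each true positive: AP = sum over TP ranks of max precision at any
## rank >= that one, divided by the ground-truth count. Equivalent to
## the area under the all-points interpolated PR curve, computed by a
## different route.
oracle_ap <- function(tp_flag, n_gt) {
  n <- length(tp_flag)
  if (n == 0) return(0)
  prec <- cumsum(tp_flag) / seq_len(n)
  total <- 0
  for (r in seq_len(n)) {
    if (tp_flag[r]) total <- total + max(prec[r:n])
  }
  total / n_gt
}

## Random half-open boxes inside a frame x fraction-scores fixture.
random_boxes <- function(n, frame = 100, min_side = 5, max_side = 30) {
  x0 <- runif(n, 0, frame - max_side)
  y0 <- runif(n, 0, frame - max_side)
  cbind(x0, y0, x0 + runif(n, min_side, max_side), y0 + runif(n, min_side, max_side))
}

## Small easy synthetic plate reused by segmentation tests.
easy_plate <- function(seed, n_worms = 8, n_blobs = 6, size = 560) {
  generate_dish_image(synth_config(
    image_width = size, image_height = size, n_worms = n_worms,
    n_blobs = n_blobs, noise_sigma = 0, allow_overlap = FALSE, seed = seed))
}

## Masks -> detection table with unit scores (classical detector view).
masks_as_detections <- function(masks) {
  stopifnot(length(masks) > 0)
  bb <- t(vapply(masks, function(m) {
    idx <- which(m, arr.ind = TRUE)
    c(min(idx[, 2]) - 1, min(idx[, 1]) - 1, max(idx[, 2]), max(idx[, 1]))
  }, numeric(4)))
  detection_table(bb, score = rep(1, length(masks)), mask = masks)
}

## A filled rectangle mask (r0..r1 x c0..c1, 1-based inclusive).
rect_mask <- function(h, w, r0, r1, c0, c1) {
  m <- matrix(FALSE, h, w)
  m[r0:r1, c0:c1] <- TRUE
  m
}

## A filled disc mask centered at (cx, cy) (1-based pixel centers).
disc_mask <- function(h, w, cx, cy, r) {
  m <- matrix(FALSE, h, w)
  for (row in 1:h) for (col in 1:w)
    if ((col - cx)^2 + (row - cy)^2 <= r^2) m[row, col] <- TRUE
  m
}
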