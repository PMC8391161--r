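test_that("mask IoU handles the canonical cases", {
  ## intersection 211 px, union 364 px -> 0.58 at 2 dp
  a <- matrix(FALSE, 1, 400); b <- a
  a[1, 1:300] <- TRUE          # area 300
  b[1, 90:364] <- TRUE         # area 275, intersection 211, union 364
  expect_equal(sum(a & b), 211)
  expect_equal(sum(a | b), 364)
  expect_equal(round(mask_iou(a, b), 2), 0.58)

  m <- rect_mask(10, 10, 2, 5, 2, 5)
  expect_equal(mask_iou(m, m), 1)
  expect_equal(mask_iou(m, rect_mask(10, 10, 7, 9, 7, 9)), 0)
  expect_error(mask_iou(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)), "empty")
  expect_error(mask_iou(m, rect_mask(9, 9, 1, 2, 1, 2)), "frames")
})

test_that("box IoU matches hand arithmetic", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(10, 0, 20, 10)), 0)   # touching
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 1 / 3)
  expect_error(box_iou(c(5, 0, 5, 10), c(0, 0, 1, 1)), "degenerate")
})

test_that("matching follows the single-use ground-truth rule", {
  gt <- rect_mask(20, 20, 3, 10, 3, 10)
  pred <- detection_table(c(2, 2, 10, 10), 0.9, mask = list(gt))
  m <- match_detections(pred, list(gt))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))

  near <- rect_mask(20, 20, 3, 10, 4, 11)
  preds <- detection_table(rbind(c(2, 2, 10, 10), c(3, 2, 11, 10)),
                           score = c(0.9, 0.8), mask = list(gt, near))
  m <- match_detections(preds, list(gt))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 0))
})

test_that("matching counts agree with the brute-force reference", {
  set.seed(17)
  for (trial in 1:60) {
    np <- sample(1:6, 1); ng <- sample(1:6, 1)
    pb <- random_boxes(np, frame = 60, min_side = 8, max_side = 25)
    gb <- random_boxes(ng, frame = 60, min_side = 8, max_side = 25)
    s <- runif(np)
    preds <- detection_table(pb, s)
    gts <- lapply(seq_len(ng), function(j) gb[j, ])
    m <- match_detections(preds, gts, iou_min = 0.3, mode = "box")
    o <- oracle_match(pb, s, 1:np, gb, 0.3)
    expect_equal(c(m$tp, m$fp, m$fn), c(o$tp, o$fp, o$fn))
  }
})

test_that("match results conserve prediction and ground-truth counts", {
  set.seed(18)
  for (trial in 1:40) {
    np <- sample(1:8, 1); ng <- sample(1:8, 1)
    preds <- detection_table(random_boxes(np), runif(np))
    gts <- lapply(seq_len(ng), function(j) random_boxes(1)[1, ])
    m <- match_detections(preds, gts, iou_min = 0.5, mode = "box")
    expect_equal(m$tp + m$fn, ng)
    expect_equal(m$tp + m$fp, np)
    expect_equal(m$tp, nrow(m$pairs))
    if (nrow(m$pairs) > 0) {
      expect_true(all(m$pairs$iou >= 0.5))
      expect_false(any(duplicated(m$pairs$gt)))
      expect_false(any(duplicated(m$pairs$pred_id)))
    }
  }
})

test_that("F1 is the harmonic mean and degenerate counts are flagged", {
  met <- precision_recall_f1(96, 4, 4)
  expect_equal(met$precision, 0.96)
  expect_equal(met$f1, 2 * 0.96 * 0.96 / (0.96 + 0.96))

  expect_equal(round(f1_score(0.960, 0.956), 3), 0.958)
  expect_equal(round(f1_score(0.896, 0.917), 3), 0.906)

  expect_warning(met <- precision_recall_f1(0, 0, 5), "precision undefined")
  expect_equal(met$recall, 0)
  expect_true(is.nan(met$precision))
})

test_that("average precision covers the degenerate extremes", {
  gt1 <- rect_mask(30, 30, 2, 9, 2, 9)
  gt2 <- rect_mask(30, 30, 15, 22, 15, 22)
  perfect <- detection_table(rbind(c(1, 1, 9, 9), c(14, 14, 22, 22)),
                             score = c(0.9, 0.8), mask = list(gt1, gt2))
  expect_equal(average_precision(perfect, list(gt1, gt2))$ap, 1)

  off <- detection_table(c(25, 1, 29, 5), 0.9)
  expect_equal(average_precision(off, list(gt1, gt2), mode = "box")$ap, 0)

  expect_error(average_precision(perfect, list()), "no ground truths")
})

test_that("AP equals the independent per-TP interpolated-precision sum", {
  ## hand-constructed ranking: 5 predictions on 3 ground truths
  gb <- rbind(c(0, 0, 10, 10), c(20, 0, 30, 10), c(40, 0, 50, 10))
  pb <- rbind(c(0, 0, 10, 10),    # hits gt1
              c(60, 0, 70, 10),   # miss
              c(20, 0, 30, 10),   # hits gt2
              c(62, 0, 72, 10),   # miss
              c(40, 0, 50, 10))   # hits gt3
  s <- c(0.95, 0.9, 0.85, 0.8, 0.75)
  preds <- detection_table(pb, s)
  gts <- lapply(1:3, function(j) gb[j, ])
  ap <- average_precision(preds, gts, iou_min = 0.5, mode = "box")$ap
  o <- oracle_match(pb, s, 1:5, gb, 0.5)
  expect_equal(ap, oracle_ap(o$tp_flag, 3))
  ## by hand: precisions 1, 1/2, 2/3, 2/4, 3/5; envelope at TPs 1, 2/3, 3/5
  expect_equal(ap, (1 + 2 / 3 + 3 / 5) / 3)

  set.seed(19)
  for (trial in 1:60) {
    np <- sample(1:12, 1); ng <- sample(1:8, 1)
    pb <- random_boxes(np, frame = 80, min_side = 8, max_side = 25)
    gb <- random_boxes(ng, frame = 80, min_side = 8, max_side = 25)
    s <- runif(np)
    preds <- detection_table(pb, s)
    gts <- lapply(seq_len(ng), function(j) gb[j, ])
    ap <- average_precision(preds, gts, iou_min = 0.3, mode = "box")$ap
    o <- oracle_match(pb, s, 1:np, gb, 0.3)
    expect_equal(ap, oracle_ap(o$tp_flag, ng))
  }
})

test_that("recall is non-decreasing along the PR curve and AP is bounded", {
  set.seed(20)
  pb <- random_boxes(15, frame = 80, min_side = 8, max_side = 25)
  gb <- random_boxes(6, frame = 80, min_side = 8, max_side = 25)
  preds <- detection_table(pb, runif(15))
  gts <- lapply(1:6, function(j) gb[j, ])
  curve <- average_precision(preds, gts, iou_min = 0.3, mode = "box")
  expect_true(all(diff(curve$points$recall) >= 0))
  expect_gte(curve$ap, 0); expect_lte(curve$ap, 1)
})

test_that("the IoU sweep reproduces individual calls and F1 never rises", {
  plate <- easy_plate(seed = 41, n_worms = 6, n_blobs = 0, size = 450)
  masks <- segment_plate(plate$image)
  preds <- masks_as_detections(masks)
  sweep <- iou_sweep(preds, plate$masks, thresholds = c(0.3, 0.5, 0.7, 0.9))
  expect_true(all(diff(sweep$f1) <= 1e-12))   # shrinking match set
  expect_true(all(diff(sweep$tp) <= 0))

  ## each row equals the individual module calls at that threshold
  for (k in seq_len(nrow(sweep))) {
    t <- sweep$iou_min[k]
    m <- match_detections(preds, plate$masks, iou_min = t)
    met <- precision_recall_f1(m)
    expect_equal(sweep$precision[k], met$precision)
    expect_equal(sweep$recall[k], met$recall)
    expect_equal(sweep$ap[k], average_precision(preds, plate$masks, iou_min = t)$ap)
  }
  expect_error(iou_sweep(preds, plate$masks, thresholds = c(0, 0.5)),
               "thresholds")
})
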