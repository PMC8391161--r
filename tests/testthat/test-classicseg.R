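test_that("bilateral filtering preserves constants and edges, shrinks outliers", {
  flat <- matrix(100, 20, 20)
  expect_equal(bilateral_denoise(flat), flat, tolerance = 1e-12)

  ## step edge: the max-gradient column is unchanged
  step <- cbind(matrix(50, 30, 15), matrix(200, 30, 15))
  den <- bilateral_denoise(step)
  grad_in <- which.max(abs(diff(step[15, ])))
  grad_out <- which.max(abs(diff(den[15, ])))
  expect_equal(grad_out, grad_in)

  ## single noisy pixel on a flat field moves strictly toward the field,
  ## by exactly the directly computed weighted average
  noisy <- matrix(100, 21, 21)
  noisy[11, 11] <- 180
  den <- bilateral_denoise(noisy, diameter = 9, sigma_color = 10, sigma_space = 5)
  expect_lt(den[11, 11], 180)
  num <- 0; den_w <- 0
  for (dy in -4:4) for (dx in -4:4) {
    v <- noisy[11 + dy, 11 + dx]
    w <- exp(-(dx^2 + dy^2) / (2 * 5^2)) * exp(-((v - 180)^2) / (2 * 10^2))
    num <- num + w * v; den_w <- den_w + w
  }
  expect_equal(den[11, 11], num / den_w, tolerance = 1e-10)

  expect_error(bilateral_denoise(flat, diameter = 0), "diameter")
})

test_that("grayscale conversion uses the standard luma weights", {
  white <- array(255, dim = c(2, 2, 3))
  expect_equal(to_grayscale(white), matrix(255, 2, 2))
  gray <- matrix(77, 3, 3)
  expect_identical(to_grayscale(gray), gray)
  rgb <- array(0, dim = c(1, 1, 3))
  rgb[1, 1, ] <- c(30, 60, 90)
  expect_equal(to_grayscale(rgb)[1, 1],
               0.299 * 30 + 0.587 * 60 + 0.114 * 90)
})

test_that("adaptive thresholding marks dark structures, not flat fields", {
  expect_false(any(adaptive_binarize(matrix(128, 30, 30), window = 11)))

  ## dark 5-px-wide vertical line on a bright field
  img <- matrix(200, 41, 41)
  img[, 19:23] <- 50
  bin <- adaptive_binarize(img, window = 21, offset_c = 4)
  expect_true(all(bin[, 19:23]))
  expect_false(any(bin[, c(1:10, 32:41)]))

  ## matches a direct per-pixel Gaussian-mean computation
  small <- matrix(c(rep(200, 60), rep(40, 21)), 9, 9)
  w <- 5; sigma <- 0.3 * ((w - 1) * 0.5 - 1) + 0.8
  k <- exp(-((-2:2)^2) / (2 * sigma^2)); k <- k / sum(k)
  ref <- matrix(FALSE, 9, 9)
  for (r in 1:9) for (cc in 1:9) {
    mu <- 0
    for (dy in -2:2) for (dx in -2:2) {
      rr <- min(max(r + dy, 1), 9); ccx <- min(max(cc + dx, 1), 9)
      mu <- mu + k[dy + 3] * k[dx + 3] * small[rr, ccx]
    }
    ref[r, cc] <- small[r, cc] < mu - 4
  }
  expect_identical(adaptive_binarize(small, window = 5, offset_c = 4), ref)

  expect_error(adaptive_binarize(img, window = 20), "odd")
})

test_that("inverting the image and the polarity gives the complementary view", {
  img <- matrix(200, 31, 31)
  img[, 14:18] <- 50
  dark <- adaptive_binarize(img, window = 15, offset_c = 4)
  bright <- adaptive_binarize(255 - img, window = 15, offset_c = 4,
                              polarity = "bright")
  expect_identical(dark, bright)
})

test_that("morphological cleanup removes specks, fills holes, keeps shapes", {
  speck <- matrix(FALSE, 20, 20); speck[10, 10] <- TRUE
  expect_false(any(morph_clean(speck)))

  holed <- rect_mask(30, 30, 5, 24, 5, 24)
  holed[15, 15] <- FALSE
  cleaned <- morph_clean(holed)
  expect_true(cleaned[15, 15])                       # hole filled
  expect_identical(cleaned, rect_mask(30, 30, 5, 24, 5, 24))  # outline kept

  expect_identical(morph_clean(speck, kernel_size = 1), speck)
  expect_error(morph_clean(speck, kernel_size = 4), "odd")
})

test_that("shape descriptors separate discs, bars and worms", {
  disc <- disc_mask(50, 50, 25, 25, 20)
  d <- shape_descriptors(disc)
  expect_gt(d$circularity, 0.9); expect_lt(d$circularity, 1.05)
  expect_gt(d$convexity, 0.95); expect_lte(d$convexity, 1.0)
  expect_gt(d$inertia_ratio, 0.9); expect_lte(d$inertia_ratio, 1.0)
  expect_equal(d$area, sum(disc))

  bar <- rect_mask(10, 110, 4, 6, 5, 104)   # 100 x 3 bar
  b <- shape_descriptors(bar)
  expect_lt(b$inertia_ratio, 0.05)
  expect_gt(b$convexity, 0.9)
  ## closed-form second moments of the rectangle (with pixel-square term)
  expect_equal(b$inertia_ratio, (8 / 12 + 1 / 12) / (9999 / 12 + 1 / 12),
               tolerance = 1e-10)

  ## S-shaped synthetic worm: non-convex and elongated
  t <- seq(0, 2 * pi, length.out = 60)
  skel <- cbind(20 + t * 8, 40 + 18 * sin(t))
  worm <- render_worm(skel, rep(3, 60), c(80, 100))
  s <- shape_descriptors(worm)
  expect_lt(s$convexity, 0.7)
  expect_lt(s$inertia_ratio, 0.2)

  expect_error(shape_descriptors(matrix(FALSE, 5, 5)), "empty")
})

test_that("the blob filter removes small round objects and keeps worms", {
  disc300 <- disc_mask(40, 40, 20, 20, 9.8)         # area ~ 300 px^2
  expect_true(sum(disc300) < 700 && sum(disc300) > 250)
  t <- seq(0, 2 * pi, length.out = 80)
  worm <- render_worm(cbind(20 + t * 12, 50 + 20 * sin(t)), rep(3, 80),
                      c(100, 130))
  expect_gt(sum(worm), 700)

  out <- filter_blobs(list(disc300, worm))
  expect_length(out, 1)
  expect_identical(out[[1]], worm)
  expect_length(filter_blobs(list()), 0)
})

test_that("the size filter applies the conjunctive small-segment rule", {
  tiny <- rect_mask(250, 250, 11, 20, 11, 20)     # bbox 10x10: below both
  thin <- rect_mask(250, 250, 11, 15, 11, 210)    # bbox 5x200: area 1000
  big <- rect_mask(250, 250, 11, 40, 11, 40)      # bbox 30x30
  out <- size_filter(list(tiny, thin, big))
  expect_length(out, 2)   # tiny removed; thin kept under AND
  expect_true(any(vapply(out, identical, logical(1), thin)))

  out_or <- size_filter(list(tiny, thin, big),
                        size_filter_params(policy = "or"))
  expect_length(out_or, 1)   # thin also removed: short edge < 24
  expect_identical(out_or[[1]], big)
})

test_that("the full chain recovers non-overlapping worms and rejects blobs", {
  plate <- easy_plate(seed = 31, n_worms = 8, n_blobs = 20)
  masks <- segment_plate(plate$image)
  expect_equal(length(masks), 8)   # every blob filtered out
  m <- match_detections(masks_as_detections(masks), plate$masks,
                        iou_min = 0.5, mode = "mask")
  expect_gte(m$tp, 7)
  expect_equal(m$fp + m$tp, 8)

  ## every surviving mask is worm-like: outside the blob-removal region
  ## and inside the worm area band
  band <- worm_area_band()
  for (mk in masks) {
    d <- shape_descriptors(mk)
    expect_true(d$area > 700 || d$inertia_ratio < 0.2 || d$circularity <= 0.2)
    expect_gte(d$area, band$min_area)
    expect_lte(d$area, band$max_area)
  }
})

test_that("a blank dish yields no masks and the chain is deterministic", {
  blank <- easy_plate(seed = 2, n_worms = 0, n_blobs = 0, size = 300)
  expect_length(segment_plate(blank$image), 0)

  plate <- easy_plate(seed = 32, n_worms = 4, n_blobs = 3, size = 400)
  a <- segment_plate(plate$image)
  b <- segment_plate(plate$image)
  expect_identical(a, b)
})

test_that("stage composition: segment_plate equals the hand-run chain", {
  plate <- easy_plate(seed = 33, n_worms = 4, n_blobs = 3, size = 400)
  geom <- detect_dish(plate$image)
  manual <- apply_dish_mask(plate$image, geom)
  manual <- bilateral_denoise(manual)
  manual <- to_grayscale(manual)
  manual <- adaptive_binarize(manual)
  manual <- morph_clean(manual)
  expect_identical(segment_plate(plate$image),
                   extract_worm_masks(manual))
})

test_that("adding the blob filter never increases the mask count", {
  plate <- easy_plate(seed = 34, n_worms = 5, n_blobs = 8, size = 450)
  geom <- detect_dish(plate$image)
  bin <- morph_clean(adaptive_binarize(to_grayscale(
    bilateral_denoise(apply_dish_mask(plate$image, geom)))))
  lab <- wormscope:::label_components(bin)
  comps <- wormscope:::masks_from_labels(lab)
  filtered <- filter_blobs(comps)
  expect_lte(length(filtered), length(comps))
  expect_lte(length(size_filter(filtered)), length(filtered))
})
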