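## Classical mask-extraction segmentation chain.
##
## Reusable both as the reference-annotation generator and as a
## classical baseline worm detector: bilateral denoising, grayscale
## conversion, Gaussian adaptive thresholding, morphological cleanup,
## connected-component extraction, and shape-descriptor filtering that
## removes round blob artifacts (trapped air/gas in the agar) while
## keeping elongated worms.

#' Blob-removal filter parameters
#'
#' A connected component is removed as a blob artifact when its
#' descriptors fall inside ALL of these ranges: blobs are small, round
#' and convex, whereas worms are elongated, larger than 700 px^2 and
#' have a low inertia ratio.
#'
#' @param area_range Pixel-area range `(min, max)`; default `(0, 700)`.
#' @param convexity_range Area / convex-hull-area range; default
#'   `(0.3, 1)`.
#' @param circularity_min Lower circularity bound (`4*pi*A/P^2`);
#'   default 0.2.
#' @param inertia_range Principal-moment-ratio range; default
#'   `(0.2, 1)`.
#' @return A `blob_filter_params` list.
#' @export
blob_filter_params <- function(area_range = c(0, 700),
                               convexity_range = c(0.3, 1),
                               circularity_min = 0.2,
                               inertia_range = c(0.2, 1)) {
  for (nm in c("area_range", "convexity_range", "inertia_range")) {
    v <- get(nm)
    if (length(v) != 2L || v[1] > v[2]) stopf("blob_filter_params: %s must be ordered (min, max)", nm)
  }
  if (any(c(convexity_range, inertia_range) < 0) || any(c(convexity_range, inertia_range) > 1))
    stopf("blob_filter_params: convexity/inertia fractions must lie in [0, 1]")
  structure(list(area_range = area_range, convexity_range = convexity_range,
                 circularity_min = circularity_min, inertia_range = inertia_range),
            class = "blob_filter_params")
}

#' Small-segment size-filter parameters
#'
#' Segments whose bounding box covers less than `min_bbox_area` px^2
#' and whose shorter bbox edge is below `min_edge` px are removed as
#' too small for meaningful analysis.
#'
#' @param min_bbox_area Minimum bounding-box area in px^2; default 700.
#' @param min_edge Minimum shorter bbox edge in px; default 24.
#' @param policy `"and"` (default; both conditions must hold for
#'   removal) or `"or"` (either suffices).
#' @return A `size_filter_params` list.
#' @export
size_filter_params <- function(min_bbox_area = 700, min_edge = 24,
                               policy = c("and", "or")) {
  if (min_bbox_area < 0 || min_edge < 0)
    stopf("size_filter_params: bounds must be >= 0")
  structure(list(min_bbox_area = min_bbox_area, min_edge = min_edge,
                 policy = match.arg(policy)),
            class = "size_filter_params")
}

#' Accepted worm pixel-area band
#'
#' Components similar to worms in shape but differing in area from the
#' average adult worm are rejected; this band replaces the visual
#' inspection step of a semi-automatic workflow with an explicit
#' parameter.
#'
#' @param min_area,max_area Accepted mask pixel-area range in px^2.
#' @return A `worm_area_band` list.
#' @export
worm_area_band <- function(min_area = 700, max_area = 6000) {
  if (min_area >= max_area) stopf("worm_area_band: min_area must be < max_area")
  structure(list(min_area = min_area, max_area = max_area), class = "worm_area_band")
}

#' Edge-preserving bilateral denoising
#'
#' Each output pixel is the normalized average of its neighborhood,
#' weighted by both spatial distance (sigma `sigma_space`) and
#' intensity difference (sigma `sigma_color`), so flat regions are
#' smoothed while sharp edges survive. RGB input is filtered per
#' channel.
#'
#' @param image Grayscale matrix or RGB array, 0..255.
#' @param diameter Neighborhood diameter in px (odd); default 9.
#' @param sigma_color Range sigma in gray levels; default 10.
#' @param sigma_space Spatial sigma in px; default 5.
#' @return The denoised image, same shape.
#' @export
bilateral_denoise <- function(image, diameter = 9L, sigma_color = 10,
                              sigma_space = 5) {
  if (diameter <= 0) stopf("bilateral_denoise: diameter must be positive")
  d <- dim(image)
  if (length(d) == 3L) {
    for (ch in seq_len(d[3L]))
      image[, , ch] <- bilateral_denoise(image[, , ch], diameter, sigma_color, sigma_space)
    return(image)
  }
  r <- as.integer(diameter) %/% 2L
  if (r == 0L) return(image)
  h <- nrow(image); w <- ncol(image)
  padded <- pad_replicate(image, r)
  num <- matrix(0, h, w)
  den <- matrix(0, h, w)
  for (dy in -r:r) {
    for (dx in -r:r) {
      sw <- exp(-(dx^2 + dy^2) / (2 * sigma_space^2))
      shifted <- padded[(r + 1L + dy):(r + h + dy), (r + 1L + dx):(r + w + dx)]
      rw <- exp(-((shifted - image)^2) / (2 * sigma_color^2))
      wgt <- sw * rw
      num <- num + wgt * shifted
      den <- den + wgt
    }
  }
  num / den
}

#' Gaussian adaptive thresholding
#'
#' A pixel becomes foreground when its value is below the
#' Gaussian-weighted mean of its `window`-pixel neighborhood minus
#' `offset_c`. On brightfield plates worms are darker than the agar, so
#' worm bodies come out as foreground. `polarity = "bright"` inverts
#' the convention (foreground above mean + C).
#'
#' @param gray Grayscale matrix, 0..255.
#' @param window Odd neighborhood width in px; default 71.
#' @param offset_c Constant subtracted from the local mean; default 4.
#' @param polarity `"dark"` (default) or `"bright"` foreground.
#' @return A logical matrix (TRUE = foreground).
#' @export
adaptive_binarize <- function(gray, window = 71L, offset_c = 4,
                              polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (window < 3L || window %% 2L == 0L)
    stopf("adaptive_binarize: window must be odd and >= 3")
  mu <- local_gaussian_mean(gray, as.integer(window))
  if (polarity == "dark") gray < mu - offset_c else gray > mu + offset_c
}

#' Morphological cleanup: closing then opening
#'
#' Closing (dilation then erosion) fills small holes inside large
#' objects; opening (erosion then dilation) then removes specks smaller
#' than the structuring element. A 1-px kernel is the identity.
#'
#' @param binary Logical or 0/1 matrix.
#' @param kernel_size Odd structuring-element width in px; default 3
#'   (3 x 3 block).
#' @return A logical matrix.
#' @export
morph_clean <- function(binary, kernel_size = 3L) {
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stopf("morph_clean: kernel_size must be odd and >= 1")
  if (kernel_size == 1L) return(binary > 0)
  kern <- EBImage::makeBrush(as.integer(kernel_size), shape = "disc")
  x <- binary * 1
  x <- EBImage::closing(x, kern)
  x <- EBImage::opening(x, kern)
  matrix(as.numeric(x), nrow(binary), ncol(binary)) > 0.5
}

#' Shape descriptors of one connected component
#'
#' Computed from the component's pixels and outer contour, following
#' the conventions of standard blob detectors: `area` is the pixel
#' count, `perimeter` the length of the traced outer contour,
#' `circularity = 4*pi*area / perimeter^2`, `convexity` the ratio of
#' pixel area to convex-hull area, and `inertia_ratio` the ratio of the
#' smaller to the larger principal second central moment (1 for a disc,
#' near 0 for a thin bar or worm).
#'
#' @param component Logical mask of a single connected component.
#' @return A `shape_descriptors` list.
#' @export
shape_descriptors <- function(component) {
  idx <- which(component, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stopf("shape_descriptors: empty component")
  area <- n
  x <- idx[, 2L]; y <- idx[, 1L]

  ## perimeter from the traced outer contour (sum of step lengths)
  ct <- EBImage::ocontour(component * 1)
  perimeter <- if (length(ct) >= 1L && nrow(ct[[1L]]) >= 2L) {
    p <- ct[[1L]]
    steps <- sqrt(diff(c(p[, 1L], p[1L, 1L]))^2 + diff(c(p[, 2L], p[1L, 2L]))^2)
    sum(steps)
  } else 4  # single pixel

  circularity <- 4 * pi * area / perimeter^2

  ## convex hull over pixel outlines (corners of the unit squares) so a
  ## single row of pixels still has positive hull area
  cx <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  cy <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  hull <- grDevices::chull(cx, cy)
  hx <- cx[hull]; hy <- cy[hull]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  convexity <- if (hull_area > 0) area / hull_area else 1

  mu20 <- mean((x - mean(x))^2) + 1 / 12   # + pixel-square moment
  mu02 <- mean((y - mean(y))^2) + 1 / 12
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  inertia_ratio <- if (l1 > 0) max(0, l2) / l1 else 1

  structure(list(area = area, perimeter = perimeter, convexity = convexity,
                 circularity = circularity, inertia_ratio = inertia_ratio),
            class = "shape_descriptors")
}

#' @export
print.shape_descriptors <- function(x, ...) {
  cat(sprintf("area %d px^2, perimeter %.1f px, circularity %.3f, convexity %.3f, inertia %.3f\n",
              x$area, x$perimeter, x$circularity, x$convexity, x$inertia_ratio))
  invisible(x)
}

#' Remove round blob artifacts from a component list
#'
#' A component is removed iff its descriptors fall inside ALL blob
#' ranges (small area, high convexity, circularity above the floor,
#' inertia ratio in range) — the signature of trapped air or gas
#' bubbles in the agar. Anything failing at least one range (in
#' particular any adult worm, whose area and inertia ratio fall
#' outside) is kept.
#'
#' @param components List of logical instance masks.
#' @param params A [blob_filter_params()].
#' @return The filtered list.
#' @export
filter_blobs <- function(components, params = blob_filter_params()) {
  stopifnot(inherits(params, "blob_filter_params"))
  keep <- vapply(components, function(m) {
    d <- shape_descriptors(m)
    is_blob <- d$area >= params$area_range[1] && d$area <= params$area_range[2] &&
      d$convexity >= params$convexity_range[1] && d$convexity <= params$convexity_range[2] &&
      d$circularity > params$circularity_min &&
      d$inertia_ratio >= params$inertia_range[1] && d$inertia_ratio <= params$inertia_range[2]
    !is_blob
  }, logical(1))
  components[keep]
}

#' Remove segments too small for meaningful analysis
#'
#' Under the default `"and"` policy a mask is removed iff its bounding
#' box covers less than `min_bbox_area` px^2 AND its shorter bbox edge
#' is below `min_edge` px; under `"or"`, either condition suffices.
#'
#' @param masks List of logical instance masks.
#' @param params A [size_filter_params()].
#' @return The filtered list.
#' @export
size_filter <- function(masks, params = size_filter_params()) {
  stopifnot(inherits(params, "size_filter_params"))
  keep <- vapply(masks, function(m) {
    bb <- mask_bbox(m)
    !small_bbox(bb, params)
  }, logical(1))
  masks[keep]
}

small_bbox <- function(bb, params) {
  area <- bbox_area(bb)
  short_edge <- min(bb[3L] - bb[1L], bb[4L] - bb[2L])
  below_area <- area < params$min_bbox_area
  below_edge <- short_edge < params$min_edge
  if (params$policy == "and") below_area && below_edge else below_area || below_edge
}

#' Extract per-worm instance masks from a binarized plate
#'
#' Labels connected components (8-connectivity), then applies the blob
#' filter, the small-segment size filter, and the worm pixel-area band.
#' Each surviving component is returned as one instance mask — one mask
#' encoding a single worm (crossing worms merge into one component and
#' are returned as one instance).
#'
#' @param binary Logical matrix from the thresholding/morphology chain.
#' @param band A [worm_area_band()].
#' @param blob_params A [blob_filter_params()].
#' @param size_params A [size_filter_params()].
#' @return List of logical instance masks.
#' @export
extract_worm_masks <- function(binary, band = worm_area_band(),
                               blob_params = blob_filter_params(),
                               size_params = size_filter_params()) {
  stopifnot(inherits(band, "worm_area_band"))
  lab <- label_components(binary, connectivity = 8L)
  masks <- masks_from_labels(lab)
  masks <- filter_blobs(masks, blob_params)
  masks <- size_filter(masks, size_params)
  areas <- vapply(masks, sum, numeric(1))
  masks[areas >= band$min_area & areas <= band$max_area]
}

#' Full classical segmentation of a plate image
#'
#' Runs the whole chain: optional dish masking, bilateral denoising,
#' grayscale conversion, Gaussian adaptive thresholding, morphological
#' closing + opening, connected-component extraction and blob/size/area
#' filtering. Entirely deterministic.
#'
#' @param image Grayscale matrix or RGB array, 0..255 (or a file path
#'   readable by [read_image()]).
#' @param dish `TRUE` to locate and mask the dish first, `FALSE` to
#'   skip, or a [dish_geometry()] to use directly.
#' @param bilateral_diameter,sigma_color,sigma_space See
#'   [bilateral_denoise()].
#' @param window,offset_c See [adaptive_binarize()].
#' @param kernel_size See [morph_clean()].
#' @param band,blob_params,size_params See [extract_worm_masks()].
#' @return List of logical instance masks in full-image coordinates.
#' @export
segment_plate <- function(image, dish = TRUE,
                          bilateral_diameter = 9L, sigma_color = 10, sigma_space = 5,
                          window = 71L, offset_c = 4, kernel_size = 3L,
                          band = worm_area_band(),
                          blob_params = blob_filter_params(),
                          size_params = size_filter_params()) {
  if (is.character(image)) image <- read_image(image)
  if (inherits(dish, "dish_geometry")) {
    image <- apply_dish_mask(image, dish)
  } else if (isTRUE(dish)) {
    image <- apply_dish_mask(image, detect_dish(image))
  }
  image <- bilateral_denoise(image, bilateral_diameter, sigma_color, sigma_space)
  gray <- to_grayscale(image)
  binary <- adaptive_binarize(gray, window, offset_c)
  binary <- morph_clean(binary, kernel_size)
  extract_worm_masks(binary, band, blob_params, size_params)
}
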