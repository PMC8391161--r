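## Synthetic Petri-dish image generator.
##
## Emulates a whole-plate brightfield capture: a bright circular agar disc
## with a dark rim annulus on a black background, thin dark curved worms,
## near-circular dark blob artifacts (trapped air in the agar), and
## additive Gaussian sensor noise. Every worm comes with its exact pixel
## mask, so the segmentation and evaluation stages can be validated
## against known ground truth.

#' Configuration for the synthetic dish generator
#'
#' Defaults emulate the nominal full-plate capture geometry
#' (3280 x 2464 px) with adult worms whose rendered masks are roughly
#' 850-1600 px^2 — comfortably above the 700 px^2 / 24 px small-segment
#' filters, as adult worms are on real plates. Tests use much smaller
#' frames by overriding `image_width`/`image_height` and the dish radius.
#'
#' @param image_width,image_height Frame size in px.
#' @param dish_center `(x, y)` of the dish center in px (0-based,
#'   continuous); defaults to the frame center.
#' @param dish_radius Radius of the bright agar disc in px; default 44%
#'   of the smaller frame dimension.
#' @param rim_width Width of the dark dish-rim annulus in px.
#' @param n_worms,n_blobs Number of worms / circular blob artifacts.
#' @param worm_length_range `(min, max)` worm skeleton length in px.
#' @param worm_halfwidth Peak half-width of the worm body in px; the
#'   body tapers toward head and tail.
#' @param blob_radius_range `(min, max)` blob radius in px.
#' @param noise_sigma Additive Gaussian noise sigma in gray levels.
#' @param background_level,worm_level,rim_level,blob_level Gray levels
#'   (0..255) of the agar, worms, rim annulus and blobs.
#' @param allow_overlap If `FALSE`, worms are rejection-sampled so that
#'   no two worm masks (or blob discs) touch — easy fixtures for
#'   segmentation tests. Default `TRUE` (worms on real plates cross).
#' @param min_area_ratio Postures whose rendered mask area falls below
#'   this fraction of the straightened body footprint
#'   (`length * (2 * mean halfwidth + 1)`) are resampled: tightly
#'   self-coiled bodies would otherwise lose the calibrated adult mask
#'   area. Set to 0 to allow arbitrary coiling.
#' @param worm_margin Worm skeletons are kept within
#'   `worm_margin * dish_radius` of the dish center, away from the
#'   contrast-rich rim region.
#' @param seed Integer seed; identical configurations (including seed)
#'   produce bit-identical images and masks.
#' @return A validated `synth_config` list.
#' @seealso [generate_dish_image()]
#' @export
synth_config <- function(image_width = 3280L, image_height = 2464L,
                         dish_center = NULL, dish_radius = NULL,
                         rim_width = NULL, n_worms = 10L,
                         worm_length_range = c(120, 180),
                         worm_halfwidth = 5,
                         n_blobs = 5L, blob_radius_range = c(4, 14),
                         noise_sigma = 4, background_level = 200,
                         worm_level = 60, rim_level = 35, blob_level = 70,
                         allow_overlap = TRUE, worm_margin = 0.8,
                         min_area_ratio = 0.8, seed = 1L) {
  half <- min(image_width, image_height) / 2
  if (is.null(dish_radius)) dish_radius <- floor(0.44 * min(image_width, image_height))
  if (is.null(rim_width)) rim_width <- max(4, floor(0.05 * half))
  if (is.null(dish_center)) dish_center <- c(image_width / 2, image_height / 2)
  cfg <- list(
    image_width = as.integer(image_width), image_height = as.integer(image_height),
    dish_center = as.numeric(dish_center), dish_radius = as.numeric(dish_radius),
    rim_width = as.numeric(rim_width), n_worms = as.integer(n_worms),
    worm_length_range = as.numeric(worm_length_range),
    worm_halfwidth = as.numeric(worm_halfwidth),
    n_blobs = as.integer(n_blobs), blob_radius_range = as.numeric(blob_radius_range),
    noise_sigma = as.numeric(noise_sigma), background_level = as.numeric(background_level),
    worm_level = as.numeric(worm_level), rim_level = as.numeric(rim_level),
    blob_level = as.numeric(blob_level), allow_overlap = isTRUE(allow_overlap),
    worm_margin = as.numeric(worm_margin),
    min_area_ratio = as.numeric(min_area_ratio), seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (cfg$image_width < 8L || cfg$image_height < 8L)
    stopf("synth_config: image_width/image_height must be at least 8 px")
  if (cfg$dish_radius <= 0)
    stopf("synth_config: dish_radius must be positive")
  if (cfg$dish_radius + cfg$rim_width > min(cfg$image_width, cfg$image_height) / 2)
    stopf("synth_config: dish_radius + rim_width exceeds half the smaller frame dimension")
  if (cfg$n_worms < 0L) stopf("synth_config: n_worms must be >= 0")
  if (cfg$n_blobs < 0L) stopf("synth_config: n_blobs must be >= 0")
  if (length(cfg$worm_length_range) != 2L || cfg$worm_length_range[1] > cfg$worm_length_range[2])
    stopf("synth_config: worm_length_range must be an ordered (min, max) pair")
  if (length(cfg$blob_radius_range) != 2L || cfg$blob_radius_range[1] > cfg$blob_radius_range[2])
    stopf("synth_config: blob_radius_range must be an ordered (min, max) pair")
  if (cfg$worm_halfwidth < 0) stopf("synth_config: worm_halfwidth must be >= 0")
  if (cfg$noise_sigma < 0) stopf("synth_config: noise_sigma must be >= 0")
  if (cfg$worm_margin <= 0 || cfg$worm_margin > 1)
    stopf("synth_config: worm_margin must be in (0, 1]")
  if (cfg$min_area_ratio < 0 || cfg$min_area_ratio > 1)
    stopf("synth_config: min_area_ratio must be in [0, 1]")
  cfg
}

## Random smoothed-heading walk for one worm skeleton: unit steps, the
## heading receives Normal(0, sigma_turn) increments, and steers back
## toward the dish center when the walk approaches the placement circle.
## Produces the sinusoidal postures adult C. elegans show on agar.
random_worm_skeleton <- function(cfg, sigma_turn = 0.12) {
  len <- round(runif(1, cfg$worm_length_range[1], cfg$worm_length_range[2]))
  rmax <- cfg$worm_margin * cfg$dish_radius - cfg$worm_halfwidth - 2
  ## uniform start in the placement disc
  repeat {
    sx <- runif(1, -rmax, rmax); sy <- runif(1, -rmax, rmax)
    if (sx^2 + sy^2 <= rmax^2) break
  }
  cx <- cfg$dish_center[1] + sx
  cy <- cfg$dish_center[2] + sy
  theta <- runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, len, 2L)
  pts[1L, ] <- c(cx, cy)
  for (i in seq_len(len - 1L)) {
    theta <- theta + rnorm(1, 0, sigma_turn)
    nxt <- pts[i, ] + c(cos(theta), sin(theta))
    d2 <- (nxt[1] - cfg$dish_center[1])^2 + (nxt[2] - cfg$dish_center[2])^2
    if (d2 > rmax^2) {
      ## steer back toward the dish center
      theta <- atan2(cfg$dish_center[2] - pts[i, 2L], cfg$dish_center[1] - pts[i, 1L]) +
        rnorm(1, 0, sigma_turn)
      nxt <- pts[i, ] + c(cos(theta), sin(theta))
    }
    pts[i + 1L, ] <- nxt
  }
  pts
}

## Half-width profile tapering toward both ends (head and tail).
halfwidth_profile <- function(n, halfwidth) {
  if (n == 1L) return(halfwidth)
  t <- (seq_len(n) - 1) / (n - 1)
  halfwidth * sqrt(pmax(4 * t * (1 - t), 0.04))
}

#' Rasterize a worm body as the union of discs along its skeleton
#'
#' The worm mask is the union of discs centered on the skeleton points,
#' with per-point radii from the half-width profile. The polyline is
#' resampled at sub-pixel spacing first so the mask is 4-connected; with
#' an all-zero profile the mask degenerates to the rasterized skeleton
#' line.
#'
#' @param skeleton n x 2 matrix of `(x, y)` points in px (continuous
#'   coordinates; pixel `[y, x]` has center `(x, y)`). At least 2 points.
#' @param halfwidth_profile Numeric vector of per-point disc radii in px,
#'   same length as the skeleton (a scalar is recycled).
#' @param image_shape `(height, width)` of the output frame.
#' @return A logical matrix mask of dimension `image_shape`.
#' @export
render_worm <- function(skeleton, halfwidth_profile, image_shape) {
  if (is.null(dim(skeleton)) || nrow(skeleton) < 2L)
    stopf("render_worm: skeleton needs at least 2 points")
  n <- nrow(skeleton)
  if (length(halfwidth_profile) == 1L) halfwidth_profile <- rep(halfwidth_profile, n)
  if (length(halfwidth_profile) != n)
    stopf("render_worm: halfwidth profile length (%d) != skeleton length (%d)",
          length(halfwidth_profile), n)
  h <- image_shape[1L]; w <- image_shape[2L]
  mask <- matrix(FALSE, h, w)

  ## densify the polyline (spacing <= 0.35 px) interpolating the profile
  seg <- sqrt(diff(skeleton[, 1L])^2 + diff(skeleton[, 2L])^2)
  s <- c(0, cumsum(seg))
  total <- s[n]
  if (total == 0) stopf("render_worm: degenerate skeleton of zero length")
  ## keep the original vertex positions in the sample grid so discs at
  ## the stated skeleton points are rendered exactly
  sq <- sort(unique(c(s, seq(0, total, by = 0.35))))
  xs <- stats::approx(s, skeleton[, 1L], xout = sq, ties = "ordered")$y
  ys <- stats::approx(s, skeleton[, 2L], xout = sq, ties = "ordered")$y
  hs <- stats::approx(s, halfwidth_profile, xout = sq, ties = "ordered")$y

  for (i in seq_along(xs)) {
    r <- hs[i]
    if (r <= 0) next
    c0 <- max(1L, floor(xs[i] - r)); c1 <- min(w, ceiling(xs[i] + r))
    r0 <- max(1L, floor(ys[i] - r)); r1 <- min(h, ceiling(ys[i] + r))
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    d2 <- outer((rows - ys[i])^2, (cols - xs[i])^2, `+`)
    mask[rows, cols] <- mask[rows, cols] | (d2 <= r^2)
  }

  if (all(hs <= 0)) {
    ## zero half-width: 4-connected rasterized skeleton line
    px <- pmin(pmax(round(xs), 1L), w)
    py <- pmin(pmax(round(ys), 1L), h)
    mask[cbind(py[1L], px[1L])] <- TRUE
    for (i in seq_along(px)[-1L]) {
      mask[py[i], px[i]] <- TRUE
      if (px[i] != px[i - 1L] && py[i] != py[i - 1L])
        mask[py[i - 1L], px[i]] <- TRUE  # break the diagonal step
    }
  }
  if (!any(mask)) stopf("render_worm: skeleton lies outside the frame")
  mask
}

draw_disc <- function(canvas, cx, cy, r, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  c0 <- max(1L, floor(cx - r)); c1 <- min(w, ceiling(cx + r))
  r0 <- max(1L, floor(cy - r)); r1 <- min(h, ceiling(cy + r))
  if (c0 > c1 || r0 > r1) return(canvas)
  cols <- c0:c1; rows <- r0:r1
  d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
  block <- canvas[rows, cols]
  block[d2 <= r^2] <- value
  canvas[rows, cols] <- block
  canvas
}

#' Generate a synthetic Petri-dish image with per-worm ground truth
#'
#' Renders the bright agar disc and dark rim annulus on a black
#' background, places `n_worms` dark curved worms and `n_blobs` dark
#' circular artifacts inside the dish, then adds Gaussian sensor noise.
#' Deterministic given the configuration (including its seed).
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_plate` with elements `image` (numeric
#'   matrix, gray 0..255), `masks` (list of logical ground-truth masks,
#'   one per worm, same frame), `worms` (skeletons and half-width
#'   profiles) and `config`.
#' @export
#' @examples
#' plate <- generate_dish_image(synth_config(
#'   image_width = 200, image_height = 200, n_worms = 2, n_blobs = 0,
#'   worm_length_range = c(30, 40), worm_halfwidth = 2, noise_sigma = 0,
#'   seed = 7))
#' length(plate$masks)
generate_dish_image <- function(config) {
  cfg <- validate_synth_config(config)
  withr::with_seed(cfg$seed, {
    h <- cfg$image_height; w <- cfg$image_width
    img <- matrix(0, h, w)
    cx <- cfg$dish_center[1]; cy <- cfg$dish_center[2]
    d2 <- outer(((1:h) - 0.5 - cy)^2, ((1:w) - 0.5 - cx)^2, `+`)
    img[d2 <= (cfg$dish_radius + cfg$rim_width)^2] <- cfg$rim_level
    img[d2 <= cfg$dish_radius^2] <- cfg$background_level

    occupied <- matrix(FALSE, h, w)  # union of placed worm masks
    masks <- vector("list", cfg$n_worms)
    worms <- vector("list", cfg$n_worms)
    i <- 0L
    tries <- 0L
    while (i < cfg$n_worms) {
      tries <- tries + 1L
      skel <- random_worm_skeleton(cfg)
      prof <- halfwidth_profile(nrow(skel), cfg$worm_halfwidth)
      ## skeleton coordinates are (x, y) with pixel [y, x] centered at
      ## (x - 0.5, y - 0.5) in the 0-based frame; shift to 1-based centers
      m <- render_worm(cbind(skel[, 1L] + 0.5, skel[, 2L] + 0.5), prof, c(h, w))
      footprint <- nrow(skel) * (2 * mean(prof) + 1)
      if (sum(m) < cfg$min_area_ratio * footprint && tries < 200L)
        next  # tightly coiled posture: resample
      if (!cfg$allow_overlap) {
        dil <- EBImage::dilate(m * 1, EBImage::makeBrush(5, "box"))
        if (any(dil > 0 & occupied) && tries < 200L) next  # resample this worm
      }
      i <- i + 1L
      masks[[i]] <- m
      worms[[i]] <- list(skeleton = skel, halfwidth_profile = prof)
      occupied <- occupied | m
      img[m] <- cfg$worm_level
    }

    if (cfg$n_blobs > 0L) {
      rmax <- cfg$worm_margin * cfg$dish_radius
      placed <- 0L
      while (placed < cfg$n_blobs) {
        r <- runif(1, cfg$blob_radius_range[1], cfg$blob_radius_range[2])
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * (rmax - r - 2)
        bx <- cx + rad * cos(ang); by <- cy + rad * sin(ang)
        if (!cfg$allow_overlap) {
          ## keep easy fixtures clean: blobs touch neither worms nor
          ## other blobs (touching discs would merge into an elongated,
          ## worm-sized component)
          h0 <- max(1L, floor(by - r - 2)); h1 <- min(h, ceiling(by + r + 2))
          w0 <- max(1L, floor(bx - r - 2)); w1 <- min(w, ceiling(bx + r + 2))
          if (any(occupied[h0:h1, w0:w1])) next
          occupied[h0:h1, w0:w1] <- TRUE
        }
        img <- draw_disc(img, bx + 0.5, by + 0.5, r, cfg$blob_level)
        placed <- placed + 1L
      }
    }

    if (cfg$noise_sigma > 0)
      img <- img + matrix(rnorm(h * w, 0, cfg$noise_sigma), h, w)
    img <- round(clip255(img))

    structure(
      list(image = img, masks = masks[seq_len(cfg$n_worms)],
           worms = worms[seq_len(cfg$n_worms)], config = cfg),
      class = "synth_plate"
    )
  })
}

#' @export
print.synth_plate <- function(x, ...) {
  cat(sprintf("synthetic plate %dx%d px, %d worms, %d blobs, seed %d\n",
              x$config$image_width, x$config$image_height,
              x$config$n_worms, x$config$n_blobs, x$config$seed))
  invisible(x)
}

#' Write a synthetic plate (or any image + masks) as a reusable fixture
#'
#' Writes `image.png`, one `mask_NNN.png` per instance, and a
#' `manifest.json` listing, for every instance, its id, minimal bounding
#' box `[x0, y0, w, h]`, pixel area and mask file. The manifest also
#' records the generator configuration and seed when available.
#'
#' @param image Numeric matrix, gray 0..255 (or a `synth_plate`, in
#'   which case `masks` is taken from it).
#' @param masks List of logical instance masks in the same frame.
#' @param out_dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_fixture <- function(image, masks = NULL, out_dir) {
  cfg <- NULL
  if (inherits(image, "synth_plate")) {
    masks <- image$masks
    cfg <- image$config
    image <- image$image
  }
  if (is.null(masks)) masks <- list()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("write_fixture: cannot create directory '%s'", out_dir)
  png::writePNG(image / 255, file.path(out_dir, "image.png"))
  instances <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    mf <- sprintf("mask_%03d.png", i)
    png::writePNG(masks[[i]] * 1, file.path(out_dir, mf))
    bb <- mask_bbox(masks[[i]])
    instances[[i]] <- list(
      id = i,
      bbox = c(bb[["x0"]], bb[["y0"]], bb[["x1"]] - bb[["x0"]], bb[["y1"]] - bb[["y0"]]),
      area = sum(masks[[i]]),
      mask_file = mf
    )
  }
  manifest <- list(instances = instances)
  if (!is.null(cfg)) {
    manifest$config <- unclass(cfg)
    manifest$seed <- cfg$seed
  }
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read back a fixture written by [write_fixture()]
#'
#' @param dir Fixture directory containing `manifest.json`.
#' @return List with `image` (numeric matrix 0..255), `masks` (list of
#'   logical masks) and `manifest` (parsed JSON).
#' @export
read_fixture <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stopf("read_fixture: no manifest.json in '%s'", dir)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  image <- round(png::readPNG(file.path(dir, "image.png")) * 255)
  if (length(dim(image)) == 3L) image <- to_grayscale(image * 255) / 255 * 255
  masks <- lapply(manifest$instances, function(inst) {
    m <- png::readPNG(file.path(dir, inst$mask_file))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m > 0.5
  })
  list(image = image, masks = masks, manifest = manifest)
}
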