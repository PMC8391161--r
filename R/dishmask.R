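## Dish localization and background masking.
##
## The rim region of a Petri dish is contrast-rich and frequently
## produces false worm detections, while holding no worms; everything
## outside the usable agar circle is therefore blackened before any
## detection runs.

#' Dish geometry
#'
#' Circle bounding the usable agar region, in 0-based continuous pixel
#' coordinates (pixel `[y, x]` has center `(x - 0.5, y - 0.5)`).
#'
#' @param center_x,center_y Circle center in px.
#' @param radius Circle radius in px (> 0).
#' @param margin_fraction Fraction in `[0, 0.5)` by which the effective
#'   radius is shrunk when masking, removing the contrast-rich rim zone.
#' @return A `dish_geometry` list.
#' @export
dish_geometry <- function(center_x, center_y, radius, margin_fraction = 0.05) {
  if (radius <= 0) stopf("dish_geometry: radius must be positive")
  if (margin_fraction < 0 || margin_fraction >= 0.5)
    stopf("dish_geometry: margin_fraction must be in [0, 0.5)")
  structure(
    list(center_x = as.numeric(center_x), center_y = as.numeric(center_y),
         radius = as.numeric(radius), margin_fraction = as.numeric(margin_fraction)),
    class = "dish_geometry"
  )
}

#' @export
print.dish_geometry <- function(x, ...) {
  cat(sprintf("dish: center (%.1f, %.1f), radius %.1f px, margin %.2f\n",
              x$center_x, x$center_y, x$radius, x$margin_fraction))
  invisible(x)
}

#' Locate the Petri dish on a whole-plate image
#'
#' Scans the horizontal line through the image's vertical center for the
#' characteristic luminance transitions at the dish edge. The line is
#' smoothed with a width-5 moving average, and a transition is any
#' position where the absolute luminance difference across a small
#' window exceeds `luminance_jump`. The first and last transitions are
#' taken as the endpoints of the dish's horizontal diameter; the circle
#' center is their midpoint on the scan line.
#'
#' If the dish edge runs off one side of the frame, the corresponding
#' image border is used as that diameter endpoint (the radius is clamped
#' to the frame). If no transition is found at all, a "dish not found"
#' error is raised; callers may fall back to a full-image circle.
#'
#' @param image Grayscale matrix or RGB array, 0..255.
#' @param luminance_jump Transition threshold in gray levels; default
#'   25% of the image's dynamic range.
#' @param margin_fraction Stored in the returned geometry (see
#'   [dish_geometry()]).
#' @param smooth_width Moving-average width for the scan line.
#' @param diff_lag Window (px) over which the luminance difference is
#'   evaluated.
#' @return A [dish_geometry()].
#' @export
detect_dish <- function(image, luminance_jump = NULL, margin_fraction = 0.05,
                        smooth_width = 5L, diff_lag = 3L) {
  gray <- to_grayscale(image)
  h <- nrow(gray); w <- ncol(gray)
  if (h < 1L || w < diff_lag + 1L) stopf("detect_dish: image too small")
  if (is.null(luminance_jump)) {
    rng <- range(gray)
    luminance_jump <- 0.25 * (rng[2] - rng[1])
  }
  if (luminance_jump <= 0) stopf("dish not found: image has no luminance variation")

  row <- gray[max(1L, round(h / 2)), ]
  ## centered moving average; ends replicate-padded
  k <- rep(1 / smooth_width, smooth_width)
  r <- (smooth_width - 1L) %/% 2L
  padded <- c(rep(row[1L], r), row, rep(row[w], r))
  sm <- as.numeric(stats::filter(padded, k, sides = 2))
  sm <- sm[(r + 1L):(r + w)]

  d <- abs(sm[(diff_lag + 1L):w] - sm[seq_len(w - diff_lag)])
  hits <- which(d > luminance_jump)
  if (length(hits) == 0L) stopf("dish not found: no luminance transition on the center scan line")

  half <- floor(w / 2)
  left_hits <- hits[hits <= half]
  right_hits <- hits[hits > half]
  ## localize each edge at the maximum-gradient position of its
  ## transition run (the first run on the left, the last on the right):
  ## unbiased against the smear introduced by smoothing
  run_peak <- function(run_hits, take_first) {
    runs <- split(run_hits, cumsum(c(1, diff(run_hits) > 1)))
    run <- if (take_first) runs[[1L]] else runs[[length(runs)]]
    mean(run[d[run] == max(d[run])])   # center of a gradient plateau
  }
  ## d[i] spans pixel centers (i - 0.5) .. (i + diff_lag - 0.5), 0-based;
  ## the transition sits at the window midpoint
  mid_off <- (diff_lag - 1) / 2
  left <- if (length(left_hits)) run_peak(left_hits, TRUE) + mid_off else 0
  right <- if (length(right_hits)) run_peak(right_hits, FALSE) + mid_off else w
  if (length(left_hits) == 0L && length(right_hits) == 0L)
    stopf("dish not found: no edge transitions on either side")  # unreachable, kept for clarity
  if (right <= left) stopf("dish not found: transitions do not bracket a dish")

  center_x <- (left + right) / 2
  center_y <- h / 2
  radius <- (right - left) / 2
  dish_geometry(center_x, center_y, radius, margin_fraction)
}

#' Blacken everything outside the dish circle
#'
#' Every pixel farther than `radius * (1 - margin_fraction)` from the
#' circle center is set to 0; interior pixels are untouched. Applying
#' the same geometry twice is a no-op.
#'
#' @param image Grayscale matrix or RGB array, 0..255.
#' @param geom A [dish_geometry()].
#' @return Image of the same shape with the exterior blackened.
#' @export
apply_dish_mask <- function(image, geom) {
  stopifnot(inherits(geom, "dish_geometry"))
  d <- dim(image)
  h <- d[1L]; w <- d[2L]
  eff <- geom$radius * (1 - geom$margin_fraction)
  outside <- outer(((1:h) - 0.5 - geom$center_y)^2,
                   ((1:w) - 0.5 - geom$center_x)^2, `+`) > eff^2
  if (length(d) == 2L) {
    image[outside] <- 0
  } else {
    for (ch in seq_len(d[3L])) {
      plane <- image[, , ch]
      plane[outside] <- 0
      image[, , ch] <- plane
    }
  }
  image
}
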