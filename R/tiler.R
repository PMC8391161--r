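## Sliding-window tiling of large plate images.
##
## Full plates (nominally 3280 x 2464 px) are processed in overlapping
## chunks (default 820 x 821 px, 25% overlap); detections made inside a
## tile are mapped back to full-image coordinates and de-duplicated
## across overlap regions.

#' Plan a sliding-window tile grid
#'
#' Tile offsets advance by `floor(tile * (1 - overlap))` along each
#' axis; the final offset in each axis is clamped to
#' `image_dim - tile_dim` so every tile lies fully inside the image
#' (the last row/column of tiles simply overlaps more). Every image
#' pixel is covered by at least one tile.
#'
#' @param image_w,image_h Image size in px.
#' @param tile_w,tile_h Tile size in px (defaults 820 x 821).
#' @param overlap Fractional overlap between consecutive tiles, in
#'   `[0, 1)`; default 0.25.
#' @return A `tile_grid` list with `offsets` (data.frame of 0-based
#'   `x0`, `y0`), tile and image dimensions.
#' @export
#' @examples
#' grid <- plan_tiles(3280, 2464)   # 5 x 4 = 20 tiles
#' nrow(grid$offsets)
plan_tiles <- function(image_w, image_h, tile_w = 820L, tile_h = 821L,
                       overlap = 0.25) {
  if (tile_w > image_w || tile_h > image_h)
    stopf("plan_tiles: tile (%d x %d) larger than image (%d x %d)",
          tile_w, tile_h, image_w, image_h)
  if (overlap < 0 || overlap >= 1) stopf("plan_tiles: overlap must be in [0, 1)")
  axis_offsets <- function(dim, tile) {
    stride <- max(1L, floor(tile * (1 - overlap)))
    off <- seq.int(0L, dim - tile, by = stride)
    if (off[length(off)] != dim - tile) off <- c(off, dim - tile)
    off
  }
  xs <- axis_offsets(as.integer(image_w), as.integer(tile_w))
  ys <- axis_offsets(as.integer(image_h), as.integer(tile_h))
  offsets <- expand.grid(x0 = xs, y0 = ys, KEEP.OUT.ATTRS = FALSE)
  structure(
    list(tile_w = as.integer(tile_w), tile_h = as.integer(tile_h),
         overlap = overlap, image_w = as.integer(image_w),
         image_h = as.integer(image_h), offsets = offsets),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile grid: %d tiles of %d x %d px (overlap %.0f%%) on %d x %d image\n",
              nrow(x$offsets), x$tile_w, x$tile_h, 100 * x$overlap,
              x$image_w, x$image_h))
  invisible(x)
}

#' Extract one tile as a sub-image copy
#'
#' @param image Grayscale matrix or RGB array.
#' @param offset 0-based `(x0, y0)` tile origin.
#' @param tile_w,tile_h Tile size in px.
#' @return The tile sub-image.
#' @export
extract_tile <- function(image, offset, tile_w, tile_h) {
  d <- dim(image)
  x0 <- offset[[1L]]; y0 <- offset[[2L]]
  if (x0 < 0 || y0 < 0 || x0 + tile_w > d[2L] || y0 + tile_h > d[1L])
    stopf("extract_tile: tile at (%d, %d) of %d x %d exceeds image bounds",
          x0, y0, tile_w, tile_h)
  rows <- (y0 + 1L):(y0 + tile_h)
  cols <- (x0 + 1L):(x0 + tile_w)
  if (length(d) == 2L) image[rows, cols, drop = FALSE] else image[rows, cols, , drop = FALSE]
}

#' Map tile-local detections to full-image coordinates
#'
#' Boxes are translated by the tile offset; masks are re-embedded into a
#' full-image frame when the global frame size is given. Scores, labels
#' and ids are unchanged.
#'
#' @param detections A [detection_table()] in tile coordinates.
#' @param offset 0-based `(x0, y0)` tile origin.
#' @param image_w,image_h Global frame size (required to translate
#'   masks; boxes alone need neither).
#' @return The translated detection table.
#' @export
to_global <- function(detections, offset, image_w = NULL, image_h = NULL) {
  x0 <- offset[[1L]]; y0 <- offset[[2L]]
  detections$x0 <- detections$x0 + x0
  detections$y0 <- detections$y0 + y0
  detections$x1 <- detections$x1 + x0
  detections$y1 <- detections$y1 + y0
  if (!is.null(detections$mask) && !is.null(image_w) && !is.null(image_h)) {
    detections$mask <- I(lapply(detections$mask, function(m) {
      if (is.null(m)) return(NULL)
      g <- matrix(FALSE, image_h, image_w)
      idx <- which(m, arr.ind = TRUE)
      if (nrow(idx) > 0L)
        g[cbind(idx[, 1L] + y0, idx[, 2L] + x0)] <- TRUE
      g
    }))
  }
  detections
}

#' De-duplicate detections across overlapping tiles
#'
#' Greedy suppression by descending score (ties broken by lower id):
#' among detections whose IoU is at least `iou_threshold`, only the
#' highest-scoring one survives. Mask IoU is used when both detections
#' carry masks, box IoU otherwise. Output is sorted by descending score.
#'
#' @param detections A [detection_table()] in global coordinates.
#' @param iou_threshold Suppression threshold; default 0.3, the usual
#'   per-class NMS level.
#' @return The de-duplicated detection table.
#' @export
merge_tile_detections <- function(detections, iou_threshold = 0.3) {
  n <- nrow(detections)
  if (is.null(n) || n <= 1L) return(detections)
  ord <- order(-detections$score, detections$id)
  det <- detections[ord, , drop = FALSE]
  keep <- logical(n)
  alive <- rep(TRUE, n)
  pair_iou <- function(i, j) {
    mi <- if (!is.null(det$mask)) det$mask[[i]] else NULL
    mj <- if (!is.null(det$mask)) det$mask[[j]] else NULL
    if (!is.null(mi) && !is.null(mj)) mask_iou(mi, mj)
    else box_iou(unlist(det[i, c("x0", "y0", "x1", "y1")]),
                 unlist(det[j, c("x0", "y0", "x1", "y1")]))
  }
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < n) for (j in (i + 1L):n) {
      if (alive[j] && pair_iou(i, j) >= iou_threshold) alive[j] <- FALSE
    }
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
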