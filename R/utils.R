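## Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_image_matrix <- function(x) is.matrix(x) && is.numeric(x)

image_dims <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) stopf("not an image: need a matrix or h x w x 3 array")
  list(h = d[1L], w = d[2L], channels = if (length(d) == 3L) d[3L] else 1L)
}

#' Convert an image to grayscale
#'
#' RGB arrays are collapsed with the standard Rec.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale matrices pass through
#' unchanged.
#'
#' @param image Numeric matrix (grayscale) or h x w x 3 array (RGB),
#'   values on the 0..255 scale.
#' @return A numeric matrix with the same height and width.
#' @export
#' @examples
#' rgb <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(rgb)  # 0.299 * 255
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) == 2L) return(image)
  if (length(d) == 3L && d[3L] >= 3L) {
    g <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
    return(matrix(g, d[1L], d[2L]))
  }
  if (length(d) == 3L && d[3L] == 1L) return(matrix(image[, , 1L], d[1L], d[2L]))
  stopf("cannot convert array with %d channels to grayscale", d[3L])
}

## Pad a matrix by `r` rows/cols on each side, replicating edge values.
pad_replicate <- function(m, r) {
  if (r <= 0L) return(m)
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

## 1-D Gaussian kernel of odd length n; when sigma <= 0 the usual
## OpenCV-style default sigma = 0.3*((n-1)*0.5 - 1) + 0.8 is used.
gaussian_kernel1d <- function(n, sigma = 0) {
  stopifnot(n >= 1L, n %% 2L == 1L)
  if (sigma <= 0) sigma <- 0.3 * ((n - 1) * 0.5 - 1) + 0.8
  x <- seq_len(n) - (n + 1) / 2
  k <- exp(-(x^2) / (2 * sigma^2))
  k / sum(k)
}

## Local Gaussian-weighted mean of a grayscale matrix (replicate border).
local_gaussian_mean <- function(gray, window) {
  k1 <- gaussian_kernel1d(window)
  kern <- outer(k1, k1)
  r <- (window - 1L) / 2L
  padded <- pad_replicate(gray, r)
  out <- EBImage::filter2(padded, kern, boundary = "replicate")
  out <- out[(r + 1L):(r + nrow(gray)), (r + 1L):(r + ncol(gray)), drop = FALSE]
  ## filter2 may return an Image object; coerce back to a plain matrix
  matrix(as.numeric(out), nrow(gray), ncol(gray))
}

## Minimal axis-aligned bounding box of a logical mask, 0-based half-open.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("empty mask has no bounding box")
  c(
    x0 = min(idx[, 2L]) - 1L, y0 = min(idx[, 1L]) - 1L,
    x1 = max(idx[, 2L]), y1 = max(idx[, 1L])
  )
}

bbox_area <- function(b) (b[3L] - b[1L]) * (b[4L] - b[2L])

## Label connected components. EBImage::bwlabel is 4-connected; for
## 8-connectivity, labels touching only diagonally are merged afterwards
## via union-find over the (few) label ids.
label_components <- function(binary, connectivity = 8L) {
  lab <- EBImage::bwlabel(binary * 1)
  lab <- matrix(as.integer(lab), nrow(binary), ncol(binary))
  n <- max(lab)
  if (connectivity == 4L || n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal pairs
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal pairs
  pairs <- rbind(
    cbind(a1[a1 > 0L & b1 > 0L & a1 != b1], b1[a1 > 0L & b1 > 0L & a1 != b1]),
    cbind(a2[a2 > 0L & b2 > 0L & a2 != b2], b2[a2 > 0L & b2 > 0L & a2 != b2])
  )
  if (nrow(pairs) > 0L) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

## Split a label matrix into a list of logical instance masks.
masks_from_labels <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(list())
  lapply(seq_len(n), function(i) lab == i)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)
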