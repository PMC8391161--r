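## Image IO on the package's 0..255 numeric convention.

#' Read a PNG image as a 0..255 matrix or array
#'
#' @param path PNG file path.
#' @param gray Convert RGB to grayscale on read.
#' @return Numeric matrix (grayscale) or h x w x 3 array, 0..255.
#' @export
read_image <- function(path, gray = FALSE) {
  if (!file.exists(path)) stopf("read_image: no such file '%s'", path)
  img <- png::readPNG(path) * 255
  d <- dim(img)
  if (length(d) == 3L && d[3L] == 2L) img <- img[, , 1L]            # gray+alpha
  if (length(d) == 3L && d[3L] == 4L) img <- img[, , 1:3]           # drop alpha
  if (gray) img <- to_grayscale(img)
  img
}

#' Write a 0..255 image to PNG
#'
#' @param image Numeric matrix or h x w x 3 array, 0..255.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(clip255(image) / 255, path)
  invisible(path)
}
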