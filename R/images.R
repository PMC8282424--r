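# RGB images are plain numeric arrays of dim c(height, width, 3) holding
# 8-bit levels in [0, 255]; nuclei masks are integer matrices in {0, 1}.
# This keeps indexing in the familiar [row, col] order; conversion to
# EBImage's (x, y) layout happens only inside functions that call into it.

#' Validate an RGB image array
#' @param img object to check
#' @param name argument name for error messages
#' @return the image, invisibly
#' @keywords internal
assert_rgb <- function(img, name = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop(sprintf("`%s` must be a height x width x 3 array (RGB)", name),
         call. = FALSE)
  }
  if (any(dim(img)[1:2] == 0L)) {
    stop(sprintf("`%s` has a zero-sized dimension", name), call. = FALSE)
  }
  invisible(img)
}

assert_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask) || length(mask) == 0L) {
    stop(sprintf("`%s` must be a nonempty binary matrix", name), call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) {
    stop(sprintf("`%s` must contain only 0/1 values", name), call. = FALSE)
  }
  invisible(mask)
}

#' Luma (grayscale) conversion of an RGB image
#'
#' Uses the Rec. 709 weights 0.2125 R + 0.7154 G + 0.0721 B, the standard
#' luminance approximation for ranking tissue darkness.
#'
#' @param img RGB array (height x width x 3), 8-bit levels
#' @return matrix of gray levels in [0, 255]
#' @export
rgb_to_gray <- function(img) {
  assert_rgb(img)
  0.2125 * img[, , 1] + 0.7154 * img[, , 2] + 0.0721 * img[, , 3]
}

#' Read an RGB image from a PNG file
#'
#' @param path PNG file path
#' @return RGB array (height x width x 3) with 8-bit levels
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' Write an RGB image to a PNG file
#' @param img RGB array, 8-bit levels
#' @param path output path
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  assert_rgb(img)
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG (0/255 convention)
#' @param path PNG file path
#' @return integer matrix in {0, 1}
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  m <- matrix(as.integer(x > 0.5), nrow(x), ncol(x))
  m
}

#' Write a binary mask as a single-channel PNG (0/255)
#' @param mask 0/1 matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# row-major array <-> EBImage (x = col, y = row) conversions
to_ebimage <- function(img) {
  EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
}

from_ebimage <- function(eb) {
  a <- EBImage::imageData(eb)
  round(pmin(pmax(aperm(a, c(2, 1, 3)), 0), 1) * 255)
}
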