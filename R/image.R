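#' Read an RGB image from a PNG file
#'
#' Returns a numeric array `[row, col, 3]` with values in `[0, 1]`. Grayscale
#' and RGBA inputs are expanded/trimmed to 3 channels.
#'
#' @param path path to a PNG file.
#' @return numeric array `[h, w, 3]`.
#' @export
read_image_rgb <- function(path) {
  img <- png::readPNG(path)
  as_rgb_array(img)
}

#' @noRd
as_rgb_array <- function(img) {
  if (is.matrix(img)) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  } else if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    pheno_error("pheno_invalid_input", "expected a grayscale or RGB(A) image")
  }
  img
}

#' Write an RGB image or mask to a PNG file
#'
#' @param img numeric array `[h, w, 3]` in `[0,1]`, or a matrix (grayscale;
#'   label maps are rescaled to use the full 16-bit range).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  if (is.matrix(img) && max(img) > 1) img <- img / max(img)
  png::writePNG(clamp(img, 0, 1), path)
  invisible(path)
}

#' 8-bit luminance channel of an RGB image
#'
#' Rec. 601 luma: `0.299 R + 0.587 G + 0.114 B`, rounded to integer levels
#' 0..255. This is the grayscale channel the Otsu-based segmentations use.
#'
#' @param img numeric array `[h, w, 3]` in `[0,1]`.
#' @return integer matrix `[h, w]` with values in 0..255.
#' @export
luminance <- function(img) {
  stopifnot(length(dim(img)) == 3)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(as.integer(round(255 * clamp(g, 0, 1))), nrow = dim(img)[1])
}

#' Convert an RGB image to HSV channel matrices
#'
#' @param img numeric array `[h, w, 3]` in `[0,1]`.
#' @return list with matrices `h` (degrees, `[0, 360)`), `s`, `v` (in `[0,1]`).
#' @export
image_hsv <- function(img) {
  d <- dim(img)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(img[, , 1]), g = as.vector(img[, , 2]), b = as.vector(img[, , 3]),
    maxColorValue = 1
  )
  list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
}

#' Histogram of an 8-bit grayscale image
#'
#' @param gray integer matrix with values in 0..255 (e.g. from [luminance()]).
#' @return integer vector of 256 counts for levels 0..255.
#' @export
gray_histogram <- function(gray) {
  tabulate(as.integer(gray) + 1L, nbins = 256L)
}
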