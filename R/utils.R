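#' @keywords internal
"_PACKAGE"

#' @importFrom stats cov median quantile rbinom rexp rnorm runif sd uniroot
#'   predict coef pchisq rank setNames aggregate
#' @importFrom grDevices contourLines
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_rgb <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("%s must be an H x W x 3 rgb array", what), call. = FALSE)
  invisible(img)
}

# per-pixel intensity: mean over the three channels, 0-255 scale
pixel_intensity <- function(img) {
  stop_if_not_rgb(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

# reflect an index vector into 1..n (mirror boundary, period 2n)
reflect_index <- function(i, n) {
  i2 <- ((i - 1) %% (2 * n))
  ifelse(i2 < n, i2 + 1, 2 * n - i2)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Read an RGB image as a 0-255 array
#'
#' Thin wrapper over [png::readPNG()] returning the package's working
#' representation: a numeric `H x W x 3` array on the 0-255 intensity scale.
#' Grayscale and RGBA files are promoted/truncated to 3 channels.
#'
#' @param path path to a PNG file.
#' @return numeric array `H x W x 3`, values in \[0, 255\].
#' @export
read_slide_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' Write a 0-255 RGB array as PNG
#'
#' @param img numeric `H x W x 3` array, values in \[0, 255\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_slide_png <- function(img, path) {
  stop_if_not_rgb(img)
  png::writePNG(clamp255(img) / 255, path)
  invisible(path)
}
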