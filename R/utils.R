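# Shared helpers: error conditions, image coercion, HSV conversion.

gs_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "grainscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_invalid <- function(msg) gs_stop(msg, "gs_invalid_input")
stop_config <- function(msg) gs_stop(msg, "gs_config_error")
stop_state <- function(msg) gs_stop(msg, "gs_state_error")

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

#' Coerce an image to a numeric RGB array
#'
#' Accepts a file path (PNG/TIFF/JPEG, read via [EBImage::readImage()]), an
#' `EBImage::Image`, or a numeric array, and returns a plain numeric array of
#' dimension `c(nx, ny, 3)` with values in `[0, 1]`. Coordinates throughout
#' the package are 0-based pixel indices with the origin at the top-left
#' corner, `x` increasing rightward along the first array dimension and `y`
#' downward along the second.
#'
#' Grayscale inputs are replicated across the three channels.
#'
#' @param image path, `Image`, or array.
#' @return numeric array `c(nx, ny, 3)` in `[0, 1]`.
#' @export
as_rgb_array <- function(image) {
  if (is.character(image)) {
    if (length(image) != 1L || !file.exists(image)) {
      stop_invalid(sprintf("image file not found: %s", image[1]))
    }
    image <- EBImage::readImage(image)
  }
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (!is.numeric(image)) stop_invalid("image must be numeric")
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) stop_invalid("image must be at least 2-D")
  if (length(d) == 2L) {
    image <- array(rep(image, 3L), dim = c(d, 3L))
  } else if (d[3] == 1L) {
    image <- array(rep(image[, , 1L], 3L), dim = c(d[1], d[2], 3L))
  } else if (d[3] >= 3L) {
    image <- image[, , 1:3, drop = FALSE]
  }
  if (max(image) > 1 + 1e-8) image <- image / 255
  image[image < 0] <- 0
  image[image > 1] <- 1
  image
}

#' Convert an RGB array to HSV channels on imaging-convention scales
#'
#' Hue is reported on the half-degree 0-179 scale and saturation/value on
#' 0-255, the convention used by mainstream imaging libraries for 8-bit HSV.
#' This scale choice is load-bearing for all configured HSV ranges and is
#' documented with [hsv_range()].
#'
#' @param rgb numeric array `c(nx, ny, 3)` in `[0, 1]`.
#' @return numeric array `c(nx, ny, 3)`: H in `[0, 179]`, S and V in
#'   `[0, 255]`.
#' @export
rgb_to_hsv_cv <- function(rgb) {
  d <- dim(rgb)
  m <- matrix(aperm(rgb, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  out <- array(0, dim = d)
  out[, , 1] <- matrix(hsv[1, ] * 179, d[1], d[2])
  out[, , 2] <- matrix(hsv[2, ] * 255, d[1], d[2])
  out[, , 3] <- matrix(hsv[3, ] * 255, d[1], d[2])
  out
}

# Euclidean distance between two (x, y) points.
pt_dist <- function(a, b) sqrt(sum((a - b)^2))

# Clamp to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
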