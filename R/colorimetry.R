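# HSV in-range colour scoring: yellowness and chalkiness per kernel.
#
# Scoring runs in HSV because scanner lighting varies between devices and
# sessions; hue/saturation separate the colour signal from brightness. The
# fraction of a kernel's pixels falling inside a configured HSV box is its
# score for that trait, and a kernel is flagged when the fraction passes a
# configurable threshold.

#' An inclusive HSV box
#'
#' Hue is on the half-degree 0-179 scale and saturation/value on 0-255 (the
#' 8-bit convention of mainstream imaging libraries; note this is NOT the
#' 0-360 degree scale). `lower` must be `<=` `upper` componentwise: hue
#' wraparound across 179/0 (needed only for reds) is not supported and is
#' rejected at validation.
#'
#' @param lower,upper numeric length-3 vectors `(h, s, v)`.
#' @return an object of class `hsv_range`.
#' @examples
#' hsv_range(c(20, 80, 80), c(35, 255, 255))  # a yellow box
#' @export
hsv_range <- function(lower, upper) {
  if (length(lower) != 3 || length(upper) != 3) {
    stop_invalid("`lower` and `upper` must be length-3 (h, s, v)")
  }
  if (lower[1] < 0 || upper[1] > 179) {
    stop_invalid("hue must lie in [0, 179] (half-degree scale)")
  }
  if (any(lower[2:3] < 0) || any(upper[2:3] > 255)) {
    stop_invalid("saturation and value must lie in [0, 255]")
  }
  if (any(lower > upper)) {
    stop_invalid(paste(
      "`lower` must be <= `upper` componentwise;",
      "hue wraparound ranges are not supported -",
      "split red ranges into two boxes if ever needed"))
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "hsv_range")
}

#' Default starting ranges for yellow and chalky scoring
#'
#' Calibration starting points for milled white rice; production deployments
#' tune these per rice type against reference kernels. Chalk is low
#' saturation at high value (opaque white); yellow is a mid-hue band.
#'
#' @return an [hsv_range()].
#' @export
default_yellow_range <- function() hsv_range(c(20, 80, 80), c(35, 255, 255))

#' @rdname default_yellow_range
#' @export
default_chalky_range <- function() hsv_range(c(0, 0, 200), c(179, 40, 255))

#' Fraction of masked pixels inside an HSV range
#'
#' Converts the kernel's pixels to HSV and returns the fraction that fall
#' inside `range` on all three channels simultaneously.
#'
#' @param image path, `Image`, or RGB array.
#' @param kernel_mask logical or 0/1 matrix of the same x/y shape selecting
#'   the kernel's pixels; must have at least one foreground pixel.
#' @param range an [hsv_range()].
#' @return fraction in `[0, 1]`.
#' @export
mask_fraction <- function(image, kernel_mask, range) {
  if (!inherits(range, "hsv_range")) stop_invalid("`range` must be an hsv_range")
  rgb <- as_rgb_array(image)
  mask <- kernel_mask > 0
  if (!identical(dim(mask), dim(rgb)[1:2])) {
    stop_invalid("`kernel_mask` shape must match the image")
  }
  n <- sum(mask)
  if (n == 0) stop_invalid("`kernel_mask` selects no pixels")
  hsv <- rgb_to_hsv_cv(rgb)
  mask_fraction_hsv(hsv, mask, range)
}

#' Core mask of a segmented kernel
#'
#' Erodes a kernel mask by `radius` pixels. Segmentation masks carry a
#' transition band of mixed kernel/background colour at the rim (antialiased
#' edge, smoothing, hysteresis growth); scoring colour on the eroded core
#' keeps that band from diluting the in-range fractions.
#'
#' @param mask logical or 0/1 matrix.
#' @param radius erosion radius in pixels, default 2.
#' @return logical matrix; if erosion would empty the mask, the original
#'   mask is returned unchanged.
#' @export
kernel_core_mask <- function(mask, radius = 2) {
  m <- mask > 0
  core <- EBImage::imageData(EBImage::erode(
    EBImage::Image(m * 1), EBImage::makeBrush(2L * radius + 1L, "box"))) > 0
  if (!any(core)) m else core
}

# Fast path over a precomputed HSV array (used per-kernel by analyze_scene
# so the image is converted once per scene, not once per kernel).
mask_fraction_hsv <- function(hsv, mask, range) {
  n <- sum(mask)
  inr <- rep(TRUE, n)
  for (ch in 1:3) {
    v <- hsv[, , ch][mask]
    inr <- inr & v >= range$lower[ch] & v <= range$upper[ch]
  }
  sum(inr) / n
}

#' Score one kernel's yellowness and chalkiness
#'
#' Computes the yellow and chalky in-range fractions over the kernel mask
#' and flags the kernel when a fraction reaches its threshold.
#'
#' @inheritParams mask_fraction
#' @param yellow_range,chalky_range [hsv_range()] boxes.
#' @param yellow_flag_threshold,chalky_flag_threshold flagging thresholds in
#'   `(0, 1]`; a kernel is flagged when its fraction is `>=` the threshold.
#' @return object of class `color_score`: `yellow_fraction`,
#'   `chalky_fraction`, `is_yellow`, `is_chalky`.
#' @export
score_kernel_color <- function(image, kernel_mask,
                               yellow_range = default_yellow_range(),
                               chalky_range = default_chalky_range(),
                               yellow_flag_threshold = 0.30,
                               chalky_flag_threshold = 0.30) {
  for (thr in c(yellow_flag_threshold, chalky_flag_threshold)) {
    if (!is.numeric(thr) || length(thr) != 1 || thr <= 0 || thr > 1) {
      stop_invalid("flag thresholds must lie in (0, 1]")
    }
  }
  yf <- mask_fraction(image, kernel_mask, yellow_range)
  cf <- mask_fraction(image, kernel_mask, chalky_range)
  structure(
    list(yellow_fraction = yf, chalky_fraction = cf,
         is_yellow = yf >= yellow_flag_threshold,
         is_chalky = cf >= chalky_flag_threshold),
    class = "color_score"
  )
}
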