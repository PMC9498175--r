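# Pixel <-> millimetre calibration from a reference disk of known diameter.

#' Calibration profile of a scanner setup
#'
#' A calibration profile holds the pixels-per-millimetre (ppm) scale of one
#' scanner configuration. Profiles come either from detecting a reference
#' disk of known physical diameter in a calibration image
#' ([detect_reference_disk()]), in which case
#' `ppm * reference_width_mm == reference_width_px`, or from a manual
#' override where only `ppm` is known.
#'
#' @param ppm pixels per millimetre, must be positive.
#' @param reference_width_mm known physical width of the reference object
#'   (mm), `NA` for manual profiles.
#' @param reference_width_px measured pixel width of the reference object,
#'   `NA` for manual profiles.
#' @param source `"reference_image"` or `"manual"`.
#' @return an object of class `calibration_profile`.
#' @examples
#' calibration_profile(compute_ppm(281.25, 22.5), 22.5, 281.25,
#'                     source = "reference_image")
#' @export
calibration_profile <- function(ppm, reference_width_mm = NA_real_,
                                reference_width_px = NA_real_,
                                source = c("manual", "reference_image")) {
  source <- match.arg(source)
  check_positive_scalar(ppm, "ppm")
  if (source == "reference_image") {
    check_positive_scalar(reference_width_mm, "reference_width_mm")
    check_positive_scalar(reference_width_px, "reference_width_px")
    rel <- abs(ppm * reference_width_mm - reference_width_px) /
      reference_width_px
    if (rel > 1e-9) {
      stop_invalid("ppm is inconsistent with the reference measurements")
    }
  }
  structure(
    list(ppm = ppm, reference_width_mm = reference_width_mm,
         reference_width_px = reference_width_px, source = source),
    class = "calibration_profile"
  )
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf("<calibration_profile> ppm = %.4f px/mm (source: %s)\n",
              x$ppm, x$source))
  if (x$source == "reference_image") {
    cat(sprintf("  reference: %.3f px / %.3f mm\n",
                x$reference_width_px, x$reference_width_mm))
  }
  invisible(x)
}

#' Pixels-per-metric scale from a reference object
#'
#' The scale of a scanner image is the pixel width of a reference object
#' divided by its known physical width:
#' `ppm = reference_width_px / known_width_mm`. With the customary 22.5 mm
#' reference coin spanning 281.25 px this gives 12.50 px/mm.
#'
#' @param reference_width_px measured width of the reference object, pixels.
#' @param known_width_mm physical width of the reference object, mm.
#' @return pixels per millimetre (numeric scalar).
#' @seealso [px_to_mm()], [detect_reference_disk()]
#' @export
compute_ppm <- function(reference_width_px, known_width_mm) {
  check_positive_scalar(reference_width_px, "reference_width_px")
  check_positive_scalar(known_width_mm, "known_width_mm")
  reference_width_px / known_width_mm
}

#' Convert a pixel distance to millimetres
#'
#' @param distance_px distance in pixels, `>= 0` (vectorised).
#' @param profile a [calibration_profile()].
#' @return distance in millimetres.
#' @export
px_to_mm <- function(distance_px, profile) {
  if (!inherits(profile, "calibration_profile")) {
    stop_invalid("`profile` must be a calibration_profile")
  }
  if (any(!is.finite(distance_px)) || any(distance_px < 0)) {
    stop_invalid("`distance_px` must be finite and >= 0")
  }
  distance_px / profile$ppm
}

#' Locate the reference disk in a calibration image
#'
#' Finds the most circular bright object in the search region and returns its
#' pixel diameter (maximum point-to-point extent of its boundary, plus one
#' pixel of raster footprint). Circularity is `4 * pi * area / perimeter^2`,
#' 1 for an ideal disk; candidates below `min_circularity` are rejected so
#' that rice kernels (circularity ~0.65 at a 3:1 aspect) never masquerade as
#' the reference. The disk is conventionally placed near the left edge of the
#' scanner bed, so the default search region is the left quarter of the
#' image.
#'
#' @param image path, `Image`, or RGB array (see [as_rgb_array()]).
#' @param expected_diameter_mm known disk diameter, mm (recorded in the
#'   returned attributes; not used for detection).
#' @param search_region `"left"` (left quarter, the default) or `"full"`.
#' @param min_circularity minimum acceptable circularity, default 0.8.
#' @return the disk pixel diameter, with attributes `circularity` and
#'   `center` (0-based x, y).
#' @export
detect_reference_disk <- function(image, expected_diameter_mm = 22.5,
                                  search_region = c("left", "full"),
                                  min_circularity = 0.8) {
  search_region <- match.arg(search_region)
  rgb <- as_rgb_array(image)
  # the disk is uniformly bright: plain Otsu, no hysteresis growth (growth
  # would inflate the measured diameter by the blur halo)
  bin <- preprocess(rgb, hysteresis_ratio = 1)
  nx <- dim(bin)[1]
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  n <- max(lab)
  if (n < 1) gs_stop("calibration failed: no objects found", "gs_calibration_failure")
  contours <- EBImage::ocontour(lab)
  best <- NULL
  for (i in seq_len(n)) {
    pts <- contours[[i]]
    if (nrow(pts) < 8) next
    cx <- mean(pts[, 1])
    if (search_region == "left" && cx > nx / 4) next
    area <- sum(EBImage::imageData(lab) == i)
    per <- contour_perimeter(pts)
    circ <- 4 * pi * area / per^2
    if (circ < min_circularity) next
    if (is.null(best) || circ > best$circ) {
      best <- list(circ = circ, pts = pts, center = c(cx, mean(pts[, 2])))
    }
  }
  if (is.null(best)) {
    gs_stop(sprintf(
      "calibration failed: no object with circularity >= %.2f in the %s region",
      min_circularity, search_region), "gs_calibration_failure")
  }
  # Feret diameter over the convex hull + 1 px footprint (contour points are
  # pixel centres).
  hull <- best$pts[grDevices::chull(best$pts), , drop = FALSE]
  d2 <- as.matrix(stats::dist(hull))
  diam <- max(d2) + 1
  structure(diam, circularity = best$circ, center = best$center,
            expected_diameter_mm = expected_diameter_mm)
}

# Perimeter of an 8-connected boundary chain (pixel-centre polygon length).
contour_perimeter <- function(pts) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

#' Calibrate a scanner image against a reference disk
#'
#' Convenience wrapper: detects the reference disk and builds the
#' corresponding [calibration_profile()].
#'
#' @inheritParams detect_reference_disk
#' @return a `calibration_profile` with `source = "reference_image"`.
#' @export
calibrate_image <- function(image, expected_diameter_mm = 22.5,
                            search_region = c("left", "full"),
                            min_circularity = 0.8) {
  width_px <- detect_reference_disk(image, expected_diameter_mm,
                                    search_region, min_circularity)
  calibration_profile(
    ppm = compute_ppm(as.numeric(width_px), expected_diameter_mm),
    reference_width_mm = expected_diameter_mm,
    reference_width_px = as.numeric(width_px),
    source = "reference_image"
  )
}

#' Read/write a calibration profile as JSON
#'
#' @param profile a [calibration_profile()].
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the profile.
#' @export
write_calibration <- function(profile, path) {
  if (!inherits(profile, "calibration_profile")) {
    stop_invalid("`profile` must be a calibration_profile")
  }
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_profile(
    ppm = as.numeric(x$ppm),
    reference_width_mm = if (is.null(x$reference_width_mm)) NA_real_ else
      as.numeric(x$reference_width_mm),
    reference_width_px = if (is.null(x$reference_width_px)) NA_real_ else
      as.numeric(x$reference_width_px),
    source = x$source
  )
}
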