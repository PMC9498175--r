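# Kernel segmentation and rotated-bounding-box morphometry.
#
# Kernels lie bright on a dark background (scanner bed covered with a black
# sheet). The measurement chain is: grayscale -> Gaussian smoothing -> binary
# threshold -> external contours -> minimum-area rotated rectangle -> the
# Euclidean distances between the midpoints of opposite rectangle edges,
# divided by the calibrated pixels-per-mm scale.

#' A scanner scene ready for analysis
#'
#' Bundles an RGB image with the calibration profile that converts its pixel
#' distances to millimetres.
#'
#' @param image path, `Image`, or RGB array (see [as_rgb_array()]).
#' @param profile a [calibration_profile()].
#' @param source_path optional provenance string.
#' @return an object of class `grain_scene` with elements `image`, `profile`,
#'   `source_path`.
#' @export
grain_scene <- function(image, profile, source_path = "") {
  src <- if (is.character(image)) image else source_path
  rgb <- as_rgb_array(image)
  d <- dim(rgb)
  if (d[1] < 2 || d[2] < 2) stop_invalid("image must be at least 2 x 2 pixels")
  if (!inherits(profile, "calibration_profile")) {
    stop_invalid("`profile` must be a calibration_profile")
  }
  structure(list(image = rgb, profile = profile, source_path = src),
            class = "grain_scene")
}

#' @export
print.grain_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<grain_scene> %d x %d px at %.3f px/mm\n", d[1], d[2],
              x$profile$ppm))
  invisible(x)
}

#' Binarise a scene: grayscale, smoothing, threshold
#'
#' Converts to luminance, smooths with a Gaussian filter, and thresholds to a
#' foreground mask (kernel pixels 1, background 0). The threshold is Otsu's
#' method by default; a fixed threshold is available for controlled tests. A
#' gradient-magnitude edge map with double-threshold hysteresis is retained
#' as the `edges` attribute for diagnostics; contours are traced on the
#' threshold mask.
#'
#' @param image path, `Image`, or RGB array.
#' @param smooth_ks Gaussian smoothing kernel size in pixels; odd, `>= 3`.
#' @param threshold `"otsu"` or `"fixed"`.
#' @param threshold_value threshold in `[0, 1]` when `threshold = "fixed"`.
#' @param canny_thresholds low/high hysteresis thresholds for the retained
#'   edge map, on the 0-255 gradient scale.
#' @param invert set `TRUE` for dark kernels on a bright background.
#' @param hysteresis_ratio in Otsu mode, components are seeded at the Otsu
#'   threshold and grown down to `hysteresis_ratio` times it, so that
#'   partially darkened (damaged) kernel regions - dimmer than the global
#'   kernel/background split but far brighter than the black sheet - stay
#'   attached to their kernel. Set 1 to disable. Ignored in fixed mode.
#' @return integer matrix `c(nx, ny)` of 0/1, with attribute `edges`.
#' @export
preprocess <- function(image, smooth_ks = 7,
                       threshold = c("otsu", "fixed"), threshold_value = 0.5,
                       canny_thresholds = c(50, 150), invert = FALSE,
                       hysteresis_ratio = 0.4) {
  threshold <- match.arg(threshold)
  if (length(smooth_ks) != 1L || smooth_ks < 3 || smooth_ks %% 2 != 1) {
    stop_invalid("`smooth_ks` must be odd and >= 3")
  }
  rgb <- as_rgb_array(image)
  gray <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  if (invert) gray <- 1 - gray
  # sigma from kernel size, the usual imaging-library heuristic
  sigma <- 0.3 * ((smooth_ks - 1) / 2 - 1) + 0.8
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(gray), sigma = sigma))
  if (threshold == "otsu") {
    thr <- as.numeric(EBImage::otsu(EBImage::Image(sm)))
    if (hysteresis_ratio < 1) {
      low <- thr * hysteresis_ratio
      lab <- EBImage::bwlabel(EBImage::Image(matrix(as.integer(sm > low),
                                                    nrow = nrow(sm))))
      labdat <- EBImage::imageData(lab)
      keep <- setdiff(unique(labdat[sm > thr]), 0)
      bin <- matrix(as.integer(labdat %in% keep), nrow = nrow(sm))
    } else {
      bin <- matrix(as.integer(sm > thr), nrow = nrow(sm))
    }
  } else {
    thr <- threshold_value
    bin <- matrix(as.integer(sm > thr), nrow = nrow(sm))
  }
  attr(bin, "edges") <- edge_map(sm, canny_thresholds)
  attr(bin, "threshold") <- thr
  bin
}

# Sobel gradient magnitude + double-threshold hysteresis (8-connected),
# the Canny core without non-maximum suppression.
edge_map <- function(gray, thresholds = c(50, 150)) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::imageData(EBImage::filter2(EBImage::Image(gray), sx))
  gy <- EBImage::imageData(EBImage::filter2(EBImage::Image(gray), t(sx)))
  mag <- sqrt(gx^2 + gy^2) * 255
  strong <- mag >= thresholds[2]
  weak <- mag >= thresholds[1]
  if (!any(strong)) return(strong)
  # weak pixels survive if 8-connected to a strong pixel
  lab <- EBImage::bwlabel(EBImage::Image(weak * 1))
  keep <- unique(EBImage::imageData(lab)[strong])
  matrix(EBImage::imageData(lab) %in% setdiff(keep, 0), nrow = nrow(gray))
}

#' Minimum-area rotated rectangle of a point set
#'
#' Rotating-calipers search over the convex hull: the minimum-area enclosing
#' rectangle has one side collinear with a hull edge. Because contour points
#' are pixel centres, the rectangle is inflated by half a pixel on every side
#' so that its sides measure the true pixel footprint (a 50-px-wide drawn
#' rectangle yields a 50-px-wide box).
#'
#' @param points numeric matrix with columns x, y (0-based pixel centres).
#' @return list with `corners` (4 x 2 matrix ordered top-left, top-right,
#'   bottom-right, bottom-left), `width`, `height` (the two side lengths),
#'   and `angle` (degrees of the `width` side from the x axis).
#' @export
min_area_rect <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop_invalid("need at least 3 points")
  hull <- points[grDevices::chull(points), , drop = FALSE]
  n <- nrow(hull)
  best <- NULL
  for (i in seq_len(n)) {
    e <- hull[if (i == n) 1 else i + 1, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% v
    eu <- max(pu) - min(pu)
    ev <- max(pv) - min(pv)
    area <- (eu + 1) * (ev + 1)
    if (is.null(best) || area < best$area) {
      ctr <- (c(min(pu) + max(pu), min(pv) + max(pv)) / 2)
      center <- ctr[1] * u + ctr[2] * v
      best <- list(area = area, u = u, v = v, eu = eu + 1, ev = ev + 1,
                   center = center)
    }
  }
  if (is.null(best)) stop_invalid("degenerate point set")
  hu <- best$eu / 2
  hv <- best$ev / 2
  corners <- rbind(
    best$center - hu * best$u - hv * best$v,
    best$center + hu * best$u - hv * best$v,
    best$center + hu * best$u + hv * best$v,
    best$center - hu * best$u + hv * best$v
  )
  corners <- order_box_corners(corners)
  side1 <- pt_dist(corners[1, ], corners[2, ])
  side2 <- pt_dist(corners[2, ], corners[3, ])
  ang <- atan2(corners[2, 2] - corners[1, 2],
               corners[2, 1] - corners[1, 1]) * 180 / pi
  list(corners = corners, width = side1, height = side2, angle = ang)
}

# Cyclic order top-left, top-right, bottom-right, bottom-left: sort by angle
# about the centroid (clockwise on screen with y down), then rotate the cycle
# to start at the corner nearest the image origin.
order_box_corners <- function(corners) {
  ctr <- colMeans(corners)
  ang <- atan2(corners[, 2] - ctr[2], corners[, 1] - ctr[1])
  corners <- corners[order(ang), , drop = FALSE]
  start <- which.min(corners[, 1] + corners[, 2])
  idx <- ((seq_len(4) + start - 2) %% 4) + 1
  corners[idx, , drop = FALSE]
}

#' Find kernel contours in a binary mask
#'
#' Labels connected foreground components, drops those below `min_area_px`
#' (dust suppression; the default elsewhere in the package is the pixel area
#' of a 1 mm square, since no rice kernel is smaller than that), and returns
#' each remaining component as a `kernel_contour`: its ordered boundary
#' points, area, minimum-area rotated box, and the four edge midpoints. The
#' list is ordered top-to-bottom then left-to-right by centroid.
#'
#' @param binary 0/1 matrix from [preprocess()].
#' @param min_area_px minimum component area in pixels.
#' @return list of `kernel_contour` objects (possibly empty). Each has
#'   `points` (boundary, 0-based), `area_px`, `box_corners` (4 x 2, ordered
#'   top-left, top-right, bottom-right, bottom-left), `edge_midpoints`
#'   (4 x 2: top, right, bottom, left), `centroid`.
#' @export
find_kernels <- function(binary, min_area_px = 25) {
  lab <- EBImage::bwlabel(EBImage::Image(binary))
  n <- max(lab)
  if (n < 1) return(list())
  labdat <- EBImage::imageData(lab)
  contours <- EBImage::ocontour(lab)
  areas <- tabulate(labdat[labdat > 0], nbins = n)
  out <- list()
  for (i in seq_len(n)) {
    if (areas[i] < min_area_px) next
    pts <- contours[[i]]
    if (nrow(pts) < 3) next
    idx <- which(labdat == i, arr.ind = TRUE)
    centroid <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
    rect <- min_area_rect(pts)
    co <- rect$corners
    mids <- rbind(
      (co[1, ] + co[2, ]) / 2,  # top
      (co[2, ] + co[3, ]) / 2,  # right
      (co[3, ] + co[4, ]) / 2,  # bottom
      (co[4, ] + co[1, ]) / 2   # left
    )
    out[[length(out) + 1L]] <- structure(
      list(points = pts, area_px = areas[i], box_corners = co,
           edge_midpoints = mids, centroid = centroid, label = i),
      class = "kernel_contour"
    )
  }
  if (length(out) > 1) {
    cy <- vapply(out, function(k) k$centroid[2], 0)
    cx <- vapply(out, function(k) k$centroid[1], 0)
    out <- out[order(cy, cx)]
  }
  # label matrix retained so downstream stages can recover per-kernel masks
  attr(out, "labels") <- labdat
  out
}

#' Measure a kernel's length and width in millimetres
#'
#' Connects the midpoints of opposite edges of the minimum-area rotated box
#' and takes the two Euclidean distances; the larger, divided by the ppm
#' scale, is the kernel length, the smaller its width.
#'
#' The box alone is quantised to the pixel raster (up to half a pixel per
#' side, which matters for the ~25 px kernel width). When the grayscale
#' image and the kernel's mask are supplied, the two distances are refined
#' to subpixel precision: the box still fixes the kernel centre and axes,
#' and each dimension is re-measured as the integral of edge coverage along
#' the midpoint-connecting chord. Coverage is 1 on interior pixels and, in
#' the boundary band, the gray level normalised between the local background
#' and the nearest interior brightness - local normalisation keeps dark
#' damage patches from biasing the edge position.
#'
#' @param contour a `kernel_contour` from [find_kernels()].
#' @param profile a [calibration_profile()].
#' @param gray optional grayscale matrix of the full scene (values in
#'   `[0, 1]`), enabling subpixel refinement.
#' @param mask optional logical matrix, this kernel's pixels.
#' @return object of class `kernel_geometry`: `length_mm`, `width_mm`,
#'   `centroid` (pixels).
#' @export
measure_kernel <- function(contour, profile, gray = NULL, mask = NULL) {
  if (!inherits(contour, "kernel_contour")) {
    stop_invalid("`contour` must be a kernel_contour")
  }
  if (!inherits(profile, "calibration_profile")) {
    stop_invalid("`profile` must be a calibration_profile")
  }
  m <- contour$edge_midpoints
  d_vert <- pt_dist(m[1, ], m[3, ])  # top-bottom
  d_horz <- pt_dist(m[2, ], m[4, ])  # right-left
  if (min(d_vert, d_horz) <= 1e-9) {
    gs_stop("degenerate kernel: zero extent", "gs_degenerate_kernel")
  }
  if (!is.null(gray) && !is.null(mask)) {
    ref <- refine_extents(contour, gray, mask)
    if (!is.null(ref)) {
      d_vert <- ref[1]
      d_horz <- ref[2]
    }
  }
  structure(
    list(length_mm = max(d_vert, d_horz) / profile$ppm,
         width_mm = min(d_vert, d_horz) / profile$ppm,
         centroid = contour$centroid),
    class = "kernel_geometry"
  )
}

# Subpixel chord-integral refinement of the two box dimensions.
# Returns c(vertical_extent, horizontal_extent) in the box sense of
# measure_kernel, or NULL if the local window is unusable.
refine_extents <- function(contour, gray, mask, step = 0.25) {
  co <- contour$box_corners
  ctr <- colMeans(co)
  u <- co[2, ] - co[1, ]          # top edge direction
  u <- u / sqrt(sum(u^2))
  v <- c(-u[2], u[1])             # left->bottom direction
  half_u <- pt_dist(co[1, ], co[2, ]) / 2
  half_v <- pt_dist(co[2, ], co[3, ]) / 2

  d <- dim(gray)
  pad <- 5L
  x0 <- max(1L, floor(min(co[, 1])) - pad + 1L)
  x1 <- min(d[1], ceiling(max(co[, 1])) + pad + 1L)
  y0 <- max(1L, floor(min(co[, 2])) - pad + 1L)
  y1 <- min(d[2], ceiling(max(co[, 2])) + pad + 1L)
  g <- gray[x0:x1, y0:y1, drop = FALSE]
  mk <- mask[x0:x1, y0:y1, drop = FALSE]
  if (!any(mk) || any(dim(g) < 5)) return(NULL)

  # The mask may carry a 1-2 px blur halo (hysteresis growth), so the
  # full-coverage core is the mask eroded by 2 px; everything between core
  # and background is the transition band, normalised against the nearest
  # core brightness.
  interior <- EBImage::imageData(EBImage::erode(
    EBImage::Image(mk * 1), EBImage::makeBrush(5, "box"))) > 0
  if (!any(interior)) return(NULL)
  far <- !EBImage::imageData(EBImage::dilate(
    EBImage::Image(mk * 1), EBImage::makeBrush(7, "box"))) > 0
  bg <- if (any(far)) stats::median(g[far]) else min(g)
  fg_src <- ifelse(interior, g, 0)
  fg_nb <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(fg_src), EBImage::makeBrush(9, "box")))
  cov <- ifelse(interior, 1,
                ifelse(fg_nb - bg > 0.05,
                       clamp((g - bg) / (fg_nb - bg), 0, 1), 0))

  # bilinear sampler in window coordinates (0-based scene coords in)
  sample_cov <- function(pts) {
    x <- pts[, 1] - (x0 - 1)
    y <- pts[, 2] - (y0 - 1)
    x <- clamp(x, 0, nrow(cov) - 1.001)
    y <- clamp(y, 0, ncol(cov) - 1.001)
    ix <- floor(x); iy <- floor(y)
    fx <- x - ix; fy <- y - iy
    cov[cbind(ix + 1, iy + 1)] * (1 - fx) * (1 - fy) +
      cov[cbind(ix + 2, iy + 1)] * fx * (1 - fy) +
      cov[cbind(ix + 1, iy + 2)] * (1 - fx) * fy +
      cov[cbind(ix + 2, iy + 2)] * fx * fy
  }
  chord <- function(dir, half) {
    t <- seq(-half - 3, half + 3, by = step)
    # average three parallel chords a fraction of a pixel apart to smooth
    # raster phase effects near the centre line
    perp <- c(-dir[2], dir[1])
    ext <- vapply(c(-0.75, 0, 0.75), function(off) {
      pts <- cbind(ctr[1] + t * dir[1] + off * perp[1],
                   ctr[2] + t * dir[2] + off * perp[2])
      sum(sample_cov(pts)) * step
    }, 0)
    mean(ext)
  }
  c(chord(v, half_v), chord(u, half_u))
}

#' Segment and measure every kernel in a scene
#'
#' Runs [preprocess()], [find_kernels()] and [measure_kernel()] and returns
#' both the contours and a per-kernel geometry table.
#'
#' @param scene a [grain_scene()].
#' @param min_area_px minimum kernel area; default `(1 mm * ppm)^2`.
#' @param ... passed to [preprocess()].
#' @return list with `contours` (list of `kernel_contour`), `geometry`
#'   (data.frame: id, length_mm, width_mm, cx, cy, area_px), `binary`.
#' @export
segment_scene <- function(scene, min_area_px = NULL, ...) {
  if (!inherits(scene, "grain_scene")) stop_invalid("`scene` must be a grain_scene")
  if (is.null(min_area_px)) min_area_px <- scene$profile$ppm^2
  bin <- preprocess(scene$image, ...)
  ks <- find_kernels(bin, min_area_px = min_area_px)
  labels <- attr(ks, "labels")
  gray <- 0.299 * scene$image[, , 1] + 0.587 * scene$image[, , 2] +
    0.114 * scene$image[, , 3]
  geom <- lapply(ks, function(k) {
    measure_kernel(k, scene$profile, gray = gray, mask = labels == k$label)
  })
  df <- data.frame(
    id = seq_along(ks),
    length_mm = vapply(geom, `[[`, 0, "length_mm"),
    width_mm = vapply(geom, `[[`, 0, "width_mm"),
    cx = vapply(ks, function(k) k$centroid[1], 0),
    cy = vapply(ks, function(k) k$centroid[2], 0),
    area_px = vapply(ks, `[[`, 0, "area_px")
  )
  list(contours = ks, geometry = df, binary = bin,
       labels = attr(ks, "labels"))
}

#' Write an annotated overlay image
#'
#' Paints contours (orange), box corners (red) and edge midpoints (blue) on
#' the scene and writes a PNG, for operator inspection of the segmentation.
#'
#' @param scene a [grain_scene()].
#' @param contours list of `kernel_contour`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
annotate_scene <- function(scene, contours, path) {
  img <- scene$image
  d <- dim(img)
  paint <- function(img, xy, col) {
    xy <- round(xy) + 1
    ok <- xy[, 1] >= 1 & xy[, 1] <= d[1] & xy[, 2] >= 1 & xy[, 2] <= d[2]
    xy <- xy[ok, , drop = FALSE]
    for (ch in 1:3) img[cbind(xy, ch)] <- col[ch]
    img
  }
  for (k in contours) {
    img <- paint(img, k$points, c(1, 0.55, 0))
    img <- paint(img, k$box_corners, c(1, 0, 0))
    img <- paint(img, k$edge_midpoints, c(0, 0.3, 1))
  }
  EBImage::writeImage(EBImage::Image(img, colormode = "Color"), path)
  invisible(path)
}
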