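# Synthetic scanner scenes with exact ground truth.
#
# The generator renders what a calibrated flatbed scan of a single-layer
# rice sample looks like: a near-black background (the black cover sheet)
# with additive sensor noise, bright convex kernels of known millimetre
# dimensions at a known pixels-per-mm scale, and an optional reference disk.
# Kernels are capsules (a rectangle with semicircular caps) so that the
# minimum-area enclosing rectangle of the true shape is exactly
# length x width - dimension ground truth is unambiguous. Paint classes
# emulate the commercially graded kernel appearances: plain milled, yellow
# (discoloured), chalky patch (opaque white), damaged patch (darkened), and
# hull-textured paddy. Every kernel's true geometry, class and weight go
# into a manifest, which is the oracle for end-to-end evaluation.

# 8-bit palette per paint class; chosen to sit unambiguously inside/outside
# the default HSV scoring boxes (yellow hue band 20-35, chalk sat <= 40 at
# value >= 200 on the 0-179/0-255 scales).
gs_palette <- function() list(
  plain = c(190, 183, 160),
  yellow = c(204, 173, 61),
  chalky = c(245, 244, 242),
  damaged = c(77, 56, 26),
  paddy = c(175, 125, 70),
  disk = c(200, 200, 200)
)

#' Specify one synthetic kernel
#'
#' @param length_mm,width_mm kernel dimensions, `length_mm >= width_mm > 0`.
#' @param rotation_deg major-axis angle from the x axis, degrees.
#' @param centroid_px length-2 `(x, y)` centre, 0-based pixels.
#' @param paint_class one of `"plain"`, `"yellow"`, `"chalky_patch"`,
#'   `"damaged_patch"`, `"paddy_texture"`.
#' @param patch_fraction area fraction of the chalky/damaged patch, in
#'   (0, 1); ignored for other classes.
#' @param true_weight_g ground-truth weight, grams.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(length_mm, width_mm, rotation_deg = 0,
                        centroid_px = c(0, 0),
                        paint_class = c("plain", "yellow", "chalky_patch",
                                        "damaged_patch", "paddy_texture"),
                        patch_fraction = 0.4, true_weight_g = NULL) {
  paint_class <- match.arg(paint_class)
  if (!is.finite(length_mm) || !is.finite(width_mm) ||
      width_mm <= 0 || length_mm < width_mm) {
    stop_invalid("need length_mm >= width_mm > 0")
  }
  if (paint_class %in% c("chalky_patch", "damaged_patch") &&
      (patch_fraction <= 0 || patch_fraction >= 1)) {
    stop_invalid("`patch_fraction` must lie in (0, 1)")
  }
  if (is.null(true_weight_g)) {
    true_weight_g <- weight_law(length_mm, width_mm)
  }
  structure(list(length_mm = length_mm, width_mm = width_mm,
                 rotation_deg = rotation_deg, centroid_px = centroid_px,
                 paint_class = paint_class, patch_fraction = patch_fraction,
                 true_weight_g = true_weight_g),
            class = "kernel_spec")
}

#' The generator's kernel-weight law
#'
#' Ground-truth weight is a smooth volume-like function of the two measured
#' dimensions, `w = c * L * W^alpha`, optionally perturbed by multiplicative
#' noise elsewhere. The default `c` puts a 6.4 x 2.0 mm kernel at about
#' 0.0205 g, a realistic long-grain kernel mass.
#'
#' @param length_mm,width_mm kernel dimensions, mm.
#' @param c_coef scale coefficient, grams per mm^(1+alpha).
#' @param alpha width exponent, default 2.
#' @return weight in grams.
#' @export
weight_law <- function(length_mm, width_mm, c_coef = 8e-4, alpha = 2) {
  c_coef * length_mm * width_mm^alpha
}

#' Specify a synthetic scene
#'
#' @param kernels list of [kernel_spec()] objects (may be empty).
#' @param ppm render scale, pixels per millimetre.
#' @param width_px,height_px image size.
#' @param background_level background gray level on the 8-bit scale
#'   (default 15, a black cover sheet).
#' @param background_noise_sd additive Gaussian sensor noise, 8-bit units.
#' @param reference_disk optional list `(diameter_mm, center_px)` rendering
#'   a calibration disk.
#' @param seed integer seed for the background noise.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(kernels = list(), ppm = 12.5, width_px = 600,
                       height_px = 450, background_level = 15,
                       background_noise_sd = 3, reference_disk = NULL,
                       seed = 0) {
  check_positive_scalar(ppm, "ppm")
  for (k in kernels) {
    if (!inherits(k, "kernel_spec")) stop_invalid("kernels must be kernel_spec")
    half <- k$length_mm * ppm / 2 + 1
    c_px <- k$centroid_px
    if (c_px[1] - half < 0 || c_px[1] + half > width_px - 1 ||
        c_px[2] - half < 0 || c_px[2] + half > height_px - 1) {
      stop_invalid("kernel extends outside the image bounds")
    }
  }
  structure(list(kernels = kernels, ppm = ppm, width_px = width_px,
                 height_px = height_px, background_level = background_level,
                 background_noise_sd = background_noise_sd,
                 reference_disk = reference_disk, seed = seed),
            class = "scene_spec")
}

# Minimum distance between segments p1-q1 and p2-q2 (clamped closed form).
seg_seg_dist <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) {
    s <- 0; t <- clamp(f / e, 0, 1)
  } else {
    c_ <- sum(d1 * r)
    if (e <= 1e-12) {
      t <- 0; s <- clamp(-c_ / a, 0, 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-12) clamp((b * f - c_ * e) / den, 0, 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- clamp(-c_ / a, 0, 1) }
      else if (t > 1) { t <- 1; s <- clamp((b - c_) / a, 0, 1) }
    }
  }
  v <- p1 + s * d1 - (p2 + t * d2)
  sqrt(sum(v * v))
}

# Truncated normal by inverse-CDF (deterministic under the current RNG).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Random scene specification for a long-grain (IRRI-6-like) sample
#'
#' Draws kernel lengths from a truncated normal around the 6.4 mm nominal
#' long-grain length (optionally mixing in a broken fraction of short
#' fragments), widths around 2.0 mm, uniform orientations, and places the
#' kernels by rejection sampling so no two overlap (single-layer scan).
#' Paint classes are assigned by the `class_mix` proportions; true weights
#' follow [weight_law()] with multiplicative noise.
#'
#' @param n number of kernels.
#' @param ppm render scale, px/mm.
#' @param seed integer seed (drawing and placement).
#' @param width_px,height_px image size; defaults scale with `ppm` so that
#'   placement density stays constant.
#' @param length_mean,length_sd,length_range length distribution, mm.
#' @param width_mean,width_sd,width_range width distribution, mm.
#' @param broken_fraction fraction of kernels drawn as short fragments
#'   (uniform 3-4.5 mm), default 0.
#' @param class_mix named proportions over paint classes
#'   plain/yellow/chalky_patch/damaged_patch/paddy_texture.
#' @param patch_fraction_range patch area-fraction range for chalky/damaged.
#' @param weight_noise_sd multiplicative weight-noise sd, default 0.05.
#' @param max_tries placement attempts before a scene-too-crowded error.
#' @return a [scene_spec()].
#' @export
irri6_scene_spec <- function(n = 64, ppm = 12.5, seed = 0,
                             width_px = round(72 * ppm),
                             height_px = round(56 * ppm),
                             length_mean = 6.4, length_sd = 0.5,
                             length_range = c(3, 8),
                             width_mean = 2.0, width_sd = 0.15,
                             width_range = c(1.5, 2.6),
                             broken_fraction = 0,
                             class_mix = c(plain = 0.6, yellow = 0.1,
                                           chalky_patch = 0.1,
                                           damaged_patch = 0.1,
                                           paddy_texture = 0.1),
                             patch_fraction_range = c(0.35, 0.6),
                             weight_noise_sd = 0.05,
                             max_tries = 200000) {
  set.seed(seed)
  len <- rnorm_trunc(n, length_mean, length_sd, length_range[1], length_range[2])
  n_broken <- round(broken_fraction * n)
  if (n_broken > 0) {
    len[seq_len(n_broken)] <- stats::runif(n_broken, 3, 4.5)
  }
  wid <- rnorm_trunc(n, width_mean, width_sd, width_range[1], width_range[2])
  wid <- pmin(wid, len - 1e-3)
  rot <- stats::runif(n, 0, 180)
  classes <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
  pf <- stats::runif(n, patch_fraction_range[1], patch_fraction_range[2])
  eps <- pmax(stats::rnorm(n, 0, weight_noise_sd), -0.9)
  w_g <- weight_law(len, wid) * (1 + eps)

  # non-overlap placement: rejection sampling with capsule-capsule
  # (segment-segment) distance checks, 8 px clearance (scanner operators spread
  # kernels; blur halos of closer kernels would merge under hysteresis)
  half_seg <- pmax(len - wid, 0) * ppm / 2
  half_w <- wid * ppm / 2
  margin <- len * ppm / 2 + 4
  th <- rot * pi / 180
  ux <- cos(th); uy <- sin(th)
  placed <- matrix(NA_real_, n, 2)
  tries <- 0L
  for (i in order(-len)) {
    repeat {
      tries <- tries + 1L
      if (tries > max_tries) {
        gs_stop("scene too crowded: could not place all kernels",
                "gs_scene_too_crowded")
      }
      cand <- c(stats::runif(1, margin[i], width_px - 1 - margin[i]),
                stats::runif(1, margin[i], height_px - 1 - margin[i]))
      ok <- TRUE
      for (j in which(!is.na(placed[, 1]))) {
        lim <- half_w[i] + half_w[j] + 8
        if (sum((placed[j, ] - cand)^2) >
            (half_seg[i] + half_seg[j] + lim)^2) next  # far apart, cheap out
        dd <- seg_seg_dist(
          cand - half_seg[i] * c(ux[i], uy[i]),
          cand + half_seg[i] * c(ux[i], uy[i]),
          placed[j, ] - half_seg[j] * c(ux[j], uy[j]),
          placed[j, ] + half_seg[j] * c(ux[j], uy[j]))
        if (dd < lim) { ok <- FALSE; break }
      }
      if (ok) { placed[i, ] <- cand; break }
    }
  }

  kernels <- lapply(seq_len(n), function(i) {
    kernel_spec(len[i], wid[i], rot[i], placed[i, ],
                paint_class = classes[i], patch_fraction = pf[i],
                true_weight_g = w_g[i])
  })
  scene_spec(kernels = kernels, ppm = ppm, width_px = width_px,
             height_px = height_px, seed = seed)
}

# Paint one capsule kernel (or a disk when length == width) onto img.
# Returns the modified image. Coverage-antialiased; patch classes paint the
# +t end of the major axis up to the exact area fraction of solid pixels.
paint_capsule <- function(img, cx, cy, l_px, w_px, theta_deg, base_col,
                          patch_col = NULL, patch_fraction = 0,
                          texture = FALSE) {
  d <- dim(img)
  half <- l_px / 2 + 2
  xr <- max(1, floor(cx - half) + 1):min(d[1], ceiling(cx + half) + 1)
  yr <- max(1, floor(cy - half) + 1):min(d[2], ceiling(cy + half) + 1)
  x <- xr - 1
  y <- yr - 1
  th <- theta_deg * pi / 180
  u <- c(cos(th), sin(th))
  dx <- outer(x - cx, rep(1, length(y)))
  dy <- outer(rep(1, length(x)), y - cy)
  t <- dx * u[1] + dy * u[2]
  s <- -dx * u[2] + dy * u[1]
  h <- max((l_px - w_px) / 2, 0)
  dt <- pmax(abs(t) - h, 0)
  dist <- sqrt(dt^2 + s^2)
  alpha <- clamp(w_px / 2 - dist + 0.5, 0, 1)
  if (all(alpha == 0)) return(img)

  col <- array(rep(base_col / 255, each = length(t)),
               dim = c(dim(t), 3))
  if (texture) {
    mod <- 0.82 + 0.18 * sin(2 * pi * t / 4)
    for (ch in 1:3) col[, , ch] <- col[, , ch] * mod
  }
  if (!is.null(patch_col) && patch_fraction > 0) {
    solid_t <- t[alpha >= 0.5]
    t_cut <- stats::quantile(solid_t, probs = 1 - patch_fraction, names = FALSE)
    patch <- t >= t_cut
    for (ch in 1:3) {
      pc <- col[, , ch]
      pc[patch] <- patch_col[ch] / 255
      col[, , ch] <- pc
    }
  }
  for (ch in 1:3) {
    sub <- img[xr, yr, ch]
    img[xr, yr, ch] <- sub * (1 - alpha) + col[, , ch] * alpha
  }
  img
}

#' Render a synthetic scene
#'
#' Deterministic under `spec$seed`. Returns the RGB image and a ground-truth
#' manifest listing every kernel's geometry, paint class and true weight.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (array `c(nx, ny, 3)` in `[0, 1]`) and
#'   `manifest` (data.frame: id, length_mm, width_mm, rotation_deg, cx, cy,
#'   paint_class, patch_fraction, true_weight_g).
#' @export
render_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop_invalid("`spec` must be a scene_spec")
  set.seed(spec$seed)
  pal <- gs_palette()
  bg <- spec$background_level / 255
  noise <- matrix(stats::rnorm(spec$width_px * spec$height_px, 0,
                               spec$background_noise_sd / 255),
                  spec$width_px, spec$height_px)
  img <- array(0, dim = c(spec$width_px, spec$height_px, 3))
  for (ch in 1:3) img[, , ch] <- clamp(bg + noise, 0, 1)

  if (!is.null(spec$reference_disk)) {
    rd <- spec$reference_disk
    dpx <- rd$diameter_mm * spec$ppm
    img <- paint_capsule(img, rd$center_px[1], rd$center_px[2],
                         dpx, dpx, 0, pal$disk)
  }
  for (k in spec$kernels) {
    base <- switch(k$paint_class,
      plain = pal$plain, yellow = pal$yellow,
      chalky_patch = pal$plain, damaged_patch = pal$plain,
      paddy_texture = pal$paddy)
    patch <- switch(k$paint_class,
      chalky_patch = pal$chalky, damaged_patch = pal$damaged, NULL)
    img <- paint_capsule(
      img, k$centroid_px[1], k$centroid_px[2],
      k$length_mm * spec$ppm, k$width_mm * spec$ppm, k$rotation_deg,
      base, patch, k$patch_fraction,
      texture = k$paint_class == "paddy_texture")
  }
  manifest <- if (length(spec$kernels) == 0) {
    data.frame(id = integer(), length_mm = numeric(), width_mm = numeric(),
               rotation_deg = numeric(), cx = numeric(), cy = numeric(),
               paint_class = character(), patch_fraction = numeric(),
               true_weight_g = numeric())
  } else {
    data.frame(
      id = seq_along(spec$kernels),
      length_mm = vapply(spec$kernels, `[[`, 0, "length_mm"),
      width_mm = vapply(spec$kernels, `[[`, 0, "width_mm"),
      rotation_deg = vapply(spec$kernels, `[[`, 0, "rotation_deg"),
      cx = vapply(spec$kernels, function(k) k$centroid_px[1], 0),
      cy = vapply(spec$kernels, function(k) k$centroid_px[2], 0),
      paint_class = vapply(spec$kernels, `[[`, "", "paint_class"),
      patch_fraction = vapply(spec$kernels, `[[`, 0, "patch_fraction"),
      true_weight_g = vapply(spec$kernels, `[[`, 0, "true_weight_g")
    )
  }
  list(image = img, manifest = manifest)
}

#' Write a rendered scene and its manifest to disk
#'
#' @param rendered a [render_scene()] result.
#' @param image_path PNG output path.
#' @param manifest_path JSON output path (optional).
#' @return invisibly, the written paths.
#' @export
write_scene <- function(rendered, image_path, manifest_path = NULL) {
  EBImage::writeImage(EBImage::Image(rendered$image, colormode = "Color"),
                      image_path)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(rendered$manifest, manifest_path, digits = NA)
  }
  invisible(c(image_path, manifest_path))
}

#' Read a scene manifest written by [write_scene()]
#' @param path JSON manifest path.
#' @return the manifest data.frame.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Synthetic (length, width, weight) samples from the weight law
#'
#' Stands in for a manually weighed kernel dataset: lengths and widths from
#' truncated normals, weights `c * L * W^alpha * (1 + eps)` with
#' `eps ~ N(0, noise_sd^2)` truncated above -0.9.
#'
#' @param n number of samples.
#' @param c_coef,alpha weight-law parameters (see [weight_law()]).
#' @param noise_sd multiplicative noise sd (0 = exact law).
#' @param seed integer seed.
#' @param length_mean,length_sd,width_mean,width_sd dimension distributions,
#'   mm (defaults mirror a long-grain sample).
#' @return data.frame with columns `length_mm`, `width_mm`, `weight_g`.
#' @export
generate_weight_dataset <- function(n, c_coef = 8e-4, alpha = 2,
                                    noise_sd = 0, seed = 0,
                                    length_mean = 6.4, length_sd = 0.5,
                                    width_mean = 2.0, width_sd = 0.15) {
  if (n < 1) stop_invalid("`n` must be >= 1")
  set.seed(seed)
  len <- rnorm_trunc(n, length_mean, length_sd, 3, 8)
  wid <- rnorm_trunc(n, width_mean, width_sd, 1.5, 2.6)
  eps <- if (noise_sd > 0) pmax(stats::rnorm(n, 0, noise_sd), -0.9) else 0
  data.frame(
    length_mm = len, width_mm = wid,
    weight_g = weight_law(len, wid, c_coef, alpha) * (1 + eps)
  )
}

#' Labelled single-kernel crops for classifier training
#'
#' Renders `n_per_class` positive and `n_per_class` negative single-kernel
#' crops for a task: positives carry a dark damage patch (`"damaged"`) or
#' the ridged hull texture (`"paddy"`). Negatives are drawn from all other
#' kernel appearances (`neg_mix`), the way a factory "undamaged" or
#' "milled" reference set contains plain, discoloured and chalky kernels
#' alike.
#'
#' @param n_per_class crops per class, `>= 10`.
#' @param task `"damaged"` or `"paddy"`.
#' @param size output crop size in pixels (square), default 64.
#' @param ppm render scale, px/mm.
#' @param seed integer seed.
#' @param neg_mix named proportions of paint classes used for negatives;
#'   the default mixes plain with the other non-positive classes.
#' @return list with `crops` (list of `kernel_crop`) and `labels` (factor
#'   with levels `negative`, `positive`), in shuffled order.
#' @export
generate_crop_dataset <- function(n_per_class, task = c("damaged", "paddy"),
                                  size = 64, ppm = 12.5, seed = 0,
                                  neg_mix = NULL) {
  task <- match.arg(task)
  if (n_per_class < 10) stop_invalid("`n_per_class` must be >= 10")
  if (is.null(neg_mix)) {
    neg_mix <- if (task == "damaged") {
      c(plain = 0.55, yellow = 0.15, chalky_patch = 0.15, paddy_texture = 0.15)
    } else {
      c(plain = 0.55, yellow = 0.15, chalky_patch = 0.15, damaged_patch = 0.15)
    }
  }
  set.seed(seed)
  n <- 2L * n_per_class
  len <- rnorm_trunc(n, 6.4, 0.5, 4.5, 8)
  wid <- rnorm_trunc(n, 2.0, 0.15, 1.5, 2.6)
  rot <- stats::runif(n, 0, 180)
  pf <- stats::runif(n, 0.25, 0.6)
  labels <- factor(rep(c("positive", "negative"), each = n_per_class),
                   levels = c("negative", "positive"))
  neg_classes <- sample(names(neg_mix), n, replace = TRUE, prob = neg_mix)
  pos_class <- if (task == "damaged") "damaged_patch" else "paddy_texture"
  crops <- vector("list", n)
  side <- ceiling(max(len) * ppm) + 16
  ctr <- (side - 1) / 2
  profile <- calibration_profile(ppm)
  for (i in seq_len(n)) {
    cls <- if (labels[i] == "positive") pos_class else neg_classes[i]
    sp <- scene_spec(
      kernels = list(kernel_spec(len[i], wid[i], rot[i], c(ctr, ctr),
                                 paint_class = cls, patch_fraction = pf[i])),
      ppm = ppm, width_px = side, height_px = side,
      seed = (seed %% 20000) * 100003 + i
    )
    r <- render_scene(sp)
    # crop through the production path so training and analysis framing match
    scn <- grain_scene(r$image, profile,
                       source_path = sprintf("synthetic:%s:%d", task, i))
    ks <- find_kernels(preprocess(r$image), min_area_px = ppm^2)
    if (length(ks) == 0) stop_state("crop rendering produced no contour")
    areas <- vapply(ks, `[[`, 0, "area_px")
    crop <- prepare_crop(scn, ks[[which.max(areas)]], size = size)
    crop$label <- as.character(labels[i])
    crops[[i]] <- crop
  }
  ord <- sample.int(n)
  list(crops = crops[ord], labels = labels[ord])
}
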