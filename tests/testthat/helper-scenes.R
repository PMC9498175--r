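# Shared fixtures, built in code at test time.

pt_dist_test <- function(a, b) sqrt(sum((a - b)^2))

make_profile <- function(ppm = 12.5) calibration_profile(ppm)

# One kernel centred in a small scene; returns list(image, manifest)
single_kernel_scene <- function(length_mm = 6.4, width_mm = 2.0,
                                rotation = 0, paint_class = "plain",
                                patch_fraction = 0.4, ppm = 12.5,
                                seed = 1, noise_sd = 3) {
  side <- ceiling(length_mm * ppm) + 20
  sp <- scene_spec(
    kernels = list(kernel_spec(length_mm, width_mm, rotation,
                               c((side - 1) / 2, (side - 1) / 2),
                               paint_class = paint_class,
                               patch_fraction = patch_fraction)),
    ppm = ppm, width_px = side, height_px = side,
    background_noise_sd = noise_sd, seed = seed)
  render_scene(sp)
}

# Segment a rendered scene and return its geometry matched to the manifest
match_to_manifest <- function(geometry, manifest) {
  d2 <- outer(manifest$cx, geometry$cx, `-`)^2 +
    outer(manifest$cy, geometry$cy, `-`)^2
  j <- apply(d2, 1, which.min)
  cbind(manifest, det_length = geometry$length_mm[j],
        det_width = geometry$width_mm[j])
}

# Random per-kernel assessment tables for report property tests (no images)
random_assessments <- function(n, seed, broken_threshold = 4.8) {
  set.seed(seed)
  geometry <- data.frame(
    length_mm = runif(n, 2, 8.5),
    width_mm = runif(n, 1.5, 2.5),
    cx = runif(n, 0, 500), cy = runif(n, 0, 400)
  )
  geometry$width_mm <- pmin(geometry$width_mm, geometry$length_mm - 0.1)
  assess_kernels(
    geometry,
    predicted_weight_g = weight_law(geometry$length_mm, geometry$width_mm),
    broken_threshold_mm = broken_threshold,
    yellow_fraction = runif(n), chalky_fraction = runif(n),
    is_yellow = runif(n) < 0.2, is_chalky = runif(n) < 0.2,
    is_damaged = runif(n) < 0.2, is_paddy = runif(n) < 0.1
  )
}

# Models are slow-ish to train; share them across tests in one session
gs_test_env <- new.env(parent = emptyenv())

test_weight_model <- function() {
  if (is.null(gs_test_env$wm)) {
    gs_test_env$wm <- train_weight_model(
      generate_weight_dataset(400, noise_sd = 0.03, seed = 101), seed = 101)
  }
  gs_test_env$wm
}

test_classifier <- function(task) {
  key <- paste0("clf_", task)
  if (is.null(gs_test_env[[key]])) {
    d <- generate_crop_dataset(30, task, seed = 102)
    gs_test_env[[key]] <- train_classifier(
      d$crops, d$labels, classifier_spec("small_cnn", seed = 102))$classifier
  }
  gs_test_env[[key]]
}
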