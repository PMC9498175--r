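# Binary kernel-appearance classifiers: damaged vs undamaged, paddy vs
# milled.
#
# Three interchangeable backbones sit behind one train/evaluate/predict
# contract:
#   * hsv_texture_features - per-crop colour statistics (mean/sd of RGB and
#     HSV channels) with a logistic head; dependency-light and fast.
#   * small_cnn - a fixed multi-orientation convolutional filter bank
#     (edge, Laplacian and oriented-ridge filters at two scales) whose
#     pooled response statistics feed a logistic head; a desk-scale
#     convolutional classifier in the scattering-network tradition (the
#     filters are analytic, only the head is trained).
#   * vgg19_transfer - the VGG19 transfer-learning pipeline: the exact
#     19-layer architecture with its convolutional stack frozen and a
#     trainable binary head. Shipping pre-trained ImageNet weights is out of
#     scope, so the frozen stack is randomly initialised under the spec seed
#     and exercised at reduced width/input size; the structural path
#     (layer shapes, freezing, head attachment) is the real one.
#
# Damaged and paddy detection are two independently trained binary models.

#' Specify a kernel classifier
#'
#' @param backbone `"small_cnn"` (default), `"hsv_texture_features"`, or
#'   `"vgg19_transfer"`.
#' @param frozen_layers for `vgg19_transfer`: number of frozen convolutional
#'   layers, 0-16 (default all 16; the binary head is always trainable).
#' @param epochs,batch_size recorded training-schedule parameters; the
#'   logistic heads used here are fit in closed form, so these are metadata.
#' @param input_size square crop edge in pixels fed to the backbone
#'   (default 64; the canonical VGG19 input is 224).
#' @param width_scale for `vgg19_transfer`: fraction of the canonical filter
#'   counts instantiated in the frozen stack (default 1/8, smoke scale).
#' @param n_blocks for `vgg19_transfer`: convolutional blocks applied, 1-5.
#' @param seed integer seed (shuffling, head fitting, frozen-stack init).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(backbone = c("small_cnn", "hsv_texture_features",
                                         "vgg19_transfer"),
                            frozen_layers = 16, epochs = 5, batch_size = 32,
                            input_size = 64, width_scale = 1 / 8,
                            n_blocks = 2, seed = 0) {
  backbone <- match.arg(backbone)
  if (backbone == "vgg19_transfer") {
    if (frozen_layers < 0 || frozen_layers > 16) {
      stop_invalid("`frozen_layers` must lie in 0..16 (VGG19 has 16 conv layers)")
    }
    if (n_blocks < 1 || n_blocks > 5) stop_invalid("`n_blocks` must lie in 1..5")
    if (width_scale <= 0 || width_scale > 1) {
      stop_invalid("`width_scale` must lie in (0, 1]")
    }
  }
  if (input_size < 16) stop_invalid("`input_size` must be >= 16")
  if (epochs < 1 || batch_size < 1) stop_invalid("epochs and batch_size must be >= 1")
  structure(list(backbone = backbone, frozen_layers = frozen_layers,
                 epochs = epochs, batch_size = batch_size,
                 input_size = input_size, width_scale = width_scale,
                 n_blocks = n_blocks, seed = seed),
            class = "classifier_spec")
}

#' The VGG19 layer architecture
#'
#' Returns the canonical 19-layer VGG19 architecture (16 convolutional
#' layers in 5 blocks plus 3 fully connected layers), with 3x3 filters of
#' stride 1 and 2x2 max-pooling of stride 2, and the spatial shape flow for
#' a given input size. Used to validate transfer-learning specs and to
#' instantiate the frozen stack.
#'
#' @param input_size input edge length, default 224.
#' @param binary_head if `TRUE`, the three FC layers are replaced by the
#'   binary sigmoid head used for two-class grading tasks.
#' @return data.frame: `name`, `type`, `filters`, `kernel`, `out_size`
#'   (spatial edge after the layer), `trainable`.
#' @export
vgg19_architecture <- function(input_size = 224, binary_head = FALSE) {
  blocks <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                 c(512, 512, 512, 512), c(512, 512, 512, 512))
  rows <- list()
  size <- input_size
  for (b in seq_along(blocks)) {
    for (l in seq_along(blocks[[b]])) {
      rows[[length(rows) + 1]] <- data.frame(
        name = sprintf("block%d_conv%d", b, l), type = "conv",
        filters = blocks[[b]][l], kernel = "3x3/1", out_size = size,
        trainable = FALSE)
    }
    size <- floor(size / 2)
    rows[[length(rows) + 1]] <- data.frame(
      name = sprintf("block%d_pool", b), type = "maxpool", filters = NA,
      kernel = "2x2/2", out_size = size, trainable = FALSE)
  }
  head_rows <- if (binary_head) {
    data.frame(name = c("flatten", "binary_head"),
               type = c("flatten", "dense"),
               filters = c(NA, 1), kernel = c(NA, "sigmoid"),
               out_size = c(size, 1), trainable = c(FALSE, TRUE))
  } else {
    data.frame(name = c("fc1", "fc2", "predictions"),
               type = "dense", filters = c(4096, 4096, 1000),
               kernel = c("relu", "relu", "softmax"), out_size = 1,
               trainable = TRUE)
  }
  rbind(do.call(rbind, rows), head_rows)
}

# --- feature extractors ----------------------------------------------------

crop_image <- function(crop) {
  img <- if (inherits(crop, "kernel_crop")) crop$image else crop
  as_rgb_array(img)
}

# mean/sd of R, G, B, H, S, V over the crop -> 12 features
features_hsv <- function(img) {
  hsv <- rgb_to_hsv_cv(img)
  v <- c()
  for (ch in 1:3) v <- c(v, mean(img[, , ch]), stats::sd(img[, , ch]))
  for (ch in 1:3) v <- c(v, mean(hsv[, , ch]), stats::sd(hsv[, , ch]))
  v
}

# analytic filter bank: Sobel pair, Laplacian, 4 oriented ridge filters
gs_filter_bank <- function() {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  ridge <- function(theta, size = 5, period = 4) {
    g <- expand.grid(x = -(size %/% 2):(size %/% 2),
                     y = -(size %/% 2):(size %/% 2))
    w <- cos(2 * pi * (g$x * cos(theta) + g$y * sin(theta)) / period) *
      exp(-(g$x^2 + g$y^2) / (2 * (size / 3)^2))
    m <- matrix(w, size, size)
    m - mean(m)
  }
  c(list(sobel_x = sx, sobel_y = t(sx), laplacian = lap),
    stats::setNames(lapply(c(0, pi / 4, pi / 2, 3 * pi / 4), ridge),
                    c("ridge0", "ridge45", "ridge90", "ridge135")))
}

# pooled filter-bank responses on the gray channel at two scales + colour
# statistics -> 54 features
features_small_cnn <- function(img, bank) {
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  half <- EBImage::imageData(EBImage::resize(EBImage::Image(gray),
                                             w = max(8, nrow(gray) %/% 2)))
  v <- c()
  for (scale in list(gray, half)) {
    for (f in bank) {
      r <- EBImage::imageData(EBImage::filter2(EBImage::Image(scale), f))
      v <- c(v, mean(abs(r)), stats::sd(r), max(abs(r)))
    }
  }
  c(v, features_hsv(img))
}

max_pool2 <- function(m) {
  nx <- (nrow(m) %/% 2) * 2
  ny <- (ncol(m) %/% 2) * 2
  m <- m[seq_len(nx), seq_len(ny), drop = FALSE]
  pmax(m[seq(1, nx, 2), seq(1, ny, 2), drop = FALSE],
       m[seq(2, nx, 2), seq(1, ny, 2), drop = FALSE],
       m[seq(1, nx, 2), seq(2, ny, 2), drop = FALSE],
       m[seq(2, nx, 2), seq(2, ny, 2), drop = FALSE])
}

# Seeded He-initialised frozen VGG19 conv stack at reduced width.
vgg19_stack_weights <- function(spec) {
  blocks <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                 c(512, 512, 512, 512), c(512, 512, 512, 512))
  blocks <- blocks[seq_len(spec$n_blocks)]
  set.seed(spec$seed + 7919)
  weights <- list()
  in_ch <- 3L
  layer_idx <- 0L
  for (b in seq_along(blocks)) {
    for (l in seq_along(blocks[[b]])) {
      layer_idx <- layer_idx + 1L
      out_ch <- max(4L, round(blocks[[b]][l] * spec$width_scale))
      sdv <- sqrt(2 / (9 * in_ch))
      w <- array(stats::rnorm(3 * 3 * in_ch * out_ch, 0, sdv),
                 dim = c(3, 3, in_ch, out_ch))
      weights[[layer_idx]] <- list(w = w, block = b,
                                   pool_after = l == length(blocks[[b]]))
      in_ch <- out_ch
    }
  }
  weights
}

# forward pass through the frozen stack; global mean+max pool per channel
features_vgg19 <- function(img, weights) {
  chans <- lapply(1:3, function(ch) img[, , ch])
  for (layer in weights) {
    out_ch <- dim(layer$w)[4]
    nxt <- vector("list", out_ch)
    for (o in seq_len(out_ch)) {
      acc <- 0
      for (i in seq_along(chans)) {
        acc <- acc + EBImage::imageData(
          EBImage::filter2(EBImage::Image(chans[[i]]), layer$w[, , i, o]))
      }
      nxt[[o]] <- pmax(acc, 0)  # ReLU
    }
    if (layer$pool_after) nxt <- lapply(nxt, max_pool2)
    chans <- nxt
  }
  unlist(lapply(chans, function(m) c(mean(m), max(m))))
}

classifier_features <- function(crops, backbone, bank = NULL, weights = NULL,
                                input_size = 64) {
  rows <- lapply(crops, function(cr) {
    img <- crop_image(cr)
    if (dim(img)[1] != input_size) {
      img <- EBImage::imageData(EBImage::resize(
        EBImage::Image(img, colormode = "Color"),
        w = input_size, h = input_size))
    }
    switch(backbone,
           hsv_texture_features = features_hsv(img),
           small_cnn = features_small_cnn(img, bank),
           vgg19_transfer = features_vgg19(img, weights))
  })
  do.call(rbind, rows)
}

# --- crops ----------------------------------------------------------------

#' Extract a square classifier crop for one kernel
#'
#' Crops the kernel's axis-aligned bounding rectangle padded by 10% per
#' side, pads to a square with the scene's median background colour (off-
#' image regions for border kernels are filled the same way), and resizes
#' to `size` x `size`. Pixels outside the kernel's convex outline are set
#' to the background colour, so crops look the same whether the kernel sat
#' alone or next to other grains.
#'
#' @param scene a [grain_scene()].
#' @param contour a `kernel_contour` from [find_kernels()].
#' @param size output edge length, default 224 (the canonical VGG19 input).
#' @return an object of class `kernel_crop` (`image`, `label = NA`,
#'   `origin`).
#' @export
prepare_crop <- function(scene, contour, size = 224) {
  if (!inherits(scene, "grain_scene")) stop_invalid("`scene` must be a grain_scene")
  img <- scene$image
  d <- dim(img)
  pts <- contour$points
  if (any(pts[, 1] < 0) || any(pts[, 2] < 0) ||
      any(pts[, 1] > d[1] - 1) || any(pts[, 2] > d[2] - 1)) {
    stop_invalid("contour lies outside the image")
  }
  x0 <- min(pts[, 1]); x1 <- max(pts[, 1])
  y0 <- min(pts[, 2]); y1 <- max(pts[, 2])
  padx <- 0.1 * (x1 - x0 + 1); pady <- 0.1 * (y1 - y0 + 1)
  x0 <- floor(x0 - padx); x1 <- ceiling(x1 + padx)
  y0 <- floor(y0 - pady); y1 <- ceiling(y1 + pady)
  side <- max(x1 - x0 + 1, y1 - y0 + 1)
  cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
  x0 <- round(cx - side / 2); y0 <- round(cy - side / 2)
  bg <- vapply(1:3, function(ch) stats::median(img[, , ch]), 0)
  sq <- array(rep(bg, each = side * side), dim = c(side, side, 3))
  xs <- x0:(x0 + side - 1); ys <- y0:(y0 + side - 1)
  okx <- xs >= 0 & xs <= d[1] - 1
  oky <- ys >= 0 & ys <= d[2] - 1
  sq[which(okx), which(oky), ] <- img[xs[okx] + 1, ys[oky] + 1, , drop = FALSE]
  # blank out neighbouring grains: keep only the kernel's convex outline
  # (dilated by one pixel so the antialiased rim survives)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  gx <- outer(xs, rep(1, side))
  gy <- outer(rep(1, side), ys)
  inside <- matrix(TRUE, side, side)
  nh <- nrow(hull)
  nxt <- rbind(hull[-1, , drop = FALSE], hull[1, , drop = FALSE])
  orient <- sign(sum(hull[, 1] * nxt[, 2] - nxt[, 1] * hull[, 2]))  # winding
  for (e in seq_len(nh)) {
    a <- hull[e, ]; b <- nxt[e, ]
    edge_len <- sqrt(sum((b - a)^2))
    if (edge_len < 1e-9) next
    cr <- (b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])
    inside <- inside & (orient * cr >= -1.5 * edge_len)
  }
  for (ch in 1:3) {
    pl <- sq[, , ch]
    pl[!inside] <- bg[ch]
    sq[, , ch] <- pl
  }
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(sq, colormode = "Color"), w = size, h = size))
  structure(list(image = out, label = NA_character_,
                 origin = sprintf("%s:contour@(%.0f,%.0f)",
                                  scene$source_path, contour$centroid[1],
                                  contour$centroid[2])),
            class = "kernel_crop")
}

# --- training / evaluation ------------------------------------------------

#' Confusion counts and accuracy of binary predictions
#'
#' @param tp,fp,fn,tn confusion counts (positive = the flagged class).
#' @return object of class `eval_result`: `confusion` (named counts),
#'   `accuracy` (percent).
#' @export
eval_result <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  if (total == 0) stop_invalid("empty evaluation set")
  structure(list(
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
    accuracy = 100 * (tp + tn) / total
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> accuracy %.1f%%  (TP %d, FP %d, FN %d, TN %d)\n",
              x$accuracy, x$confusion["TP"], x$confusion["FP"],
              x$confusion["FN"], x$confusion["TN"]))
  invisible(x)
}

coerce_labels <- function(labels, n) {
  labels <- factor(as.character(labels), levels = c("negative", "positive"))
  if (any(is.na(labels))) {
    stop_invalid("labels must be 'positive'/'negative'")
  }
  if (length(labels) != n) stop_invalid("one label per crop required")
  labels
}

#' Train a binary kernel classifier
#'
#' Shuffles the labelled crops under `seed`, holds out
#' `1 - train_fraction`, extracts backbone features, fits the
#' ridge-regularised logistic head on the training split, and reports the
#' held-out confusion matrix and accuracy.
#'
#' @param crops list of `kernel_crop` (or RGB arrays); at least 20.
#' @param labels `"positive"`/`"negative"` per crop; both classes required.
#' @param spec a [classifier_spec()].
#' @param train_fraction training share, default 0.8.
#' @param seed integer seed for the shuffle (defaults to `spec$seed`).
#' @return list with `classifier` (class `kernel_classifier`) and `eval`
#'   (held-out [eval_result()]).
#' @export
train_classifier <- function(crops, labels, spec = classifier_spec(),
                             train_fraction = 0.8, seed = spec$seed) {
  if (!inherits(spec, "classifier_spec")) stop_invalid("`spec` must be a classifier_spec")
  n <- length(crops)
  if (n < 20) stop_invalid("need at least 20 crops")
  labels <- coerce_labels(labels, n)
  if (nlevels(droplevels(labels)) < 2) {
    stop_invalid("both classes must be present in the training crops")
  }
  bank <- if (spec$backbone == "small_cnn") gs_filter_bank() else NULL
  weights <- if (spec$backbone == "vgg19_transfer") vgg19_stack_weights(spec) else NULL

  set.seed(seed)
  idx <- sample.int(n)
  n_train <- max(2L, floor(train_fraction * n))
  tr <- idx[seq_len(n_train)]
  te <- idx[-seq_len(n_train)]
  if (nlevels(droplevels(labels[tr])) < 2) {
    stop_invalid("training split lost a class; provide more crops")
  }
  feats <- classifier_features(crops, spec$backbone, bank, weights,
                               spec$input_size)
  fit <- glmnet::glmnet(feats[tr, , drop = FALSE], labels[tr],
                        family = "binomial", alpha = 0, lambda = 1e-2)
  clf <- structure(list(spec = spec, fit = fit, bank = bank,
                        weights = weights, seed = seed,
                        n_train = length(tr)),
                   class = "kernel_classifier")
  ev <- if (length(te) > 0) {
    evaluate_classifier(clf, crops[te], labels[te],
                        .features = feats[te, , drop = FALSE])
  } else NULL
  list(classifier = clf, eval = ev)
}

#' Predict crop labels with a trained classifier
#'
#' @param classifier a `kernel_classifier` from [train_classifier()].
#' @param crops list of `kernel_crop` or RGB arrays.
#' @return factor of `"negative"`/`"positive"` predictions.
#' @export
predict_crops <- function(classifier, crops) {
  if (!inherits(classifier, "kernel_classifier") || is.null(classifier$fit)) {
    stop_state("classifier is not fitted")
  }
  feats <- classifier_features(crops, classifier$spec$backbone,
                               classifier$bank, classifier$weights,
                               classifier$spec$input_size)
  p <- stats::predict(classifier$fit, feats, type = "response")[, 1]
  factor(ifelse(p >= 0.5, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' @export
predict.kernel_classifier <- function(object, newdata, ...) {
  predict_crops(object, newdata)
}

#' Evaluate a classifier on labelled crops
#'
#' @inheritParams predict_crops
#' @param labels true labels.
#' @param .features internal: precomputed feature matrix.
#' @return an [eval_result()].
#' @export
evaluate_classifier <- function(classifier, crops, labels, .features = NULL) {
  if (!inherits(classifier, "kernel_classifier") || is.null(classifier$fit)) {
    stop_state("classifier is not fitted")
  }
  labels <- coerce_labels(labels, length(crops))
  pred <- if (is.null(.features)) {
    predict_crops(classifier, crops)
  } else {
    p <- stats::predict(classifier$fit, .features, type = "response")[, 1]
    factor(ifelse(p >= 0.5, "positive", "negative"),
           levels = c("negative", "positive"))
  }
  eval_result(
    tp = sum(pred == "positive" & labels == "positive"),
    fp = sum(pred == "positive" & labels == "negative"),
    fn = sum(pred == "negative" & labels == "positive"),
    tn = sum(pred == "negative" & labels == "negative")
  )
}

#' Save / load a kernel classifier
#'
#' @param classifier a `kernel_classifier`.
#' @param path file path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier` the
#'   classifier.
#' @export
save_classifier <- function(classifier, path) {
  if (!inherits(classifier, "kernel_classifier")) stop_invalid("not a kernel_classifier")
  saveRDS(c(unclass(classifier), list(format = "gs-classifier-1")), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "gs-classifier-1")) {
    stop_invalid("not a grainscan classifier file")
  }
  x$format <- NULL
  structure(x, class = "kernel_classifier")
}
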