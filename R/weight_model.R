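# Per-kernel weight prediction: random forest on (length, width).
#
# The rice trade limits broken content as a percent BY WEIGHT, so each
# kernel needs a weight even though only the whole sample is ever on a
# scale. A random forest regressor trained on manually weighed kernels maps
# (length_mm, width_mm) to grams; fit quality is tracked as RMSE and MAPE on
# a held-out split.

#' Root mean square error
#'
#' `sqrt(mean((actual - predicted)^2))`.
#'
#' @param actual,predicted equal-length numeric vectors.
#' @return nonnegative scalar, in the units of the inputs.
#' @export
rmse <- function(actual, predicted) {
  check_metric_args(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' Mean absolute percentage error
#'
#' `100 * mean(abs(actual - predicted) / actual)`, in percent. Undefined when
#' any actual value is zero.
#'
#' @inheritParams rmse
#' @return nonnegative scalar, percent.
#' @export
mape <- function(actual, predicted) {
  check_metric_args(actual, predicted)
  if (any(actual == 0)) {
    stop_invalid("`actual` contains zero: relative error undefined")
  }
  100 * mean(abs(actual - predicted) / abs(actual))
}

check_metric_args <- function(actual, predicted) {
  if (length(actual) == 0 || length(actual) != length(predicted)) {
    stop_invalid("`actual` and `predicted` must have equal nonzero length")
  }
  if (!is.numeric(actual) || !is.numeric(predicted) ||
      any(!is.finite(actual)) || any(!is.finite(predicted))) {
    stop_invalid("metric inputs must be finite numeric vectors")
  }
  invisible(NULL)
}

#' Train the kernel-weight regressor
#'
#' Shuffles the samples with `seed`, holds out `1 - train_fraction` of them,
#' fits a random forest of `n_estimators` trees on
#' `(length_mm, width_mm) -> weight_g`, and records RMSE (grams) and MAPE
#' (percent) on the held-out split. Forest hyperparameters beyond the tree
#' count are left at the randomForest defaults and recorded in the model for
#' reproducibility.
#'
#' @param samples data.frame with columns `length_mm`, `width_mm`,
#'   `weight_g`, all positive; at least 10 rows.
#' @param n_estimators number of trees, default 100.
#' @param train_fraction fraction used for training, in (0, 1); default 0.8.
#' @param seed integer seed controlling the shuffle and the forest.
#' @return object of class `weight_model` with elements `forest`,
#'   `n_estimators`, `seed`, `train_fraction`, `n_train`, `n_test`,
#'   `metrics` (list: `rmse` grams, `mape` percent).
#' @examples
#' \donttest{
#' d <- generate_weight_dataset(200, seed = 1)
#' m <- train_weight_model(d, seed = 1)
#' m$metrics$mape
#' }
#' @export
train_weight_model <- function(samples, n_estimators = 100,
                               train_fraction = 0.8, seed = 0) {
  cols <- c("length_mm", "width_mm", "weight_g")
  if (!is.data.frame(samples) || !all(cols %in% names(samples))) {
    stop_invalid("`samples` needs columns length_mm, width_mm, weight_g")
  }
  samples <- samples[, cols]
  if (nrow(samples) < 10) stop_invalid("need at least 10 samples")
  if (any(as.matrix(samples) <= 0)) stop_invalid("all sample values must be > 0")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_invalid("`train_fraction` must lie in (0, 1)")
  }
  if (n_estimators < 1) stop_invalid("`n_estimators` must be >= 1")

  n <- nrow(samples)
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- max(1L, floor(train_fraction * n))
  tr <- samples[idx[seq_len(n_train)], ]
  te <- samples[idx[-seq_len(n_train)], ]
  forest <- randomForest::randomForest(
    x = tr[, c("length_mm", "width_mm")], y = tr$weight_g,
    ntree = n_estimators
  )
  pred <- unname(stats::predict(forest, te[, c("length_mm", "width_mm")]))
  structure(
    list(forest = forest, n_estimators = n_estimators, seed = seed,
         train_fraction = train_fraction, n_train = nrow(tr),
         n_test = nrow(te),
         metrics = list(rmse = rmse(te$weight_g, pred),
                        mape = mape(te$weight_g, pred))),
    class = "weight_model"
  )
}

#' @export
print.weight_model <- function(x, ...) {
  cat(sprintf(
    "<weight_model> %d trees, %d train / %d test\n  test RMSE %.3g g, MAPE %.3g%%\n",
    x$n_estimators, x$n_train, x$n_test, x$metrics$rmse, x$metrics$mape))
  invisible(x)
}

#' Predict kernel weight from length and width
#'
#' @param model a fitted [train_weight_model()] result.
#' @param length_mm,width_mm positive kernel dimensions (vectorised).
#' @return predicted weight in grams.
#' @export
predict_weight <- function(model, length_mm, width_mm) {
  if (!inherits(model, "weight_model") || is.null(model$forest)) {
    stop_state("`model` is not a fitted weight_model")
  }
  if (length(length_mm) != length(width_mm)) {
    stop_invalid("length_mm and width_mm must have equal length")
  }
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(length_mm <= 0) || any(width_mm <= 0)) {
    stop_invalid("kernel dimensions must be positive")
  }
  unname(stats::predict(model$forest,
                        data.frame(length_mm = length_mm, width_mm = width_mm)))
}

#' Save / load a weight model
#'
#' Persists the fitted forest together with its seed, hyperparameters and
#' held-out metrics (R serialisation, version 2 format header `gs-weight-1`
#' recorded inside the object).
#'
#' @param model a `weight_model`.
#' @param path file path.
#' @return `save_weight_model` returns `path` invisibly; `load_weight_model`
#'   the model.
#' @export
save_weight_model <- function(model, path) {
  if (!inherits(model, "weight_model")) stop_invalid("not a weight_model")
  saveRDS(c(unclass(model), list(format = "gs-weight-1")), path)
  invisible(path)
}

#' @rdname save_weight_model
#' @export
load_weight_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "gs-weight-1")) {
    stop_invalid("not a grainscan weight-model file")
  }
  x$format <- NULL
  structure(x, class = "weight_model")
}
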