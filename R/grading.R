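# Broken/head-rice grading and the sample-level quality report.
#
# Grading is threshold-based: a kernel shorter than the configured broken
# length is broken; head rice is the strictly-longer premium fraction. The
# threshold is a per-rice-type commercial parameter with no universal
# default - every buyer sets their own. Percentages in the report are by
# weight (the trade's basis for broken-grain limits), using the predicted
# per-kernel weights.

#' Broken-kernel classification by length threshold
#'
#' A kernel is broken when its length is strictly below the threshold; a
#' kernel exactly at the threshold counts as unbroken (the tie convention is
#' documented, not standard). Vectorised over `length_mm`.
#'
#' @param length_mm kernel length(s), mm, positive.
#' @param broken_threshold_mm threshold, mm, positive.
#' @return logical vector: `TRUE` = broken.
#' @export
classify_broken <- function(length_mm, broken_threshold_mm) {
  if (!is.numeric(broken_threshold_mm) || length(broken_threshold_mm) != 1 ||
      !is.finite(broken_threshold_mm) || broken_threshold_mm <= 0) {
    stop_config("`broken_threshold_mm` must be a positive number")
  }
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    stop_invalid("`length_mm` must be positive")
  }
  length_mm < broken_threshold_mm
}

#' Assemble per-kernel assessments
#'
#' Joins geometry, colour scores, classifier flags and predicted weights
#' into the per-kernel assessment table consumed by [build_histogram()] and
#' [summarize_sample()]. `is_head_rice` is `TRUE` for kernels strictly
#' longer than the broken threshold, so head rice is always a subset of the
#' unbroken kernels. Flags are independent: a kernel may be, say, both
#' yellow and broken.
#'
#' @param geometry data.frame with `length_mm`, `width_mm` (and optionally
#'   `cx`, `cy`).
#' @param predicted_weight_g positive predicted weights, one per kernel.
#' @param broken_threshold_mm the grading threshold, mm.
#' @param yellow_fraction,chalky_fraction,is_yellow,is_chalky per-kernel
#'   colour scores/flags (default: none flagged).
#' @param is_damaged,is_paddy classifier flags (default: none flagged).
#' @return data.frame of class `kernel_assessments`.
#' @export
assess_kernels <- function(geometry, predicted_weight_g, broken_threshold_mm,
                           yellow_fraction = 0, chalky_fraction = 0,
                           is_yellow = FALSE, is_chalky = FALSE,
                           is_damaged = FALSE, is_paddy = FALSE) {
  n <- nrow(geometry)
  if (n == 0) stop_invalid("no kernels to assess")
  if (any(predicted_weight_g <= 0)) stop_invalid("predicted weights must be > 0")
  out <- data.frame(
    length_mm = geometry$length_mm,
    width_mm = geometry$width_mm,
    cx = if ("cx" %in% names(geometry)) geometry$cx else NA_real_,
    cy = if ("cy" %in% names(geometry)) geometry$cy else NA_real_,
    predicted_weight_g = rep_len(predicted_weight_g, n),
    yellow_fraction = rep_len(yellow_fraction, n),
    chalky_fraction = rep_len(chalky_fraction, n),
    is_yellow = rep_len(is_yellow, n),
    is_chalky = rep_len(is_chalky, n),
    is_damaged = rep_len(is_damaged, n),
    is_paddy = rep_len(is_paddy, n)
  )
  out$is_broken <- classify_broken(out$length_mm, broken_threshold_mm)
  out$is_head_rice <- out$length_mm > broken_threshold_mm
  attr(out, "broken_threshold_mm") <- broken_threshold_mm
  class(out) <- c("kernel_assessments", "data.frame")
  out
}

#' Length histogram with percent by weight
#'
#' Bins kernels into unit millimetre bins `[1,2), [2,3), ..., [9,10)` and
#' reports per bin the kernel count, the mean length of its kernels (0 for
#' empty bins), and the bin's share of total sample weight. The reported
#' `percent_by_weight` column is rounded to one decimal, so it can sum below
#' 100; the unrounded `percent_by_weight_raw` column always sums to exactly
#' 100 over a nonempty sample. Kernels outside 1-10 mm land in an `overflow`
#' row flagged in the result.
#'
#' @param assessments a [assess_kernels()] table.
#' @param weight_basis `"weight"` (default: percent of summed predicted
#'   weight) or `"count"` (percent of kernel count, for diagnostics).
#' @return data.frame: `lo`, `hi`, `range`, `count`, `agl` (mean length,
#'   mm), `percent_by_weight`, `percent_by_weight_raw`; attribute
#'   `has_overflow`.
#' @export
build_histogram <- function(assessments, weight_basis = c("weight", "count")) {
  weight_basis <- match.arg(weight_basis)
  if (nrow(assessments) == 0) stop_invalid("empty assessment list")
  len <- assessments$length_mm
  w <- if (weight_basis == "weight") assessments$predicted_weight_g else
    rep(1, length(len))
  total_w <- sum(w)
  lo <- 1:9
  bin <- findInterval(len, c(lo, 10))  # 0 => below 1 mm; 10 => >= 10 mm
  overflow <- bin == 0 | bin == 10
  rows <- lapply(lo, function(l) {
    in_bin <- bin == l & !overflow
    data.frame(
      lo = l, hi = l + 1, range = sprintf("(%d-%d)", l, l + 1),
      count = sum(in_bin),
      agl = if (any(in_bin)) mean(len[in_bin]) else 0,
      percent_by_weight_raw = if (total_w > 0) 100 * sum(w[in_bin]) / total_w else 0
    )
  })
  out <- do.call(rbind, rows)
  if (any(overflow)) {
    out <- rbind(out, data.frame(
      lo = NA, hi = NA, range = "overflow",
      count = sum(overflow),
      agl = mean(len[overflow]),
      percent_by_weight_raw = 100 * sum(w[overflow]) / total_w
    ))
  }
  out$percent_by_weight <- round(out$percent_by_weight_raw, 1)
  out <- out[, c("lo", "hi", "range", "count", "agl",
                 "percent_by_weight", "percent_by_weight_raw")]
  attr(out, "has_overflow") <- any(overflow)
  out
}

#' Percent deviation of a manual measurement from the software value
#'
#' `100 * (manual - software) / software`, rounded to two decimals: the
#' deviation of a manually measured average grain length from the software
#' measurement, relative to the software value (so a longer software reading
#' gives a negative deviation). Vectorised.
#'
#' @param manual_agl manually measured average grain length, mm.
#' @param software_agl software-measured average grain length, mm, positive.
#' @return percent deviation rounded to 2 decimals.
#' @export
percent_deviation <- function(manual_agl, software_agl) {
  if (any(!is.finite(software_agl)) || any(software_agl <= 0)) {
    stop_invalid("`software_agl` must be positive")
  }
  round(100 * (manual_agl - software_agl) / software_agl, 2)
}

#' Sample-level quality report
#'
#' Aggregates per-kernel assessments into the report a grading operator
#' reads: totals, average grain length/width (AGL/AGW, unweighted means),
#' head-rice AGL, whole/broken counts and weights, per-feature counts and
#' summed predicted weights for yellow/chalky/damaged/paddy kernels (counts
#' are non-exclusive), and the length histogram.
#'
#' @param assessments a [assess_kernels()] table.
#' @param weight_basis passed to [build_histogram()].
#' @param sample_grams optional measured mass of the weighed sample (10 or
#'   100 g trays in practice), recorded alongside the predicted total.
#' @return object of class `quality_report`.
#' @export
summarize_sample <- function(assessments, weight_basis = "weight",
                             sample_grams = NA_real_) {
  if (nrow(assessments) == 0) stop_invalid("empty assessment list")
  a <- assessments
  total_w <- sum(a$predicted_weight_g)
  feature <- function(flag) list(
    count = sum(flag),
    weight_g = sum(a$predicted_weight_g[flag]),
    percent_by_weight = if (total_w > 0) 100 * sum(a$predicted_weight_g[flag]) / total_w else 0
  )
  structure(list(
    total_grains = nrow(a),
    total_weight_g = total_w,
    sample_grams = sample_grams,
    agl_mm = mean(a$length_mm),
    agw_mm = mean(a$width_mm),
    head_rice_agl_mm = if (any(a$is_head_rice)) mean(a$length_mm[a$is_head_rice]) else 0,
    whole_count = sum(!a$is_broken),
    broken_count = sum(a$is_broken),
    broken_threshold_mm = attr(a, "broken_threshold_mm"),
    features = list(
      yellow = feature(a$is_yellow),
      chalky = feature(a$is_chalky),
      damaged = feature(a$is_damaged),
      paddy = feature(a$is_paddy),
      broken = feature(a$is_broken)
    ),
    histogram = build_histogram(a, weight_basis = weight_basis)
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("== Grain quality report ==\n")
  cat(sprintf("grains: %d   predicted weight: %.3f g\n",
              x$total_grains, x$total_weight_g))
  cat(sprintf("AGL %.3f mm   AGW %.3f mm   head-rice AGL %.3f mm\n",
              x$agl_mm, x$agw_mm, x$head_rice_agl_mm))
  cat(sprintf("whole %d / broken %d (threshold %.2f mm, broken %.1f%% by weight)\n",
              x$whole_count, x$broken_count, x$broken_threshold_mm,
              x$features$broken$percent_by_weight))
  for (f in c("yellow", "chalky", "damaged", "paddy")) {
    cat(sprintf("  %-7s %3d kernels  %.3f g\n", f, x$features[[f]]$count,
                x$features[[f]]$weight_g))
  }
  h <- x$histogram
  cat("length histogram (mm):\n")
  for (i in seq_len(nrow(h))) {
    cat(sprintf("  %-8s n=%-4d AGL=%-6.3f %5.1f%% by weight\n",
                h$range[i], h$count[i], h$agl[i], h$percent_by_weight[i]))
  }
  invisible(x)
}

#' Write a quality report as JSON and CSV
#'
#' The JSON document carries the full report; the CSV pair mirrors the two
#' tables an operator works with (the length histogram and the per-feature
#' summary rows).
#'
#' @param report a [summarize_sample()] result.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!inherits(report, "quality_report")) stop_invalid("not a quality_report")
  written <- list()
  if (!is.null(json_path)) {
    x <- unclass(report)
    x$histogram <- as.data.frame(report$histogram)
    jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    written$json <- json_path
  }
  if (!is.null(csv_path)) {
    h <- report$histogram
    utils::write.csv(
      data.frame(Range = h$range, Count = h$count,
                 AGL = round(h$agl, 3),
                 Percent_by_Weight = h$percent_by_weight),
      csv_path, row.names = FALSE)
    feat <- do.call(rbind, lapply(names(report$features), function(f) {
      data.frame(Feature = f, Count = report$features[[f]]$count,
                 Weight_g = round(report$features[[f]]$weight_g, 4))
    }))
    summary_path <- sub("(\\.csv)?$", "_summary.csv", csv_path)
    utils::write.csv(feat, summary_path, row.names = FALSE)
    written$csv <- c(csv_path, summary_path)
  }
  invisible(written)
}
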