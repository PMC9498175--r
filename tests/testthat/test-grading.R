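test_that("broken classification follows the strict-below convention", {
  expect_true(classify_broken(4.0, 5.0))
  expect_false(classify_broken(6.0, 5.0))
  expect_false(classify_broken(5.0, 5.0))  # tie counts as unbroken
  expect_error(classify_broken(4, -1), class = "gs_config_error")
  expect_error(classify_broken(-4, 5), class = "gs_invalid_input")
})

test_that("percent deviation reproduces the manual-vs-software convention", {
  expect_equal(percent_deviation(5.996, 6.146), -2.44)
  expect_equal(percent_deviation(5.941, 5.816), 2.15)
  expect_equal(percent_deviation(6, 6), 0)
  expect_error(percent_deviation(6, 0), class = "gs_invalid_input")
})

test_that("the length histogram conserves counts and weight", {
  set.seed(31)
  # all kernels in [6,7)
  g <- data.frame(length_mm = runif(64, 6, 6.99), width_mm = 2)
  a <- assess_kernels(g, weight_law(g$length_mm, 2), 4.8)
  h <- build_histogram(a)
  expect_equal(h$count[h$lo == 6], 64)
  expect_equal(h$percent_by_weight[h$lo == 6], 100)
  expect_equal(sum(h$count), 64)
  expect_equal(sum(h$percent_by_weight_raw), 100, tolerance = 1e-9)
})

test_that("a target bin-count vector is reproduced exactly", {
  target <- c(0, 0, 2, 4, 8, 44, 6, 0, 0)  # counts for bins (1-2)...(9-10)
  set.seed(32)
  lengths <- unlist(lapply(seq_along(target), function(i) {
    runif(target[i], i + 0.05, i + 0.95)
  }))
  g <- data.frame(length_mm = lengths, width_mm = 2)
  a <- assess_kernels(g, weight_law(lengths, 2), 4.8)
  h <- build_histogram(a)
  expect_equal(h$count, target)
  expect_equal(sum(h$count), sum(target))
  # per-bin mean lengths sit inside their bins
  nonzero <- h$count > 0
  expect_true(all(h$agl[nonzero] >= h$lo[nonzero] &
                    h$agl[nonzero] < h$hi[nonzero]))
  expect_true(all(h$agl[!nonzero] == 0))
})

test_that("rounded percents may undershoot 100 while raw percents never do", {
  set.seed(33)
  a <- random_assessments(37, seed = 33)
  h <- build_histogram(a)
  expect_lte(sum(h$percent_by_weight), 100.05)
  expect_equal(sum(h$percent_by_weight_raw), 100, tolerance = 1e-9)
})

test_that("kernels outside 1-10 mm land in a flagged overflow row", {
  g <- data.frame(length_mm = c(6.5, 11.2), width_mm = c(2, 2))
  a <- assess_kernels(g, c(0.02, 0.05), 4.8)
  h <- build_histogram(a)
  expect_true(attr(h, "has_overflow"))
  expect_equal(h$count[h$range == "overflow"], 1)
  expect_equal(sum(h$count), 2)
})

test_that("summarize aggregates a single kernel correctly", {
  g <- data.frame(length_mm = 6, width_mm = 2)
  a <- assess_kernels(g, 0.02, 4.8)
  rep <- summarize_sample(a)
  expect_equal(rep$total_grains, 1)
  expect_equal(rep$agl_mm, 6)
  expect_equal(rep$agw_mm, 2)
  expect_equal(rep$total_weight_g, 0.02)
  expect_equal(rep$whole_count, 1)
  expect_equal(rep$broken_count, 0)
  for (f in c("yellow", "chalky", "damaged", "paddy")) {
    expect_equal(rep$features[[f]]$count, 0)
  }
})

test_that("feature ratios follow the flags", {
  set.seed(34)
  n <- 60
  g <- data.frame(length_mm = runif(n, 5.5, 7), width_mm = runif(n, 1.8, 2.2))
  flags <- rep(c(TRUE, FALSE), c(12, n - 12))  # exactly 20% damaged
  a <- assess_kernels(g, weight_law(g$length_mm, g$width_mm), 4.8,
                      is_damaged = flags)
  rep <- summarize_sample(a)
  expect_equal(rep$features$damaged$count / rep$total_grains, 0.20)
})

test_that("broken percent-by-weight matches a brute-force sum", {
  a <- random_assessments(80, seed = 35)
  rep <- summarize_sample(a)
  s <- 0
  for (i in seq_len(nrow(a))) {
    if (a$is_broken[i]) s <- s + a$predicted_weight_g[i]
  }
  expect_equal(rep$features$broken$percent_by_weight,
               100 * s / sum(a$predicted_weight_g))
})

test_that("report invariants hold over random samples", {
  for (seed in 1:50) {
    n <- sample(5:120, 1)
    a <- random_assessments(n, seed = seed)
    rep <- summarize_sample(a)
    expect_equal(rep$whole_count + rep$broken_count, rep$total_grains)
    expect_equal(sum(rep$histogram$count), rep$total_grains)
    expect_equal(sum(rep$histogram$percent_by_weight_raw), 100,
                 tolerance = 1e-9)
    # head rice is a subset of unbroken kernels
    expect_true(all(!(a$is_head_rice & a$is_broken)))
  }
})

test_that("raising the broken threshold never decreases broken_count", {
  set.seed(36)
  g <- data.frame(length_mm = runif(100, 2, 8), width_mm = 2)
  w <- weight_law(g$length_mm, 2)
  prev <- -1
  for (thr in seq(2, 9, by = 0.5)) {
    a <- assess_kernels(g, w, thr)
    cnt <- sum(a$is_broken)
    expect_gte(cnt, prev)
    prev <- cnt
  }
})

test_that("percent-by-weight shares are invariant to weight rescaling", {
  a <- random_assessments(50, seed = 37)
  rep1 <- summarize_sample(a)
  a2 <- a
  a2$predicted_weight_g <- a$predicted_weight_g * 7.3
  rep2 <- summarize_sample(a2)
  expect_equal(rep1$histogram$percent_by_weight_raw,
               rep2$histogram$percent_by_weight_raw)
  expect_equal(rep1$features$broken$percent_by_weight,
               rep2$features$broken$percent_by_weight)
})

test_that("reports are written as JSON and CSV", {
  a <- random_assessments(30, seed = 38)
  rep <- summarize_sample(a)
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, json, csv)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$total_grains, 30)
  h <- utils::read.csv(csv)
  expect_equal(sum(h$Count), 30)
  expect_true(file.exists(sub("\\.csv$", "_summary.csv", csv)))
})
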