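test_that("rice-type configs validate and round-trip through YAML", {
  cfg <- default_irri6_config()
  expect_equal(cfg$broken_threshold_mm, 4.8)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_rice_config(cfg, f)
  cfg2 <- read_rice_config(f)
  expect_equal(cfg2$broken_threshold_mm, cfg$broken_threshold_mm)
  expect_equal(cfg2$yellow_range, cfg$yellow_range)

  expect_error(rice_type_config("x", broken_threshold_mm = -1),
               class = "gs_config_error")
  expect_error(rice_type_config("x", 4.8, weight_model_path = "no/such.rds"),
               class = "gs_config_error")
  expect_error(read_rice_config("no/such.yaml"), class = "gs_config_error")
})

test_that("all shipped presets load", {
  preset_dir <- system.file("extdata", "configs", package = "grainscan")
  files <- list.files(preset_dir, pattern = "\\.yaml$", full.names = TRUE)
  expect_length(files, 6)
  for (f in files) {
    cfg <- read_rice_config(f)
    expect_s3_class(cfg, "rice_type_config")
    expect_gt(cfg$broken_threshold_mm, 0)
  }
})

test_that("analyze_scene grades a synthetic sample end to end", {
  wm <- test_weight_model()
  dc <- test_classifier("damaged")
  pc <- test_classifier("paddy")
  sp <- irri6_scene_spec(n = 24, seed = 51, broken_fraction = 0.2)
  r <- render_scene(sp)
  out <- withr::local_tempdir()
  run <- analyze_scene(r$image, default_irri6_config(), make_profile(12.5),
                       weight_model = wm, damaged_classifier = dc,
                       paddy_classifier = pc, out_dir = out)
  expect_equal(run$report$total_grains, 24)
  expect_equal(run$report$whole_count + run$report$broken_count, 24)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "report.csv")))
  expect_true(file.exists(file.path(out, "overlay.png")))

  ev <- evaluate_run(run, r$manifest)
  expect_equal(ev$count_error, 0)
  expect_lt(ev$length_mae_mm, 0.13)
  expect_equal(ev$flag_confusion$broken$accuracy, 100)

  # deterministic: identical inputs give a byte-identical report
  out2 <- withr::local_tempdir()
  analyze_scene(r$image, default_irri6_config(), make_profile(12.5),
                weight_model = wm, damaged_classifier = dc,
                paddy_classifier = pc, out_dir = out2)
  expect_identical(readBin(file.path(out, "report.json"), "raw", 1e6),
                   readBin(file.path(out2, "report.json"), "raw", 1e6))
})

test_that("an empty scene warns and yields no report", {
  blank <- array(15 / 255, dim = c(200, 150, 3))
  expect_warning(
    run <- analyze_scene(blank, default_irri6_config(), make_profile(12.5),
                         weight_model = test_weight_model()),
    "empty sample")
  expect_null(run$report)
  expect_error(evaluate_run(run, data.frame()), class = "gs_invalid_input")
})

test_that("a missing weight model is a config error", {
  blank <- array(0, dim = c(50, 50, 3))
  expect_error(
    analyze_scene(blank, default_irri6_config(), make_profile(12.5)),
    class = "gs_config_error")
})

test_that("a mis-set ppm halves every measurement", {
  wm <- test_weight_model()
  sp <- irri6_scene_spec(n = 12, seed = 52)
  r <- render_scene(sp)
  run <- analyze_scene(r$image, default_irri6_config(),
                       make_profile(25),  # double the true scale
                       weight_model = wm, min_area_px = 12.5^2)
  ev <- evaluate_run(run, r$manifest)
  expect_equal(ev$length_mae_mm, mean(r$manifest$length_mm) / 2,
               tolerance = 0.1)
})

test_that("oversized contours are excluded and counted", {
  wm <- test_weight_model()
  # two collinear kernels rendered end to end merge into one long blob
  sp <- scene_spec(list(
    kernel_spec(7.5, 2.2, 0, c(60, 60)),
    kernel_spec(7.5, 2.2, 0, c(150, 60)),
    kernel_spec(6.4, 2.0, 90, c(200, 140))
  ), ppm = 12.5, width_px = 300, height_px = 200, seed = 4)
  r <- render_scene(sp)
  cfg <- default_irri6_config()
  cfg$sanity_length_mm <- 10
  run <- analyze_scene(r$image, cfg, make_profile(12.5), weight_model = wm)
  expect_equal(run$oversized_excluded, 1)
  expect_equal(run$report$total_grains, 1)
})
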