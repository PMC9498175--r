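test_that("hsv_range validates bounds and rejects hue wraparound", {
  r <- hsv_range(c(20, 80, 80), c(35, 255, 255))
  expect_s3_class(r, "hsv_range")
  expect_error(hsv_range(c(170, 0, 0), c(10, 255, 255)),
               class = "gs_invalid_input")  # wraparound
  expect_error(hsv_range(c(-1, 0, 0), c(10, 255, 255)),
               class = "gs_invalid_input")
  expect_error(hsv_range(c(0, 0, 0), c(200, 255, 255)),
               class = "gs_invalid_input")
  expect_error(hsv_range(c(0, 0, 0), c(179, 300, 255)),
               class = "gs_invalid_input")
})

test_that("mask_fraction counts in-range pixels over the mask", {
  yellow_rgb <- c(204, 173, 61) / 255
  img <- array(rep(yellow_rgb, each = 100), dim = c(10, 10, 3))
  mask <- matrix(TRUE, 10, 10)
  expect_equal(mask_fraction(img, mask, default_yellow_range()), 1)

  white <- array(1, dim = c(10, 10, 3))
  expect_equal(mask_fraction(white, mask, default_yellow_range()), 0)

  # half in-range, half out
  img2 <- img
  img2[1:5, , ] <- 1
  expect_equal(mask_fraction(img2, mask, default_yellow_range()), 0.5,
               tolerance = 1 / 100)

  expect_error(mask_fraction(img, matrix(FALSE, 10, 10),
                             default_yellow_range()),
               class = "gs_invalid_input")
  expect_error(mask_fraction(img, matrix(TRUE, 5, 5),
                             default_yellow_range()),
               class = "gs_invalid_input")
})

test_that("mask_fraction is monotone under range enlargement", {
  set.seed(77)
  img <- array(runif(20 * 20 * 3), dim = c(20, 20, 3))
  mask <- matrix(runif(400) < 0.6, 20, 20)
  full <- hsv_range(c(0, 0, 0), c(179, 255, 255))
  expect_equal(mask_fraction(img, mask, full), 1)
  for (i in 1:25) {
    lo <- c(runif(1, 0, 120), runif(1, 0, 180), runif(1, 0, 180))
    hi <- lo + c(runif(1, 5, 50), runif(1, 10, 70), runif(1, 10, 70))
    hi <- pmin(hi, c(179, 255, 255))
    inner <- hsv_range(lo, hi)
    grow <- hsv_range(pmax(lo - c(5, 15, 15), 0),
                      pmin(hi + c(5, 15, 15), c(179, 255, 255)))
    expect_gte(mask_fraction(img, mask, grow),
               mask_fraction(img, mask, inner))
  }
})

test_that("chalk patches are scored at their painted area fraction", {
  r <- single_kernel_scene(6.4, 2.0, rotation = 20,
                           paint_class = "chalky_patch",
                           patch_fraction = 0.40, seed = 8)
  seg <- segment_scene(grain_scene(r$image, make_profile(12.5)))
  mask <- kernel_core_mask(seg$labels == seg$contours[[1]]$label)
  sc <- score_kernel_color(r$image, mask)
  expect_equal(sc$chalky_fraction, 0.40, tolerance = 0.02 / 0.40)
  expect_true(sc$is_chalky)
  expect_false(sc$is_yellow)

  # threshold monotonicity: same kernel, stricter flag threshold
  sc2 <- score_kernel_color(r$image, mask, chalky_flag_threshold = 0.5)
  expect_false(sc2$is_chalky)
})

test_that("fully yellow kernels are flagged and white ones are not", {
  ry <- single_kernel_scene(paint_class = "yellow", seed = 3)
  segy <- segment_scene(grain_scene(ry$image, make_profile(12.5)))
  masky <- kernel_core_mask(segy$labels == segy$contours[[1]]$label)
  scy <- score_kernel_color(ry$image, masky)
  expect_gt(scy$yellow_fraction, 0.95)
  expect_true(scy$is_yellow)
  expect_false(scy$is_chalky)

  rp <- single_kernel_scene(paint_class = "plain", seed = 3)
  segp <- segment_scene(grain_scene(rp$image, make_profile(12.5)))
  maskp <- kernel_core_mask(segp$labels == segp$contours[[1]]$label)
  scp <- score_kernel_color(rp$image, maskp)
  expect_false(scp$is_yellow)
  expect_false(scp$is_chalky)

  expect_error(score_kernel_color(ry$image, masky, yellow_flag_threshold = 0),
               class = "gs_invalid_input")
})
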