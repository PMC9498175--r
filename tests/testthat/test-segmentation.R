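test_that("preprocess binarises bright kernels on a dark background", {
  black <- array(0, dim = c(60, 40, 3))
  expect_true(all(preprocess(black) == 0))
  expect_error(preprocess(black, smooth_ks = 4), class = "gs_invalid_input")
  expect_error(preprocess(black, smooth_ks = 1), class = "gs_invalid_input")

  sp <- irri6_scene_spec(n = 10, seed = 31)
  r <- render_scene(sp)
  bin <- preprocess(r$image)
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  expect_equal(max(lab), 10)
})

test_that("segmentation is robust to additive sensor noise", {
  sp <- irri6_scene_spec(n = 10, seed = 32)
  sp$background_noise_sd <- 5
  r <- render_scene(sp)
  bin <- preprocess(r$image)
  ks <- find_kernels(bin, min_area_px = 12.5^2)
  expect_length(ks, 10)
})

test_that("find_kernels returns boxed contours and filters specks", {
  expect_length(find_kernels(matrix(0L, 50, 50), 10), 0)

  bin <- matrix(0L, 100, 60)
  bin[26:75, 21:40] <- 1L  # 50 x 20 px rectangle
  bin[5:6, 5:6] <- 1L      # 4 px speck
  ks <- find_kernels(bin, min_area_px = 50)
  expect_length(ks, 1)
  co <- ks[[1]]$box_corners
  expect_equal(pt_dist_test(co[1, ], co[2, ]), 50, tolerance = 1 / 50)
  expect_equal(pt_dist_test(co[2, ], co[3, ]), 20, tolerance = 1 / 20)
  # corner order: top-left first, then clockwise
  expect_true(co[1, 1] < co[2, 1] && co[1, 2] < co[4, 2])
  # midpoints are corner means
  expect_equal(ks[[1]]$edge_midpoints[1, ], (co[1, ] + co[2, ]) / 2)
  expect_equal(ks[[1]]$edge_midpoints[3, ], (co[3, ] + co[4, ]) / 2)
})

test_that("an axis-aligned rectangle measures exactly", {
  bin <- matrix(0L, 100, 60)
  bin[26:75, 21:40] <- 1L
  ks <- find_kernels(bin, 50)
  g <- measure_kernel(ks[[1]], make_profile(10))
  expect_equal(g$length_mm, 5.0)
  expect_equal(g$width_mm, 2.0)
})

test_that("measurement is rotation-invariant within tolerance", {
  prof <- make_profile(12.5)
  for (rot in c(0, 30, 45, 77)) {
    r <- single_kernel_scene(6.4, 2.0, rotation = rot)
    seg <- segment_scene(grain_scene(r$image, prof))
    expect_equal(nrow(seg$geometry), 1)
    expect_equal(seg$geometry$length_mm, 6.4, tolerance = 0.02)
    expect_equal(seg$geometry$width_mm, 2.0, tolerance = 0.02)
  }
})

test_that("a 6.4 mm kernel at ppm 12.5 measures within 2%", {
  r <- single_kernel_scene(6.4, 2.0, rotation = 25, seed = 9)
  seg <- segment_scene(grain_scene(r$image, make_profile(12.5)))
  expect_equal(seg$geometry$length_mm, 6.4, tolerance = 0.13 / 6.4)
})

test_that("doubling the render and profile scale leaves mm unchanged", {
  res <- lapply(c(12.5, 25), function(ppm) {
    r <- single_kernel_scene(6.4, 2.0, rotation = 33, ppm = ppm, seed = 4)
    segment_scene(grain_scene(r$image, make_profile(ppm)))$geometry
  })
  expect_equal(res[[1]]$length_mm, res[[2]]$length_mm, tolerance = 0.01)
  expect_equal(res[[1]]$width_mm, res[[2]]$width_mm, tolerance = 0.01)
})

test_that("every rendered kernel is recovered exactly once", {
  for (seed in c(41, 42)) {
    sp <- irri6_scene_spec(n = 24, seed = seed)
    r <- render_scene(sp)
    seg <- segment_scene(grain_scene(r$image, make_profile(12.5)))
    expect_equal(nrow(seg$geometry), nrow(r$manifest))
    expect_true(all(seg$geometry$length_mm >= seg$geometry$width_mm))
  }
})

test_that("degenerate contours are rejected", {
  contour <- structure(
    list(points = cbind(c(0, 1, 2), c(0, 0, 0)), area_px = 3,
         box_corners = rbind(c(0, 0), c(2, 0), c(2, 0), c(0, 0)),
         edge_midpoints = rbind(c(1, 0), c(2, 0), c(1, 0), c(0, 0)),
         centroid = c(1, 0), label = 1L),
    class = "kernel_contour")
  expect_error(measure_kernel(contour, make_profile(10)),
               class = "gs_degenerate_kernel")
})

test_that("min_area_rect finds the enclosing box of rotated points", {
  set.seed(21)
  for (ang in c(10, 40, 65)) {
    th <- ang * pi / 180
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
    # dense points filling a 40 x 12 rotated rectangle
    g <- expand.grid(a = seq(-20, 20, by = 0.5), b = seq(-6, 6, by = 0.5))
    pts <- cbind(100 + g$a * u[1] + g$b * v[1], 100 + g$a * u[2] + g$b * v[2])
    rect <- min_area_rect(pts)
    dims <- sort(c(rect$width, rect$height))
    expect_equal(dims[1], 13, tolerance = 0.01)  # 12 + 1 px footprint
    expect_equal(dims[2], 41, tolerance = 0.01)
  }
  expect_error(min_area_rect(rbind(c(0, 0), c(1, 1))),
               class = "gs_invalid_input")
})
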