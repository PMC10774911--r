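test_that("grid geometry derives the super-resolution and synthesis pitches", {
  g <- grid_spec()
  expect_equal(g$superres_pixel, 20)
  expect_equal(g$synthesis_pixel, 6)
  expect_equal(g$wavelength / g$superres_pixel, 14)
  expect_equal(grid_area_mm2(g), 23.04)
  expect_error(grid_spec(superres_factor = 0), "factors")
})

test_that("pixel convention is half-open with centers at (i - 0.5) pitch", {
  expect_equal(um_to_pixel(0, 60), 1L)
  expect_equal(um_to_pixel(59.999, 60), 1L)
  expect_equal(um_to_pixel(60, 60), 2L)     # boundary goes to the next pixel
  expect_equal(pixel_center_um(1, 60), 30)
})

test_that("bicubic resampling is exact at identity and reproduces smooth fields", {
  img <- outer(1:20, 1:20, function(i, j) exp(-((i - 10)^2 + (j - 11)^2) / 18))
  expect_equal(resample_bicubic(img, 20, 20), img, tolerance = 1e-12)
  up <- resample_bicubic(img, 100, 100)
  down <- resample_bicubic(up, 20, 20)
  expect_lt(max(abs(down - img)), 0.01)
})

test_that("gaussian blur preserves mass direction and handles sigma 0", {
  img <- matrix(0, 15, 15); img[8, 8] <- 1
  expect_identical(gaussian_blur(img, 0), img)
  b <- gaussian_blur(img, 1)
  expect_equal(which.max(b), which.max(img))
  expect_equal(sum(b), 1, tolerance = 1e-9)
})
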