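test_that("frame synthesis honors the delta-identity and empty contracts", {
  g <- test_grid()
  psf <- test_psf(g)
  expect_identical(synthesize_frame(bubbles(), psf, NULL, g)$frame,
                   matrix(0, 40, 40))
  # one unit bubble at a native pixel center reproduces the downsampled PSF
  pos <- pixel_center_um(20, g$native_pixel)
  fr <- synthesize_frame(bubbles(pos, pos, 1), psf, NULL, g)$frame
  expect_equal(max(fr), 1, tolerance = 0.03)
  pk <- which(fr == max(fr), arr.ind = TRUE)
  expect_equal(as.integer(pk[1, ]), c(20L, 20L))
  expect_error(synthesize_frame(bubbles(1e6, 0), psf, NULL, g),
               "inside the field")
})

test_that("synthesis is linear before clipping", {
  g <- test_grid()
  psf <- test_psf(g)
  b1 <- bubbles(800, 700, 0.4)
  b2 <- bubbles(1600, 1700, 0.4)
  f1 <- synthesize_frame(b1, psf, NULL, g)$frame
  f2 <- synthesize_frame(b2, psf, NULL, g)$frame
  f12 <- synthesize_frame(dplyr::bind_rows(b1, b2), psf, NULL, g)$frame
  expect_lt(max(abs(f12 - pmin(f1 + f2, 1))), 1e-6)
})

test_that("truth centers are conserved in count and round-trip through maps", {
  g <- test_grid()
  set.seed(5)
  b <- random_bubbles(0.8, g)
  m <- make_center_map(b, g, "superres")
  expect_equal(sum(m > 0), nrow(b))       # no collisions at this density
  # recovered pixel centers within one super-resolution pixel of truth
  idx <- which(m > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(b))) {
    d <- sqrt((pixel_center_um(idx[, 1], 20) - b$depth_um[k])^2 +
                (pixel_center_um(idx[, 2], 20) - b$lateral_um[k])^2)
    expect_lt(min(d), 20)
  }
})

test_that("reference maps blur isolated centers to unit-peak blobs", {
  g <- test_grid()
  ref <- make_reference_map(bubbles(1200, 1200), g)
  expect_equal(max(ref), 1)
  expect_equal(sum(ref == 1), 1)           # unique unit peak
  expect_equal(sum(ref > 0), 25)           # 5 x 5 blob support
  # two distant centers produce two identical unit-peak blobs
  ref2 <- make_reference_map(bubbles(c(600, 1800), c(600, 1800)), g)
  expect_equal(sum(ref2 == 1), 2)
  expect_error(make_reference_map(bubbles(-5, 100), g), "outside")
})

test_that("centers on pixel boundaries follow the half-open floor convention", {
  g <- test_grid()
  # 1200 um is exactly the boundary between super-resolution pixels 60 and 61
  m <- make_center_map(bubbles(1200, 1200), g, "superres")
  idx <- which(m > 0, arr.ind = TRUE)
  expect_identical(as.integer(idx), c(61L, 61L))
  m2 <- make_center_map(bubbles(1200 - 1e-9, 1200 - 1e-9), g, "superres")
  expect_identical(as.integer(which(m2 > 0, arr.ind = TRUE)), c(60L, 60L))
})
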