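test_that("deconvolution inverts a noise-free delta to one sparse cluster", {
  g <- test_grid()
  psf <- test_psf(g)
  fr <- synthesize_frame(bubbles(1210, 1190, 1), psf, NULL, g)
  x <- deconvolve_frame(fr$frame, psf, bd_config())
  expect_true(all(x >= 0))
  expect_gt(mean(x == 0), 0.95)
  d <- bd_extract_centers(x, g)
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$depth_um - 1210)^2 + (d$lateral_um - 1190)^2), 16.8)
})

test_that("an all-zero frame deconvolves to an all-zero map", {
  g <- test_grid()
  psf <- test_psf(g)
  x <- deconvolve_frame(matrix(0, 40, 40), psf, bd_config())
  expect_identical(max(x), 0)
  expect_equal(nrow(bd_extract_centers(x, g)), 0)
})

test_that("kernels larger than the frame are rejected", {
  g <- test_grid()
  psf <- test_psf(g)
  expect_error(deconvolve_frame(matrix(0.5, 10, 10), psf,
                                bd_config(kernel_size = 31)), "larger")
})

test_that("bubbles separated by more than one FWHM resolve to two clusters", {
  g <- test_grid()
  psf <- test_psf(g)   # lateral FWHM 450
  fr <- synthesize_frame(bubbles(c(1200, 1200), c(900, 1500), c(0.9, 0.8)),
                         psf, NULL, g)
  d <- bd_extract_centers(deconvolve_frame(fr$frame, psf, bd_config()), g)
  expect_equal(nrow(d), 2)
})

test_that("PSF estimation recovers a known kernel from noise-free frames", {
  g <- test_grid()
  psf <- test_psf(g)
  set.seed(21)
  frames <- lapply(1:6, function(i) {
    b <- random_bubbles(0.7, g)
    while (nrow(b) == 0) b <- random_bubbles(0.7, g)
    synthesize_frame(b, psf, NULL, g)$frame
  })
  est <- estimate_psf_window(frames, bd_config(), g)
  expect_gte(psf_quality(psf, est), 0.95)
})

test_that("the blind-deconvolution objective is non-increasing over iterations", {
  frames <- lapply(test_scene_frames(4), `[[`, "frame")
  est <- estimate_psf_window(frames, bd_config(max_outer = 5), test_grid())
  trace <- attr(est, "objective")
  expect_gte(length(trace), 2)
  expect_true(all(diff(trace) <= 1e-9))
})

test_that("a mirror-symmetric scene yields a mirror-symmetric kernel estimate", {
  g <- test_grid()
  psf <- make_psf(420, 420, 0, grid = g)   # isotropic, so exactly symmetric
  pos <- pixel_center_um(20, g$native_pixel)
  fr <- synthesize_frame(bubbles(pos, pos, 1), psf, NULL, g)$frame
  est <- estimate_psf_window(list(fr), bd_config(max_outer = 3), g)
  k <- est$kernel_native
  expect_lt(max(abs(k - k[rev(seq_len(nrow(k))), ])), 0.05)
  expect_lt(max(abs(k - k[, rev(seq_len(ncol(k)))])), 0.05)
})

test_that("windows without signal are rejected", {
  expect_error(estimate_psf_window(list(matrix(0.01, 40, 40)),
                                   bd_config(), test_grid()),
               "no signal")
})

test_that("solver support matches exhaustive search on small noise-free scenes", {
  # 16 x 16 toy: compare the recovered support with brute-force search over
  # single-scatterer positions (amplitude solved in closed form)
  g <- grid_spec(window = 16)
  psf <- make_psf(300, 250, 0, grid = g)
  cfg <- bd_config(kernel_size = 15)
  kern <- ulmkit:::crop_kernel(psf$kernel_native, 15)
  shifted <- function(i, j) {
    big <- matrix(0, 16, 16); big[i, j] <- 1
    ulmkit:::fft_conv2_same(big, kern)
  }
  set.seed(31)
  for (trial in 1:3) {
    pos <- sample(5:12, 2)
    y <- synthesize_frame(bubbles(pixel_center_um(pos[1], 60),
                                  pixel_center_um(pos[2], 60), 1),
                          psf, NULL, g)$frame
    # brute force over all 256 positions
    best <- c(Inf, 0, 0)
    for (i in 1:16) for (j in 1:16) {
      tmpl <- shifted(i, j)
      a <- sum(tmpl * y) / sum(tmpl^2)
      r <- sum((y - a * tmpl)^2)
      if (r < best[1]) best <- c(r, i, j)
    }
    x <- deconvolve_frame(y, psf, cfg)
    pk <- which(x == max(x), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(pk - best[2:3])), 1)
  }
})

test_that("integer-pixel translation of the frame translates the centers", {
  g <- test_grid()
  psf <- test_psf(g)
  fr <- synthesize_frame(bubbles(1200, 1200, 1), psf, NULL, g)$frame
  sh <- rbind(matrix(0, 3, 40), fr[1:37, ])   # shift 3 native px in depth
  d0 <- bd_extract_centers(deconvolve_frame(fr, psf, bd_config()), g)
  d1 <- bd_extract_centers(deconvolve_frame(sh, psf, bd_config()), g)
  expect_equal(d1$depth_um - d0$depth_um, 180, tolerance = 6)
  expect_equal(d1$lateral_um - d0$lateral_um, 0, tolerance = 6)
})
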