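test_that("localization error reproduces the hand-computed cases", {
  expect_error(localization_error(bubbles(), bubbles(0, 0)), "empty truth")
  r0 <- localization_error(bubbles(0, 0), bubbles(0, 0), gate = 50)
  expect_equal(r0$E_c_um, 0)
  expect_equal(r0$eta_pct, 0)
  # two truths, one detection: unmatched truth contributes its distance
  r1 <- localization_error(bubbles(c(0, 0), c(0, 100)), bubbles(0, 0),
                           gate = 50)
  expect_equal(r1$E_c_um, 50)
  # false pair: both detections contribute, eta counts the surplus
  r2 <- localization_error(bubbles(0, 0), bubbles(c(0, 0), c(-10, 10)),
                           gate = 50)
  expect_equal(r2$E_c_um, 10)
  expect_equal(r2$eta_pct, 50)
})

test_that("localization error is translation invariant and scales with dilation", {
  set.seed(41)
  tr <- bubbles(runif(6, 0, 2000), runif(6, 0, 2000))
  det <- bubbles(tr$depth_um + rnorm(6, 0, 15),
                 tr$lateral_um + rnorm(6, 0, 15))
  base <- localization_error(tr, det, gate = 100)$E_c_um
  shift <- localization_error(
    bubbles(tr$depth_um + 500, tr$lateral_um - 300),
    bubbles(det$depth_um + 500, det$lateral_um - 300),
    gate = 100)$E_c_um
  expect_equal(base, shift, tolerance = 1e-12)
  dil <- localization_error(
    bubbles(2 * tr$depth_um, 2 * tr$lateral_um),
    bubbles(2 * det$depth_um, 2 * det$lateral_um), gate = 200)$E_c_um
  expect_equal(dil, 2 * base, tolerance = 1e-12)
})

test_that("normalized separation follows the FWHM along the connecting line", {
  psf <- make_psf(400, 400)
  expect_equal(normalized_separation(c(0, 0), c(0, 400), psf), 1,
               tolerance = 0.01)
  expect_equal(normalized_separation(c(0, 0), c(0, 200), psf), 0.5,
               tolerance = 0.01)
  el <- make_psf(500, 276)
  d_major <- normalized_separation(c(0, 0), c(0, 200), el)
  d_minor <- normalized_separation(c(0, 0), c(200, 0), el)
  expect_gt(d_minor, d_major)     # same distance, shorter FWHM across
  expect_error(normalized_separation(c(1, 1), c(1, 1), psf), "coincident")
})

test_that("separation statistics bin trials with binomial intervals", {
  trials <- tibble::tibble(D_star = c(0.25, 0.32, 0.55, 0.61, 1.4),
                           separated = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  st <- separation_stats(trials, breaks = seq(0, 2, 0.5))
  expect_equal(st$pct_unseparated[1], 100)
  expect_equal(st$pct_unseparated[2], 0)
  expect_equal(st$n[4], 0)
  expect_true(is.na(st$pct_unseparated[4]))
  allsep <- separation_stats(tibble::tibble(D_star = runif(50, 0, 2),
                                            separated = TRUE))
  expect_true(all(allsep$pct_unseparated[allsep$n > 0] == 0))
})

test_that("PSF quality is correlation-based and offset invariant", {
  psf <- test_psf()
  expect_equal(psf_quality(psf, psf), 1)
  off <- psf
  off$kernel_native <- pmin(psf$kernel_native + 0.2, 1e9)
  expect_equal(psf_quality(psf, off), 1, tolerance = 1e-12)
  flat <- psf
  flat$kernel_native <- matrix(1, 11, 11)
  expect_error(psf_quality(psf, flat), "constant")
})

test_that("gradient channel has the highest SNR on speckle-noise frames", {
  g <- test_grid()
  psf <- test_psf(g)
  set.seed(51)
  b <- random_bubbles(0.8, g)
  clean <- synthesize_frame(b, psf, NULL, g)$frame
  noisy <- pmin(clean + make_noise(noise_spec(0.16), dim(clean)), 1)
  s <- snr_channels(clean, noisy)
  expect_false(any(s$infinite))
  expect_gt(s$snr[s$channel == "gradient"],
            s$snr[s$channel == "intensity"])
  # identical images flag infinite SNR
  s0 <- snr_channels(clean, clean)
  expect_true(all(s0$infinite))
  # doubling the noise roughly halves the intensity SNR
  n1 <- make_noise(noise_spec(0.08), dim(clean))
  a <- snr_channels(clean, clean + n1)$snr[1]
  b2 <- snr_channels(clean, clean + 2 * n1)$snr[1]
  expect_equal(a / b2, 2, tolerance = 1e-9)
})
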