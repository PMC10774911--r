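test_that("isotropic PSF has AR 1 and the analytic half-max disk area", {
  psf <- make_psf(400, 400)
  expect_equal(psf$AR, 1)
  expect_equal(psf$S, pi * 200^2, tolerance = 0.01)
  # analytic area within 2 synthesis pixels' worth of the numeric support
  expect_lt(abs(psf$S - pi * 200^2), 2 * 6 * 2 * pi * 200)
  expect_equal(max(psf$kernel_native), 1)
  expect_equal(max(psf$kernel_hi), 1)
})

test_that("anisotropic PSF reproduces the quoted aspect ratio", {
  psf <- make_psf(500, 276)
  expect_equal(psf$AR, 500 / 276, tolerance = 1e-6)
  expect_equal(psf$AR, 1.81, tolerance = 0.005)
  expect_equal(psf_fwhm_length(psf, 0), 500, tolerance = 0.01)
  expect_equal(psf_fwhm_length(psf, 90), 276, tolerance = 0.01)
})

test_that("rotating a PSF by 90 degrees swaps the axis FWHM lengths", {
  p0 <- make_psf(480, 260, orientation = 0)
  p90 <- make_psf(480, 260, orientation = 90)
  expect_equal(psf_fwhm_length(p0, 0), psf_fwhm_length(p90, 90),
               tolerance = 0.01)
  expect_equal(psf_fwhm_length(p0, 90), psf_fwhm_length(p90, 0),
               tolerance = 0.01)
})

test_that("unresolvable kernels are rejected", {
  expect_error(make_psf(100, 100), "unresolvable")
})

test_that("resampling error is zero at factor one and small for smooth kernels", {
  psf <- make_psf(400, 400)
  expect_identical(psf_resampling_error(psf, factor = 1L), 0)
  expect_lt(psf_resampling_error(psf), 0.05)
  tails <- make_psf(400, 300, family = "gaussian_with_tails")
  expect_lt(psf_resampling_error(tails), 0.05)
  zero <- psf
  zero$kernel_native <- matrix(0, 5, 5)
  expect_error(psf_resampling_error(zero), "zero")
})

test_that("empirical kernels recover their FWHM geometry", {
  g <- test_grid()
  psf <- make_psf(450, 300, 0, grid = g)
  emp <- psf_from_kernel(psf$kernel_native, g)
  expect_equal(emp$fwhm_major, 450, tolerance = 0.05)
  expect_equal(emp$AR, 1.5, tolerance = 0.08)
})
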