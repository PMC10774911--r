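test_that("training pairs respect the documented parameter ranges", {
  g <- test_grid()
  ds <- build_training_set(10, psf_pool = training_psf_pool(g), grid = g,
                           psf_variants = 10, seed = 5)
  expect_length(ds$inputs, 10)
  expect_equal(dim(ds$inputs[[1]]), c(40, 40))
  expect_equal(dim(ds$refs[[1]]), c(120, 120))
  expect_true(all(ds$meta$concentration >= 0.1 &
                    ds$meta$concentration <= 1.0))
  expect_true(all(ds$meta$noise_peak %in% c(0.10, 0.15, 0.20, 0.25)))
  expect_true(all(ds$psf_meta$rotation >= -20 & ds$psf_meta$rotation <= 20))
  expect_true(all(ds$psf_meta$resize >= 0.8 & ds$psf_meta$resize <= 2))
  expect_true(all(vapply(ds$inputs, function(m)
    min(m) >= 0 && max(m) <= 1, logical(1))))
})

test_that("training sets are bit-identical under a fixed seed", {
  g <- test_grid()
  pool <- training_psf_pool(g)[1:2]
  a <- build_training_set(5, pool, g, psf_variants = 4, seed = 77)
  b <- build_training_set(5, pool, g, psf_variants = 4, seed = 77)
  expect_identical(a$inputs, b$inputs)
  expect_identical(a$refs, b$refs)
  expect_identical(a$meta, b$meta)
})

test_that("sampled concentrations are approximately uniform", {
  g <- test_grid()
  ds <- build_training_set(600, psf_pool = training_psf_pool(g)[1], grid = g,
                           psf_variants = 4, seed = 12)
  h <- table(cut(ds$meta$concentration, seq(0.1, 1.0, length.out = 7)))
  expect_gt(stats::chisq.test(h)$p.value, 0.01)
})

test_that("an empty PSF pool is rejected", {
  expect_error(build_training_set(3, list(), test_grid()), "empty PSF pool")
})
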