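test_that("line scenarios advect bubbles at the prescribed speed", {
  g <- test_grid()
  psf <- test_psf(g)
  sc <- line_scenario(120, steps = 40, arrival_rate = 0.5)
  scene <- simulate_lines(sc, psf, NULL, g, seed = 3, render = FALSE)
  tr <- scene$truth
  expect_gt(nrow(tr), 0)
  # per-step displacement 5 mm/s / 48 fps = 104.17 um
  one <- tr[tr$id == tr$id[which.max(table(tr$id))][1], ]
  one <- dplyr::arrange(one, .data$frame)
  if (nrow(one) >= 2) {
    d <- sqrt(diff(one$depth_um)^2 + diff(one$lateral_um)^2) /
      diff(one$frame)
    expect_equal(mean(d), 5000 / 48, tolerance = 1e-6)
  }
  # truth lies exactly on two lines D_l apart (horizontal lines: depth)
  depths <- sort(unique(round(tr$depth_um, 6)))
  expect_length(depths, 2)
  expect_equal(diff(depths), 120)
})

test_that("zero arrival rate produces pure-noise frames", {
  g <- test_grid()
  psf <- test_psf(g)
  sc <- line_scenario(60, steps = 5, arrival_rate = 0)
  scene <- simulate_lines(sc, psf, noise_spec(0.1), g, seed = 1)
  expect_equal(nrow(scene$truth), 0)
  expect_true(all(vapply(scene$frames, max, numeric(1)) <= 0.1 + 1e-12))
})

test_that("vessel bubbles follow the parabolic speed profile", {
  g <- test_grid()
  psf <- test_psf(g)
  sc <- vessel_scenario(240, steps = 60)
  expect_equal(vessel_u_ref(0, sc), 5e4)          # 5 cm/s at the center
  expect_equal(vessel_u_ref(240, sc), 0)          # zero at the wall
  scene <- simulate_vessel(sc, psf, NULL, g, seed = 8, render = FALSE)
  tr <- scene$truth
  # measured per-frame displacement matches U_ref(r) for a tracked bubble
  ids <- names(which(table(tr$id) >= 10))
  one <- dplyr::arrange(tr[tr$id == as.integer(ids[1]), ], .data$frame)
  sp <- sqrt(diff(one$depth_um)^2 + diff(one$lateral_um)^2) /
    (diff(one$frame) * g$frame_interval)
  expect_equal(mean(sp), vessel_u_ref(one$r_um[1], sc), tolerance = 1e-6)
  expect_error(simulate_vessel(vessel_scenario(30), psf, NULL, g),
               "radius")
})

test_that("vessel seeding maintains the prescribed mean along-axis spacing", {
  g <- grid_spec(window = 80)
  psf <- make_psf(300, 250, 0, grid = g)
  sc <- vessel_scenario(360, steps = 120, mean_spacing = 330)
  scene <- simulate_vessel(sc, psf, NULL, g, seed = 9, render = FALSE)
  ext <- grid_extent_um(g)
  sp <- scene$truth |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarize(gap = if (dplyr::n() > 1)
      mean(diff(sort(.data$lateral_um))) else NA_real_)
  expect_equal(mean(sp$gap, na.rm = TRUE), 330, tolerance = 0.12)
})

test_that("scenario generators are deterministic under a seed", {
  g <- test_grid()
  psf <- test_psf(g)
  a <- simulate_lines(line_scenario(60, steps = 12), psf, noise_spec(0.1),
                      g, seed = 11)
  b <- simulate_lines(line_scenario(60, steps = 12), psf, noise_spec(0.1),
                      g, seed = 11)
  expect_identical(a$truth, b$truth)
  expect_identical(a$frames, b$frames)
})
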