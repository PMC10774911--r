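test_that("track heatmaps count distinct traversals", {
  g <- test_grid()
  trk <- tibble::tibble(track = 1L, frame = 1:5, depth_um = 1200,
                        lateral_um = seq(300, 2100, length.out = 5),
                        interpolated = FALSE, status = "active")
  hm <- track_heatmap(trk, g)
  occ <- which(hm > 0, arr.ind = TRUE)
  expect_equal(length(unique(occ[, 1])), 1)      # one-pixel-wide line
  expect_true(all(hm[occ] == 1))
  two <- dplyr::bind_rows(trk, dplyr::mutate(trk, track = 2L))
  hm2 <- track_heatmap(two, g)
  expect_true(all(hm2[occ] == 2))                # same path doubles counts
  expect_identical(track_heatmap(trk[0, ], g), matrix(0, 120, 120))
})

test_that("a sum of two exact Gaussians is recovered with E_l = 0", {
  pos <- (1:240 - 0.5) * 20
  val <- 0.8 * exp(-(pos - 2340)^2 / (2 * 30^2)) +
    exp(-(pos - 2460)^2 / (2 * 30^2))
  fit <- line_profile_fit(tibble::tibble(pos_um = pos, value = val),
                          true_positions = c(2340, 2460))
  expect_true(fit$converged)
  expect_equal(nrow(fit$components), 2)
  expect_equal(fit$components$mu_um, c(2340, 2460), tolerance = 0.01)
  expect_equal(fit$components$eps_l_um, c(60, 60), tolerance = 0.01)
  expect_equal(fit$components$E_l_um, c(0, 0), tolerance = 0.01)
  expect_equal(glance(fit)$r_squared, 1, tolerance = 1e-6)
  # single peak falls back to a one-component fit
  one <- line_profile_fit(tibble::tibble(
    pos_um = pos, value = exp(-(pos - 2400)^2 / (2 * 50^2))))
  expect_equal(nrow(one$components), 1)
})

test_that("area fractions sum to 100 and split evenly for twin lines", {
  g <- test_grid()
  pos <- (1:120 - 0.5) * 20
  val <- exp(-(pos - 1000)^2 / (2 * 40^2)) +
    exp(-(pos - 1500)^2 / (2 * 40^2))
  hm <- matrix(rep(val, 120), 120, 120)   # continuous identical lines
  fit <- line_profile_fit(tibble::tibble(pos_um = pos, value = val))
  feats <- ghost_features(fit, hm, g)
  expect_equal(sum(feats$AF), 100, tolerance = 0.1)
  expect_equal(feats$AF, c(50, 50), tolerance = 0.5)
  # single line owns all the area
  fit1 <- line_profile_fit(tibble::tibble(
    pos_um = pos, value = exp(-(pos - 1200)^2 / (2 * 40^2))))
  f1 <- ghost_features(fit1, hm, g)
  expect_equal(f1$AF, 100)
})

test_that("continuity raises the index of detection", {
  g <- test_grid()
  pos <- (1:120 - 0.5) * 20
  val <- exp(-(pos - 1000)^2 / (2 * 40^2)) +
    exp(-(pos - 1500)^2 / (2 * 40^2))
  hm <- matrix(0, 120, 120)
  r1 <- um_to_pixel(1000, 20); r2 <- um_to_pixel(1500, 20)
  set.seed(4)
  hm[r1, ] <- 2 + runif(120, 0, 0.2)    # continuous line, slight texture
  hm[r2, seq(1, 120, by = 4)] <- 8      # intermittent, same mean
  fit <- line_profile_fit(tibble::tibble(pos_um = pos, value = val))
  feats <- ghost_features(fit, hm, g)
  expect_gt(feats$ID[1], feats$ID[2])
})

test_that("the ghost decision rule reproduces its arithmetic cases", {
  c1 <- classify_ghost(10, 50)
  expect_equal(c1$score, -1.74, tolerance = 1e-9)
  expect_equal(c1$class, "negligible")
  c2 <- classify_ghost(30, 60)
  expect_equal(c2$score, 0.64, tolerance = 1e-9)
  expect_equal(c2$class, "nonnegligible")
  # exact zero lands on the nonnegligible side by convention
  AF0 <- 10; ID0 <- (4.64 - 0.10 * AF0) / 0.038
  expect_equal(classify_ghost(AF0, ID0)$class, "nonnegligible")
})

test_that("a refit maximum-margin boundary separates labeled line sets", {
  set.seed(71)
  pts <- dplyr::bind_rows(
    tibble::tibble(AF = runif(25, 5, 20), ID = runif(25, 10, 40),
                   ghost = FALSE),
    tibble::tibble(AF = runif(25, 40, 70), ID = runif(25, 60, 95),
                   ghost = TRUE))
  bd <- fit_ghost_boundary(pts)
  pred <- bd$w[1] * pts$AF + bd$w[2] * pts$ID + bd$b > 0
  expect_equal(sum(pred != pts$ghost), 0)
  expect_error(fit_ghost_boundary(pts[pts$ghost, ]), "both classes")
  # boundary normal recovered within 5 degrees on a constructed margin
  set.seed(72)
  w_true <- c(1, 1) / sqrt(2)
  z <- tibble::tibble(AF = runif(80, 0, 100), ID = runif(80, 0, 100))
  s <- w_true[1] * z$AF + w_true[2] * z$ID - 70
  z <- z[abs(s) > 8, ]; s <- s[abs(s) > 8]
  bd2 <- fit_ghost_boundary(dplyr::mutate(z, ghost = s > 0))
  ang <- acos(sum(bd2$w * w_true) / sqrt(sum(bd2$w^2))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("five-way separation classification follows the trough rules", {
  pos <- (1:240 - 0.5) * 20
  two <- function(sep, sig) {
    exp(-(pos - (2400 - sep / 2))^2 / (2 * sig^2)) +
      exp(-(pos - (2400 + sep / 2))^2 / (2 * sig^2))
  }
  # nearly merged: trough above 95% of the primary peak
  v1 <- two(70, 60)
  f1 <- line_profile_fit(tibble::tibble(pos_um = pos, value = v1))
  expect_equal(classify_separation(f1), "unseparated")
  # clear separation with deep trough
  v2 <- two(800, 60)
  f2 <- line_profile_fit(tibble::tibble(pos_um = pos, value = v2))
  expect_equal(classify_separation(f2), "fully_separated")
  # intermediate overlap
  v3 <- two(250, 80)
  f3 <- line_profile_fit(tibble::tibble(pos_um = pos, value = v3))
  expect_equal(classify_separation(f3), "overlapped")
  # three peaks with a strong middle ghost -> judged by the decision rule
  g <- test_grid()
  v4 <- two(1600, 100) + 0.9 * exp(-(pos - 2400)^2 / (2 * 100^2))
  hm <- matrix(rep(v4, 120), 240, 120)
  f4 <- line_profile_fit(tibble::tibble(pos_um = pos, value = v4))
  expect_equal(classify_separation(f4, hm, g), "nonnegligible_ghost")
  v5 <- two(1600, 100) + 0.04 * exp(-(pos - 2400)^2 / (2 * 60^2))
  hm5 <- matrix(rep(v5, 120), 240, 120)
  hm5[um_to_pixel(2400, 20), ] <- hm5[um_to_pixel(2400, 20), ] *
    rep(c(1, 0), 60)                     # intermittent ghost
  f5 <- line_profile_fit(tibble::tibble(pos_um = pos, value = v5),
                         n_peaks = 3)
  if (nrow(f5$components) == 3)
    expect_equal(classify_separation(f5, hm5, g), "negligible_ghost")
})

test_that("exact parabolic tracks give zero velocity error and exact radius", {
  g <- grid_spec(window = 80)
  psf <- make_psf(263, 263 / 1.2, 0, grid = g)
  sc <- vessel_scenario(360, steps = 150)
  scene <- simulate_vessel(sc, psf, NULL, g, seed = 81, render = FALSE)
  # perfect detections = truth; tracker follows each bubble
  det <- scene$truth[, c("frame", "depth_um", "lateral_um", "intensity")]
  tr <- build_tracks(det, tracker_config(gate = 1300, gate_locked = 80))
  vp <- velocity_profile(tr, sc, psf, g)
  core <- vp[vp$n > 10 & abs(vp$r_um) < 0.8 * sc$R, ]
  expect_lt(max(core$E_u, na.rm = TRUE), 0.05)
  est <- estimate_radius(vp$r_um[vp$n > 0], vp$U_m[vp$n > 0],
                         "velocity_parabola", R_true = sc$R)
  expect_lt(est$E_r, 0.05)
  # exact parabola input recovers R exactly
  r <- seq(-340, 340, by = 20)
  ex <- estimate_radius(r, 5e4 * (1 - (r / 360)^2), "velocity_parabola",
                        R_true = 360)
  expect_equal(ex$R_m_um, 360, tolerance = 1e-6)
  expect_equal(ex$E_r, 0)
  expect_error(estimate_radius(r, 1e4 * (1 + (r / 360)^2),
                               "velocity_parabola"), "concave-up")
})

test_that("velocity-error proxy matches jittered-truth Monte Carlo", {
  g <- grid_spec(window = 80)
  psf <- make_psf(263, 263 / 1.2, 0, grid = g)
  sc <- vessel_scenario(360, steps = 150)
  scene <- simulate_vessel(sc, psf, NULL, g, seed = 82, render = FALSE)
  E_c <- 15
  set.seed(83)
  det <- scene$truth
  det$depth_um <- det$depth_um + rnorm(nrow(det), 0, E_c / sqrt(2))
  det$lateral_um <- det$lateral_um + rnorm(nrow(det), 0, E_c / sqrt(2))
  det <- det[det$depth_um > 0 & det$lateral_um > 0, ]
  tr <- build_tracks(det[, c("frame", "depth_um", "lateral_um", "intensity")],
                     tracker_config(gate = 1300, gate_locked = 80))
  vp <- velocity_profile(tr, sc, psf, g, bin_width = 40, E_c = E_c)
  mid <- vp[vp$n > 30 & abs(vp$r_um) > 0.3 * sc$R &
              abs(vp$r_um) < 0.85 * sc$R, ]
  # same order of magnitude as the gradient-based proxy over the bins where
  # the gradient dominates
  expect_gt(stats::cor(mid$E_u, mid$proxy), 0)
  expect_lt(median(mid$E_u / mid$proxy), 8)
  expect_gt(median(mid$E_u / mid$proxy), 1 / 8)
})

test_that("power-law fits recover exact exponents", {
  pf <- power_law_fit(1:10, 2 * (1:10)^3)
  expect_equal(pf$coefficient, 2, tolerance = 1e-9)
  expect_equal(pf$exponent, 3, tolerance = 1e-9)
  expect_equal(pf$r_squared, 1, tolerance = 1e-9)
  # log-space fit equals a direct nonlinear fit on noise-free data
  x <- seq(0.5, 4, by = 0.25); y <- 1.7 * x^2.4
  nl <- minpack.lm::nlsLM(y ~ a * x^b, start = list(a = 1, b = 1))
  pf2 <- power_law_fit(x, y)
  expect_equal(pf2$coefficient, coef(nl)[["a"]], tolerance = 1e-6)
  expect_equal(pf2$exponent, coef(nl)[["b"]], tolerance = 1e-6)
  flat <- power_law_fit(1:10, rep(2, 10))
  expect_equal(flat$exponent, 0, tolerance = 1e-9)
  expect_error(power_law_fit(c(-1, 2), c(1, 2)), "positive")
})
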