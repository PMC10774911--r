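test_that("the localizer triples resolution with squashed outputs", {
  net <- build_supbd(supbd_spec(channels = 4, n_res = 2), seed = 1)
  out <- nn_forward(net, matrix(runif(40 * 40), 40))$out
  expect_equal(dim(out), c(120, 120))
  expect_true(all(out > 0 & out < 1))
})

test_that("layer audit shows 9x9 heads and 3x3 interiors", {
  net <- build_supbd(supbd_spec(channels = 4), seed = 1)
  audit <- supbd_layer_audit(net)
  expect_equal(audit$kernel[audit$layer == "h1c"], 9)
  expect_equal(audit$kernel[audit$layer == "outc"], 9)
  inner <- audit$kernel[!audit$layer %in% c("h1c", "outc")]
  expect_true(all(inner == 3))
  expect_error(supbd_spec(upscale = 2), "upscale")
  # k-net variant: 7x7 everywhere, no upscale, no squashing
  kn <- build_supbd(knet_spec(channels = 4), seed = 1)
  ka <- supbd_layer_audit(kn)
  expect_true(all(ka$kernel == 7))
  kout <- nn_forward(kn, matrix(runif(25 * 25), 25))$out
  expect_equal(dim(kout), c(25, 25))
})

test_that("analytic gradients match finite differences", {
  set.seed(2)
  net <- build_supbd(supbd_spec(channels = 3, n_res = 1, k_first = 5,
                                k_inner = 3, k_last = 5), seed = 2)
  x <- matrix(runif(64), 8)
  ref <- matrix(runif(24 * 24), 24)
  lossf <- function(n) mean((nn_forward(n, x)$out - ref)^2)
  fw <- nn_forward(net, x, keep_cache = TRUE)
  gr <- nn_backward(net, fw$cache, 2 * (fw$out - ref) / length(ref))
  eps <- 1e-3
  probe <- list(
    list(get = function(p) p$h1c$W,
         set = function(p, v) { p$h1c$W[] <- v; p },
         g = gr$h1c$W),
    list(get = function(p) p$res$res1$c1$W,
         set = function(p, v) { p$res$res1$c1$W[] <- v; p },
         g = gr$res$res1$c1$W),
    list(get = function(p) p$upn$gamma,
         set = function(p, v) { p$upn$gamma[] <- v; p },
         g = gr$upn$gamma))
  for (pr in probe) {
    p0 <- pr$get(net$params)
    i <- which.max(abs(pr$g))     # probe the strongest component
    n2 <- net; v <- p0; v[i] <- v[i] + eps; n2$params <- pr$set(n2$params, v)
    l1 <- lossf(n2)
    n2 <- net; v <- p0; v[i] <- v[i] - eps; n2$params <- pr$set(n2$params, v)
    l0 <- lossf(n2)
    expect_equal((l1 - l0) / (2 * eps), pr$g[i], tolerance = 0.02)
  }
})

test_that("a small model can memorize a small training set", {
  g <- grid_spec(window = 16)
  ds <- build_training_set(60, psf_pool = training_psf_pool(g)[2:4],
                           grid = g, conc_range = c(0.5, 1),
                           resize_range = c(0.8, 1.2), psf_variants = 6,
                           seed = 15)
  net <- build_supbd(supbd_spec(channels = 6, n_res = 2), seed = 5)
  fit <- train_supbd(net, ds, sup_train_config(minibatch = 8,
                                               max_epochs = 6, seed = 6,
                                               peak_weight = 10))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.1 * h$train_loss[1])
  expect_equal(fit$best_epoch, which.min(h$val_loss))
})

test_that("training histories are reproducible under a fixed seed", {
  g <- grid_spec(window = 16)
  ds <- build_training_set(20, psf_pool = training_psf_pool(g)[3],
                           grid = g, psf_variants = 4, seed = 25)
  f1 <- train_supbd(build_supbd(supbd_spec(channels = 4, n_res = 1),
                                seed = 7), ds,
                    sup_train_config(minibatch = 4, max_epochs = 3,
                                     seed = 8))
  f2 <- train_supbd(build_supbd(supbd_spec(channels = 4, n_res = 1),
                                seed = 7), ds,
                    sup_train_config(minibatch = 4, max_epochs = 3,
                                     seed = 8))
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
})

test_that("early stopping triggers after the stated patience", {
  g <- grid_spec(window = 16)
  ds <- build_training_set(16, psf_pool = training_psf_pool(g)[3],
                           grid = g, psf_variants = 2, seed = 35)
  # zero learning rate: validation can never improve after epoch 1
  fit <- train_supbd(build_supbd(supbd_spec(channels = 3, n_res = 1),
                                 seed = 9), ds,
                     sup_train_config(minibatch = 4, lr = 0,
                                      max_epochs = 30, patience = 5,
                                      seed = 10))
  expect_equal(nrow(fit$history), 6)   # epoch 1 best + 5 stalled epochs
})

test_that("likelihood-map centroids recover sub-pixel blob positions", {
  g <- test_grid()
  # synthetic blob at a known sub-pixel position on the 20-um grid
  truth <- c(1234, 987)
  px <- (1:120 - 0.5) * 20
  m <- outer(exp(-(px - truth[1])^2 / (2 * 30^2)),
             exp(-(px - truth[2])^2 / (2 * 30^2)))
  d <- net_extract_centers(m, g, min_peak = 0.5)
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$depth_um - truth[1])^2 + (d$lateral_um - truth[2])^2),
            20)
  expect_equal(nrow(net_extract_centers(matrix(0, 120, 120), g)), 0)
  # two blobs three super-resolution pixels apart stay distinct
  m2 <- matrix(0, 120, 120)
  m2[60, 60] <- 0.9; m2[60, 63] <- 0.8
  expect_equal(nrow(net_extract_centers(m2, g)), 2)
})
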