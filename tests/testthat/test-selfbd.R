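# small operator context shared across the self-supervised loss tests
self_test_ctx <- function() fixture("self_ctx_12", function()
  self_ctx(grid_spec(window = 12)))

test_that("reconstruction loss vanishes exactly at a perfect model", {
  ctx <- self_test_ctx()
  w <- self_weights()
  set.seed(91)
  x <- matrix(0, ctx$ns, ctx$ns); x[sample(ctx$ns^2, 4)] <- runif(4, 0.6, 1)
  k <- ulmkit:::knet_input_disk(ctx$nk, 3)
  rec <- ulmkit:::self_reconstruct(x, k, ctx)
  expect_equal(self_loss_y(x, k, rec$y_hat, w, ctx)$loss, 0,
               tolerance = 1e-18)
  # quadratic form: doubling the residual quadruples the loss
  l1 <- self_loss_y(x, k, rec$y_hat + 0.03, w, ctx)$loss
  l2 <- self_loss_y(x, k, rec$y_hat + 0.06, w, ctx)$loss
  expect_equal(l2 / l1, 4, tolerance = 1e-9)
  expect_error(self_loss_y(x[-1, ], k, rec$y_hat, w, ctx), "shape")
})

test_that("loss gradients match finite differences through the full chain", {
  ctx <- self_test_ctx()
  w <- self_weights()
  set.seed(92)
  x <- matrix(0, ctx$ns, ctx$ns); x[sample(ctx$ns^2, 3)] <- 0.8
  k <- ulmkit:::knet_input_disk(ctx$nk, 3)
  y <- matrix(runif(ctx$nw^2, 0, 0.3), ctx$nw)
  L <- self_loss_y(x, k, y, w, ctx, grad = "both")
  eps <- 1e-6
  for (i in sample(length(k), 2)) {
    k2 <- k; k2[i] <- k[i] + eps
    l1 <- self_loss_y(x, k2, y, w, ctx)$loss
    k2[i] <- k[i] - eps
    l0 <- self_loss_y(x, k2, y, w, ctx)$loss
    expect_equal((l1 - l0) / (2 * eps), L$grad_k[i], tolerance = 1e-4)
  }
  for (i in sample(length(x), 2)) {
    x2 <- x; x2[i] <- x[i] + eps
    l1 <- self_loss_y(x2, k, y, w, ctx)$loss
    x2[i] <- x[i] - eps
    l0 <- self_loss_y(x2, k, y, w, ctx)$loss
    expect_equal((l1 - l0) / (2 * eps), L$grad_x[i], tolerance = 1e-4)
  }
})

test_that("the tanh surrogate approximates the support count", {
  w <- self_weights()
  expect_equal(reg_x(matrix(0, 10, 10), w)$loss, 0)
  # a unit pixel contributes ~alpha4 plus its four nonzero forward
  # differences times alpha5
  xs <- matrix(0, 8, 8); xs[4, 4] <- 1
  expect_equal(reg_x(xs, w)$loss,
               w$alpha4 * tanh(5) + 4 * w$alpha5 * tanh(5),
               tolerance = 1e-12)
  # surrogate bound: ||tanh(5x)||_1 <= nnz, near equality for values >= 1
  set.seed(93)
  xb <- matrix(0, 30, 30); xb[sample(900, 40)] <- runif(40, 1, 2)
  s1 <- sum(abs(tanh(5 * xb)))
  expect_lte(s1, sum(xb != 0))
  expect_gt(s1 / sum(xb != 0), 0.999)
})

test_that("the kernel energy penalty is an exact quadratic", {
  w <- self_weights()
  expect_equal(reg_k(matrix(0, 5, 5), w)$loss, 0)
  k <- matrix(runif(25), 5)
  expect_equal(reg_k(3 * k, w)$loss, 9 * reg_k(k, w)$loss,
               tolerance = 1e-12)
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  expect_equal(reg_k(imp, w)$loss, 2)     # gamma = 2 on a unit impulse
})

test_that("sparsification keeps only the brightest super-threshold peak per cluster", {
  m <- matrix(0, 10, 10)
  m[4, 4] <- 0.9; m[4, 5] <- 0.7          # one cluster, two peaks
  m[8, 8] <- 0.3                          # below threshold
  s <- sparsify_detections(m)
  expect_equal(sum(s > 0), 1)
  expect_equal(s[4, 4], 0.9)
  expect_identical(sparsify_detections(matrix(0.4, 6, 6)),
                   matrix(0, 6, 6))
  # exact tie within one 8-connected cluster: first in row-major scan
  # order wins (row 2 precedes row 3)
  t2 <- matrix(0, 6, 6); t2[3, 3] <- 0.8; t2[2, 4] <- 0.8
  st <- sparsify_detections(t2)
  expect_equal(sum(st > 0), 1)
  expect_gt(st[2, 4], 0)
})

test_that("loss decomposition terms are finite and nonnegative", {
  ctx <- self_test_ctx()
  w <- self_weights()
  set.seed(94)
  x <- matrix(0, ctx$ns, ctx$ns); x[sample(ctx$ns^2, 3)] <- 0.8
  k <- ulmkit:::knet_input_disk(ctx$nk, 4)
  y <- matrix(runif(ctx$nw^2, 0, 0.5), ctx$nw)
  ly <- self_loss_y(x, k, y, w, ctx)$loss
  lk <- ly + reg_k(k, w)$loss
  lx <- ly + reg_x(x, w)$loss
  expect_true(is.finite(lk) && lk >= ly)
  expect_true(is.finite(lx) && lx >= ly)
})

test_that("k-net adaptation is a fixed point when the truth is the input disk", {
  g <- grid_spec(window = 12)
  ctx <- self_ctx(g)
  disk <- ulmkit:::knet_input_disk(ctx$nk, 5)
  psf_disk <- psf_from_kernel(disk, g, upsample = TRUE)
  set.seed(95)
  frames <- list(); truths <- list()
  for (i in 1:8) {
    b <- bubbles(runif(1, 200, 500), runif(1, 200, 500), 1)
    frames[[i]] <- synthesize_frame(b, psf_disk, NULL, g)$frame
    truths[[i]] <- b
  }
  # oracle localizer: unit peaks at the true super-resolution pixels
  oracle_x <- function(fr) {
    i <- which(vapply(frames, function(f) identical(f, fr), logical(1)))
    make_center_map(truths[[i]], g, "superres")
  }
  ad <- adapt_knet(frames, oracle_x, knet = build_supbd(
    knet_spec(channels = 6), seed = 12), grid = g, ctx = ctx,
    max_iter = 12, seed = 13)
  expect_gt(psf_quality(psf_from_kernel(disk, g), ad$psf), 0.97)
})

test_that("adaptation demands frames and detections", {
  g <- grid_spec(window = 12)
  expect_error(adapt_knet(list(matrix(0, 12, 12)), function(fr) fr,
                          grid = g), "at least")
  frames <- replicate(8, matrix(0, 12, 12), simplify = FALSE)
  expect_error(adapt_knet(frames, function(fr) matrix(0, 36, 36),
                          grid = g, seed = 1), "no detections")
  expect_error(refine_xnet(frames, matrix(1, 13, 13),
                           build_supbd(supbd_spec(channels = 3,
                                                  n_res = 1), seed = 1),
                           grid = g), "fewer than 16")
})
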