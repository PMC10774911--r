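# Compact convolutional-network engine for the residual-learning
# localizers. Convolutions run through Rcpp/BLAS (im2col + GEMM); instance
# normalization, leaky rectifier, sigmoid, zero-stuffed x3 upsampling, and
# Adam are implemented here with explicit backward passes. Everything is
# single-sample (fully convolutional); minibatches accumulate gradients.

# ---- parameter containers ---------------------------------------------------

he_conv <- function(cin, cout, k, gain = 2) {
  sd <- sqrt(gain / (cin * k * k))
  list(type = "conv", k = as.integer(k), p = (as.integer(k) - 1L) %/% 2L,
       cin = cin, cout = cout,
       W = matrix(stats::rnorm(cout * cin * k * k, sd = sd), cout),
       b = rep(0, cout))
}

new_inorm <- function(C) list(type = "inorm", gamma = rep(1, C),
                              beta = rep(0, C))

#' Localizer network architecture specification
#'
#' The supervised localizer maps a native-resolution window to a x3
#' super-resolution center-likelihood map: two convolution blocks
#' (conv + instance norm + leaky rectifier), `n_res` residual blocks, a
#' global residual addition, a stride-3 transposed convolution, and a final
#' convolution squashed to (0, 1). The PSF-estimation variant
#' ([knet_spec()]) uses 3 residual blocks, 7 x 7 kernels throughout, no
#' upscaling and no squashing.
#'
#' @param channels Feature channels (64 in the full-scale configuration;
#'   scaled-down studies use fewer).
#' @param n_res Number of residual blocks (default 4).
#' @param k_first,k_inner,k_last Kernel sizes: 9 for the first and last
#'   convolution layers, 3 elsewhere (including the transposed
#'   convolution).
#' @param upscale Output upscale factor; the default heads require 3
#'   (or 1 for the no-upscale variant).
#' @param squash Apply the final sigmoid (default TRUE).
#' @param leaky Negative-slope of the leaky rectifier (default 0.2).
#' @return A `supbd_spec` list.
#' @export
supbd_spec <- function(channels = 64L, n_res = 4L, k_first = 9L,
                       k_inner = 3L, k_last = 9L, upscale = 3L,
                       squash = TRUE, leaky = 0.2) {
  if (!upscale %in% c(1L, 3L))
    stop("upscale must be 3 (default heads) or 1 (no-upscale variant)")
  structure(list(channels = as.integer(channels), n_res = as.integer(n_res),
                 k_first = as.integer(k_first), k_inner = as.integer(k_inner),
                 k_last = as.integer(k_last), upscale = as.integer(upscale),
                 squash = squash, leaky = leaky),
            class = "supbd_spec")
}

#' @rdname supbd_spec
#' @export
knet_spec <- function(channels = 32L, n_res = 3L) {
  sp <- supbd_spec(channels = channels, n_res = n_res, k_first = 7L,
                   k_inner = 7L, k_last = 7L, upscale = 1L, squash = FALSE)
  class(sp) <- c("knet_spec", class(sp))
  sp
}

#' Build a localizer network
#'
#' @param spec A [supbd_spec()] or [knet_spec()].
#' @param seed Optional seed for weight initialization.
#' @return An `ulm_net` with the parameter tree and the spec.
#' @export
build_supbd <- function(spec = supbd_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Fc <- spec$channels
  params <- list(
    h1c = he_conv(1L, Fc, spec$k_first), h1n = new_inorm(Fc),
    h2c = he_conv(Fc, Fc, spec$k_inner), h2n = new_inorm(Fc),
    res = stats::setNames(
      lapply(seq_len(spec$n_res), function(i)
        list(c1 = he_conv(Fc, Fc, spec$k_inner), n1 = new_inorm(Fc),
             c2 = he_conv(Fc, Fc, spec$k_inner), n2 = new_inorm(Fc))),
      paste0("res", seq_len(spec$n_res))),
    upc = he_conv(Fc, Fc, spec$k_inner), upn = new_inorm(Fc),
    outc = he_conv(Fc, 1L, spec$k_last))
  # the PSF-estimation variant adds its output to the input disk, so a
  # zero-initialized head makes the untrained net the identity on the disk
  if (inherits(spec, "knet_spec")) params$outc$W[] <- 0
  structure(list(spec = spec, params = params), class = "ulm_net")
}

#' @export
print.ulm_net <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, integer(1)))
  cat(sprintf(
    "<ulm_net> %d channels, %d res blocks, kernels %d/%d/%d, upscale x%d%s (%d parameters)\n",
    x$spec$channels, x$spec$n_res, x$spec$k_first, x$spec$k_inner,
    x$spec$k_last, x$spec$upscale,
    if (x$spec$squash) ", sigmoid" else "", np))
  invisible(x)
}

# ---- primitive forward/backward --------------------------------------------

conv_f <- function(ly, x) {
  list(out = nn_conv_fwd(x, ly$W, ly$b, ly$k, ly$p), cache = x)
}

conv_b <- function(ly, cache, dout, need_dx = TRUE) {
  r <- nn_conv_bwd(cache, dout, ly$W, ly$k, ly$p, need_dx)
  list(dx = if (need_dx) r$dx else NULL,
       grads = list(W = r$dW, b = as.numeric(r$db)))
}

inorm_f <- function(ly, x, eps = 1e-5) {
  C <- dim(x)[3]
  m <- v <- numeric(C)
  xhat <- x
  for (c in seq_len(C)) {
    s <- x[, , c]
    m[c] <- mean(s)
    v[c] <- mean((s - m[c])^2)
    xhat[, , c] <- (s - m[c]) / sqrt(v[c] + eps)
  }
  out <- xhat
  for (c in seq_len(C)) out[, , c] <- ly$gamma[c] * xhat[, , c] + ly$beta[c]
  list(out = out, cache = list(xhat = xhat, v = v, eps = eps))
}

inorm_b <- function(ly, cache, dout) {
  C <- dim(dout)[3]
  dx <- dout
  dg <- db <- numeric(C)
  for (c in seq_len(C)) {
    xh <- cache$xhat[, , c]
    dy <- dout[, , c]
    dg[c] <- sum(dy * xh)
    db[c] <- sum(dy)
    dxh <- dy * ly$gamma[c]
    dx[, , c] <- (dxh - mean(dxh) - xh * mean(dxh * xh)) /
      sqrt(cache$v[c] + cache$eps)
  }
  list(dx = dx, grads = list(gamma = dg, beta = db))
}

lrelu_f <- function(x, a) {
  neg <- x < 0
  x[neg] <- a * x[neg]
  list(out = x, cache = neg)
}

lrelu_b <- function(cache, dout, a) {
  dout[cache] <- a * dout[cache]
  dout
}

sigmoid_f <- function(x) 1 / (1 + exp(-x))

# zero-stuffed x3 upsampling: input pixel (i, j) lands at (3i - 1, 3j - 1),
# the center of its 3 x 3 output cell
stuff3_f <- function(x) {
  d <- dim(x)
  out <- array(0, c(3L * d[1], 3L * d[2], d[3]))
  out[3L * seq_len(d[1]) - 1L, 3L * seq_len(d[2]) - 1L, ] <- x
  out
}

stuff3_b <- function(dout, d_in) {
  dout[3L * seq_len(d_in[1]) - 1L, 3L * seq_len(d_in[2]) - 1L, , drop = FALSE]
}

# ---- network forward/backward ----------------------------------------------

as_input <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

#' Localizer forward pass
#'
#' @param net An `ulm_net`.
#' @param x Input matrix (or H x W x 1 array) at native resolution.
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @return List with `out` (matrix, upscaled when the spec upscales) and
#'   `cache` (or `NULL`).
#' @export
nn_forward <- function(net, x, keep_cache = FALSE) {
  sp <- net$spec
  pm <- net$params
  a <- sp$leaky
  cc <- list()
  x <- as_input(x)
  s1 <- conv_f(pm$h1c, x);   cc$h1c <- s1$cache
  s2 <- inorm_f(pm$h1n, s1$out); cc$h1n <- s2$cache
  s3 <- lrelu_f(s2$out, a);  cc$h1r <- s3$cache
  s4 <- conv_f(pm$h2c, s3$out); cc$h2c <- s4$cache
  s5 <- inorm_f(pm$h2n, s4$out); cc$h2n <- s5$cache
  s6 <- lrelu_f(s5$out, a);  cc$h2r <- s6$cache
  h2 <- s6$out                       # global residual anchor
  h <- h2
  cc$res <- vector("list", sp$n_res)
  for (i in seq_len(sp$n_res)) {
    r <- pm$res[[i]]
    rc <- list()
    t1 <- conv_f(r$c1, h);      rc$c1 <- t1$cache
    t2 <- inorm_f(r$n1, t1$out); rc$n1 <- t2$cache
    t3 <- lrelu_f(t2$out, a);   rc$r1 <- t3$cache
    t4 <- conv_f(r$c2, t3$out); rc$c2 <- t4$cache
    t5 <- inorm_f(r$n2, t4$out); rc$n2 <- t5$cache
    h <- h + t5$out
    cc$res[[i]] <- rc
  }
  g <- h + h2                        # global residual addition
  cc$dim_g <- dim(g)
  if (sp$upscale == 3L) {
    gs <- stuff3_f(g)
    u1 <- conv_f(pm$upc, gs); cc$upc <- u1$cache
  } else {
    u1 <- conv_f(pm$upc, g);  cc$upc <- u1$cache
  }
  u2 <- inorm_f(pm$upn, u1$out); cc$upn <- u2$cache
  u3 <- lrelu_f(u2$out, a);  cc$upr <- u3$cache
  o1 <- conv_f(pm$outc, u3$out); cc$outc <- o1$cache
  out <- o1$out[, , 1]
  if (sp$squash) {
    out <- sigmoid_f(out)
    cc$sig <- out
  }
  list(out = out, cache = if (keep_cache) cc else NULL)
}

#' Localizer backward pass
#'
#' @param net An `ulm_net`.
#' @param cache Cache from [nn_forward()] with `keep_cache = TRUE`.
#' @param dout Gradient of the loss with respect to the output map.
#' @param head_only Only differentiate the layers after the global residual
#'   addition (transposed convolution onward), as used when refining the
#'   x-net.
#' @return List of gradients mirroring `net$params` (head-only entries when
#'   requested).
#' @export
nn_backward <- function(net, cache, dout, head_only = FALSE) {
  sp <- net$spec
  pm <- net$params
  a <- sp$leaky
  if (sp$squash) {
    s <- cache$sig
    dout <- dout * s * (1 - s)
  }
  dout <- array(dout, c(dim(dout), 1L))
  bo <- conv_b(pm$outc, cache$outc, dout, need_dx = TRUE)
  d <- lrelu_b(cache$upr, bo$dx, a)
  bn <- inorm_b(pm$upn, cache$upn, d)
  bu <- conv_b(pm$upc, cache$upc, bn$dx, need_dx = !head_only)
  grads <- list(outc = bo$grads, upn = bn$grads, upc = bu$grads)
  if (head_only) return(grads)
  dg <- if (sp$upscale == 3L) stuff3_b(bu$dx, cache$dim_g) else bu$dx
  dh2_global <- dg            # branch into the global skip
  dh <- dg
  res_grads <- vector("list", sp$n_res)
  for (i in rev(seq_len(sp$n_res))) {
    r <- pm$res[[i]]
    rc <- cache$res[[i]]
    bn2 <- inorm_b(r$n2, rc$n2, dh)
    bc2 <- conv_b(r$c2, rc$c2, bn2$dx)
    dr <- lrelu_b(rc$r1, bc2$dx, a)
    bn1 <- inorm_b(r$n1, rc$n1, dr)
    bc1 <- conv_b(r$c1, rc$c1, bn1$dx)
    res_grads[[i]] <- list(c1 = bc1$grads, n1 = bn1$grads,
                           c2 = bc2$grads, n2 = bn2$grads)
    dh <- dh + bc1$dx           # skip connection within the block
  }
  names(res_grads) <- paste0("res", seq_len(sp$n_res))
  dh2 <- dh + dh2_global
  d <- lrelu_b(cache$h2r, dh2, a)
  bn2h <- inorm_b(pm$h2n, cache$h2n, d)
  bc2h <- conv_b(pm$h2c, cache$h2c, bn2h$dx)
  d <- lrelu_b(cache$h1r, bc2h$dx, a)
  bn1h <- inorm_b(pm$h1n, cache$h1n, d)
  bc1h <- conv_b(pm$h1c, cache$h1c, bn1h$dx, need_dx = FALSE)
  c(grads, list(res = res_grads, h2n = bn2h$grads, h2c = bc2h$grads,
                h1n = bn1h$grads, h1c = bc1h$grads))
}

# ---- parameter-tree utilities ----------------------------------------------

# gradient trees are fully named nested lists with numeric leaves; the
# gradient tree's shape (possibly a subtree of the parameters, for
# head-only training) drives all recursions

# accumulate acc + w * g over a gradient tree
grad_axpy <- function(acc, g, w = 1) {
  if (is.numeric(g)) return(if (is.null(acc)) w * g else acc + w * g)
  if (is.null(acc)) acc <- list()
  for (nm in names(g)) acc[[nm]] <- grad_axpy(acc[[nm]], g[[nm]], w)
  acc
}

grad_scale <- function(g, w) {
  if (is.numeric(g)) return(w * g)
  for (nm in names(g)) g[[nm]] <- grad_scale(g[[nm]], w)
  g
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

# one Adam step over the (possibly partial) gradient tree; first/second
# moments live in `state`, keyed by parameter path
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, path = "") {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    key <- paste0(path, nm)
    if (is.numeric(g)) {
      st <- state[[key]]
      if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      state[[key]] <- st
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    } else {
      params[[nm]] <- adam_step(params[[nm]], g, state, lr, t, beta1,
                                beta2, eps, paste0(key, "."))
    }
  }
  params
}
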