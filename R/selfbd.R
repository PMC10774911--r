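# Self-supervised adaptation to unknown PSFs. A k-net deforms a Gaussian
# disk into the local kernel; the losses are built purely from raw frames:
# the reconstruction x (x) k is compared with y in intensity, gradient and
# Hessian channels (weighted so each term has comparable magnitude), plus a
# tanh-based L1 surrogate of the L0 sparsity prior on x and an L2 energy
# penalty on k. All physics operators are linear with exact adjoints, so
# loss gradients flow to either net.

#' Self-supervised loss weights
#'
#' @param alpha1,alpha2,alpha3 Reconstruction-channel weights for
#'   intensity, gradient, and Hessian terms (defaults 1, 5, 25).
#' @param alpha4,alpha5 Sparsity-surrogate weights on `tanh(5x)` and
#'   `tanh(5 grad x)` (defaults 4e-3).
#' @param gamma Kernel energy weight (default 2).
#' @return A `self_weights` list.
#' @export
self_weights <- function(alpha1 = 1, alpha2 = 5, alpha3 = 25,
                         alpha4 = 4e-3, alpha5 = 4e-3, gamma = 2) {
  stopifnot(alpha1 > 0, alpha2 > 0, alpha3 > 0, alpha4 > 0, alpha5 > 0,
            gamma > 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 alpha4 = alpha4, alpha5 = alpha5, gamma = gamma),
            class = "self_weights")
}

# ---- linear operators -------------------------------------------------------

# central-difference operator matrix (n x n), replicate edges (matches
# grad_central)
diff_matrix_central <- function(n) {
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ip <- min(i + 1L, n); im <- max(i - 1L, 1L)
    G[i, ip] <- G[i, ip] + 0.5
    G[i, im] <- G[i, im] - 0.5
  }
  G
}

# second central difference (replicate edges)
diff2_matrix_central <- function(n) {
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ip <- min(i + 1L, n); im <- max(i - 1L, 1L)
    G[i, ip] <- G[i, ip] + 1
    G[i, im] <- G[i, im] + 1
    G[i, i] <- G[i, i] - 2
  }
  G
}

#' Precomputed operator context for the self-supervised losses
#'
#' Bundles the upsample/downsample interpolation matrices, finite-difference
#' operators, and FFT geometry for one window size and kernel grid.
#'
#' @param grid An [grid_spec()]; `grid$window` is the native window side.
#' @param kernel_px Native-pixel side of the kernel grid (odd; default
#'   `grid$window + 1`).
#' @return A `self_ctx` list.
#' @export
self_ctx <- function(grid = grid_spec(), kernel_px = NULL) {
  nw <- grid$window
  ns <- nw * grid$superres_factor
  if (is.null(kernel_px)) kernel_px <- nw + 1L
  nk <- as.integer(kernel_px)
  if (nk %% 2L == 0L) nk <- nk + 1L
  nkh <- nk * grid$superres_factor      # kernel grid at super resolution
  P <- ns + nkh                          # padded FFT side (no wraparound)
  structure(list(
    grid = grid, nw = nw, ns = ns, nk = nk, nkh = nkh, P = P,
    U = bicubic_matrix(nk, nkh),         # kernel upsample
    D = bicubic_matrix(ns, nw),          # reconstruction downsample
    G = diff_matrix_central(nw),
    G2 = diff2_matrix_central(nw)
  ), class = "self_ctx")
}

# place an odd kernel field (n x n) with its center pixel at the origin of a
# P x P periodic domain; returns the OTF
centered_otf <- function(kfield, P) {
  n <- nrow(kfield)
  h <- (n - 1L) %/% 2L
  big <- matrix(0, P, P)
  idx <- ((( -h):(h)) %% P) + 1L
  big[idx, idx] <- kfield
  stats::fft(big)
}

pad_to <- function(img, P) {
  out <- matrix(0, P, P)
  out[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  out
}

# circular 'same' convolution of img with a centered kernel OTF
conv_centered <- function(img, Kotf, P) {
  Z <- real_ifft(stats::fft(pad_to(img, P)) * Kotf)
  Z[seq_len(nrow(img)), seq_len(ncol(img))]
}

# adjoint of conv_centered with respect to the kernel: gather the full
# correlation of x with dZ back onto the kernel grid
conv_kernel_adjoint <- function(x, dZ, nk_field, P) {
  F1 <- Conj(stats::fft(pad_to(x, P)))
  F2 <- stats::fft(pad_to(dZ, P))
  full <- real_ifft(F1 * F2)
  h <- (nk_field - 1L) %/% 2L
  idx <- ((( -h):(h)) %% P) + 1L
  full[idx, idx]
}

# forward reconstruction: y_hat = D ( x_sr (x) upsample(k) ) D^T
# k is the (unit-peak) kernel on the native kernel grid
self_reconstruct <- function(x_sr, k, ctx) {
  k_hi <- ctx$U %*% k %*% t(ctx$U)
  Kotf <- centered_otf(k_hi, ctx$P)
  Z <- conv_centered(x_sr, Kotf, ctx$P)
  list(y_hat = ctx$D %*% Z %*% t(ctx$D), Z = Z, k_hi = k_hi)
}

#' Self-supervised reconstruction loss
#'
#' `L_y = a1 ||r||^2 + a2 ||grad r||^2 + a3 sum ||H r||^2` where
#' `r = D(x (x) k) - y` is the native-resolution reconstruction residual;
#' the Hessian sum runs over all four terms of the 2 x 2 matrix (the mixed
#' term twice). Gradients with respect to the kernel and/or the
#' super-resolution scatter map are exact adjoint chains.
#'
#' @param x_sr Scatter map at super resolution (`ctx$ns` square).
#' @param k Kernel on the native kernel grid (`ctx$nk` square, unit peak).
#' @param y Observed native frame (`ctx$nw` square).
#' @param weights A [self_weights()].
#' @param ctx A [self_ctx()].
#' @param grad `"none"`, `"k"`, `"x"`, or `"both"`.
#' @return List: `loss`, and `grad_k` / `grad_x` as requested.
#' @export
self_loss_y <- function(x_sr, k, y, weights = self_weights(),
                        ctx, grad = "none") {
  if (!all(dim(y) == ctx$nw) || !all(dim(x_sr) == ctx$ns) ||
      !all(dim(k) == ctx$nk))
    stop("shape mismatch with the operator context")
  rec <- self_reconstruct(x_sr, k, ctx)
  r <- rec$y_hat - y
  G <- ctx$G; G2 <- ctx$G2
  gd <- G %*% r; gl <- r %*% t(G)
  hdd <- G2 %*% r; hll <- r %*% t(G2); hdl <- G %*% r %*% t(G)
  loss <- weights$alpha1 * sum(r^2) +
    weights$alpha2 * (sum(gd^2) + sum(gl^2)) +
    weights$alpha3 * (sum(hdd^2) + sum(hll^2) + 2 * sum(hdl^2))
  out <- list(loss = loss)
  if (grad == "none") return(out)
  dr <- 2 * (weights$alpha1 * r +
               weights$alpha2 * (t(G) %*% gd + gl %*% G) +
               weights$alpha3 * (t(G2) %*% hdd + hll %*% G2 +
                                   2 * t(G) %*% hdl %*% G))
  dZ <- t(ctx$D) %*% dr %*% ctx$D
  if (grad %in% c("k", "both")) {
    dk_hi <- conv_kernel_adjoint(x_sr, dZ, ctx$nkh, ctx$P)
    out$grad_k <- t(ctx$U) %*% dk_hi %*% ctx$U
  }
  if (grad %in% c("x", "both")) {
    Kotf <- centered_otf(rec$k_hi, ctx$P)
    dxp <- real_ifft(stats::fft(pad_to(dZ, ctx$P)) * Conj(Kotf))
    out$grad_x <- dxp[seq_len(ctx$ns), seq_len(ctx$ns)]
  }
  out
}

#' Sparsity surrogate on the scatter map
#'
#' `a4 ||tanh(5x)||_1 + a5 ||tanh(5 grad x)||_1` with forward differences;
#' `tanh(5 * 1) = 0.99991`, so each bright pixel contributes about `a4` and
#' the term approximates the count of nonzeros.
#'
#' @param x_sr Nonnegative scatter map.
#' @param weights A [self_weights()].
#' @param grad Also return the gradient.
#' @return List: `loss` (and `grad`).
#' @export
reg_x <- function(x_sr, weights = self_weights(), grad = FALSE) {
  g <- grad_forward(x_sr)
  t0 <- tanh(5 * x_sr)
  td <- tanh(5 * g$d); tl <- tanh(5 * g$l)
  loss <- weights$alpha4 * sum(abs(t0)) +
    weights$alpha5 * (sum(abs(td)) + sum(abs(tl)))
  if (!grad) return(list(loss = loss))
  d0 <- weights$alpha4 * sign(t0) * 5 * (1 - t0^2)
  dd <- weights$alpha5 * sign(td) * 5 * (1 - td^2)
  dl <- weights$alpha5 * sign(tl) * 5 * (1 - tl^2)
  nr <- nrow(x_sr); nc <- ncol(x_sr)
  gback <- d0
  # adjoint of forward differences: scatter -1 at i, +1 at i+1
  gback[-nr, ] <- gback[-nr, ] - dd[-nr, ]
  gback[-1, ] <- gback[-1, ] + dd[-nr, ]
  gback[, -nc] <- gback[, -nc] - dl[, -nc]
  gback[, -1] <- gback[, -1] + dl[, -nc]
  list(loss = loss, grad = gback)
}

#' Kernel energy penalty
#'
#' `gamma ||k||_2^2`.
#'
#' @param k Kernel matrix.
#' @param weights A [self_weights()].
#' @param grad Also return the gradient.
#' @return List: `loss` (and `grad`).
#' @export
reg_k <- function(k, weights = self_weights(), grad = FALSE) {
  out <- list(loss = weights$gamma * sum(k^2))
  if (grad) out$grad <- 2 * weights$gamma * k
  out
}

#' Sparsify a center-likelihood map to brightest peaks
#'
#' Within each cluster of values exceeding `min_peak`, keeps only the
#' brightest pixel (row-major first on exact ties); everything else is
#' zeroed. Clusters are 8-connected components, with components whose
#' peaks lie within `merge_radius` pixels of a brighter peak merged into
#' it: an unfamiliar elongated PSF makes the x-net emit several blobs
#' close to the true center, and those false companions must collapse to
#' one anchor or the kernel estimate shrinks to a fraction of the trace.
#'
#' @param x_sr Likelihood map in `[0, 1]`.
#' @param min_peak Threshold (default 0.5).
#' @param merge_radius Peak-merging radius in map pixels (default 5, i.e.
#'   100 um on the super-resolution grid): wide enough to absorb the
#'   companion blobs of a split trace, narrow enough not to swallow
#'   genuinely close bubble pairs.
#' @return Sparse matrix of the same size.
#' @export
sparsify_detections <- function(x_sr, min_peak = 0.5, merge_radius = 5) {
  out <- matrix(0, nrow(x_sr), ncol(x_sr))
  mask <- x_sr > min_peak
  if (!any(mask)) return(out)
  lab <- label8(mask)
  nr <- nrow(x_sr)
  peaks <- lapply(seq_len(max(lab)), function(l) {
    idx <- which(lab == l)          # column-major order
    vals <- x_sr[idx]
    best <- idx[vals == max(vals)]
    if (length(best) > 1L) {        # ties: first in row-major scan order
      rr <- (best - 1L) %% nr + 1L
      cc <- (best - 1L) %/% nr + 1L
      best <- best[order(rr, cc)][1L]
    }
    c(best, x_sr[best])
  })
  pk_idx <- vapply(peaks, `[`, numeric(1), 1L)
  pk_val <- vapply(peaks, `[`, numeric(1), 2L)
  rr <- (pk_idx - 1L) %% nr + 1L
  cc <- (pk_idx - 1L) %/% nr + 1L
  # absorb each peak into the brightest peak within merge_radius
  keep <- rep(TRUE, length(pk_idx))
  ord <- order(-pk_val, rr, cc)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    close_by <- keep & sqrt((rr - rr[i])^2 + (cc - cc[i])^2) <=
      merge_radius
    close_by[i] <- FALSE
    keep[close_by & pk_val <= pk_val[i]] <- FALSE
  }
  out[pk_idx[keep]] <- pk_val[keep]
  out
}

# Gaussian disk fed to the k-net (unit peak, sigma in native pixels)
knet_input_disk <- function(nk, sigma = 5) {
  h <- (nk - 1L) / 2
  off <- (-h):h
  d <- exp(-outer(off^2, off^2, `+`) / (2 * sigma^2))
  d / max(d)
}

# k-net forward: net output plus the fixed disk (residual learning on the
# kernel grid), clamped nonnegative, normalized to unit peak. Returns the
# normalized kernel and the pieces needed to chain gradients.
knet_kernel <- function(knet, disk) {
  fw <- nn_forward(knet, disk, keep_cache = TRUE)
  raw <- fw$out + disk
  raw[raw < 0] <- 0
  m <- max(raw)
  if (m <= 0) stop("k-net output collapsed to zero")
  list(k = raw / m, raw = raw, m = m, fw = fw)
}

# chain dL/dk (normalized) back to dL/draw through clamp + unit-peak
# normalization (argmax treated with the standard subgradient)
knet_kernel_grad <- function(kk, dk) {
  m <- kk$m
  draw <- dk / m
  imax <- which.max(kk$raw)
  draw[imax] <- draw[imax] - sum(dk * kk$raw) / m^2
  draw[kk$raw <= 0] <- 0
  draw
}

#' Adapt the k-net to a window of frames
#'
#' Step 1 of the self-supervised pair: the x-net is frozen; its sparsified
#' outputs on a fixed random subset of frames anchor the reconstruction
#' loss `L_k = L_y + gamma ||k||^2`, minimized over the k-net parameters
#' (Adam, initial rate 1e-4, reduced x0.1 after 5 stalled iterations).
#' Terminates when the RMS change of the kernel estimate falls below `tol`.
#'
#' @param frames List of native-resolution frames for one window.
#' @param xnet Frozen localizer: an `ulm_net`/`supbd_fit`, or a function
#'   `frame -> super-resolution map`.
#' @param knet A k-net (`build_supbd(knet_spec(...))`); built fresh when
#'   `NULL`.
#' @param weights A [self_weights()].
#' @param grid An [grid_spec()].
#' @param ctx A [self_ctx()] (built from `grid` when `NULL`).
#' @param n_frames Frames anchoring the adaptation (default 8).
#' @param max_iter Iteration cap (default 400).
#' @param lr Initial learning rate (default 1e-4).
#' @param tol RMS kernel-change tolerance (default 1e-6).
#' @param disk_sigma Input-disk standard deviation in native pixels
#'   (default 5).
#' @param min_peak Sparsification threshold (default 0.5).
#' @param seed Optional seed for the frame subset.
#' @return List of class `selfbd_adapt`: `psf` (an `ulm_psf` on the kernel
#'   grid), `knet`, `history` tibble (`iter`, `loss`, `kernel_rms_change`,
#'   `lr`), `frames_used`.
#' @export
adapt_knet <- function(frames, xnet, knet = NULL,
                       weights = self_weights(), grid = grid_spec(),
                       ctx = NULL, n_frames = 8L, max_iter = 400L,
                       lr = 1e-4, tol = 1e-6, disk_sigma = 5,
                       min_peak = 0.5, seed = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) < n_frames)
    stop(sprintf("need at least %d frames in the window", n_frames))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ctx)) ctx <- self_ctx(grid)
  if (is.null(knet)) knet <- build_supbd(knet_spec(), seed = seed)
  infer <- if (is.function(xnet)) xnet else function(fr) supbd_infer(xnet, fr)
  sel <- sample(seq_along(frames), n_frames)
  xs <- lapply(frames[sel], function(fr) sparsify_detections(infer(fr),
                                                             min_peak))
  if (all(vapply(xs, function(m) all(m == 0), logical(1))))
    stop("no detections in any selected frame")
  disk <- knet_input_disk(ctx$nk, disk_sigma)
  state <- adam_state()
  stall <- 0L
  best_loss <- Inf
  k_prev <- NULL
  hist <- list()
  for (it in seq_len(max_iter)) {
    kk <- knet_kernel(knet, disk)
    dk_total <- matrix(0, ctx$nk, ctx$nk)
    loss <- 0
    for (i in seq_along(xs)) {
      ly <- self_loss_y(xs[[i]], kk$k, frames[[sel[i]]], weights, ctx,
                        grad = "k")
      loss <- loss + ly$loss
      dk_total <- dk_total + ly$grad_k
    }
    rk <- reg_k(kk$k, weights, grad = TRUE)
    loss <- loss + rk$loss
    dk_total <- dk_total + rk$grad
    draw <- knet_kernel_grad(kk, dk_total)
    gr <- nn_backward(knet, kk$fw$cache, draw)
    knet$params <- adam_step(knet$params, gr, state, lr, it)
    if (loss >= best_loss * (1 - 1e-3)) stall <- stall + 1L else stall <- 0L
    best_loss <- min(best_loss, loss)
    if (stall >= 5L) { lr <- lr * 0.1; stall <- 0L }
    drms <- if (is.null(k_prev)) NA_real_ else sqrt(mean((kk$k - k_prev)^2))
    hist[[it]] <- tibble::tibble(iter = it, loss = loss,
                                 kernel_rms_change = drms, lr = lr)
    if (!is.na(drms) && drms < tol) break
    k_prev <- kk$k
  }
  kk <- knet_kernel(knet, disk)
  psf <- psf_from_kernel(kk$k, grid)
  structure(list(psf = psf, knet = knet,
                 history = dplyr::bind_rows(hist), frames_used = sel),
            class = "selfbd_adapt")
}

#' Refine the x-net against an adapted kernel
#'
#' Step 2: the k-net (kernel) is frozen; only the x-net layers after the
#' global residual addition are updated, minimizing
#' `L_x = L_y + reg_x`. Eight held-out frames form the validation set;
#' validation runs every 5 iterations, the learning rate drops x0.1 after 5
#' stalled validations, three reductions in total; the best-validated
#' parameters are returned.
#'
#' @param frames List of native frames (>= 16: training plus validation).
#' @param kernel The adapted kernel: a `selfbd_adapt`, `ulm_psf`, or
#'   matrix on the context's kernel grid.
#' @param xnet The pretrained localizer (`ulm_net` or `supbd_fit`).
#' @param weights A [self_weights()].
#' @param grid An [grid_spec()].
#' @param ctx A [self_ctx()].
#' @param minibatch Frames per iteration (default 8).
#' @param n_val Validation frames (default 8).
#' @param lr Initial learning rate (default 1e-4).
#' @param max_iter Iteration cap (default 200).
#' @param seed Optional seed.
#' @return List of class `selfbd_refine`: `net`, `history`
#'   (`iter`, `loss`, `val_loss`, `lr`), `best_val`.
#' @export
refine_xnet <- function(frames, kernel, xnet, weights = self_weights(),
                        grid = grid_spec(), ctx = NULL, minibatch = 8L,
                        n_val = 8L, lr = 1e-4, max_iter = 200L,
                        seed = NULL) {
  if (length(frames) < 2L * n_val)
    stop("fewer than 16 frames: cannot split train/validation")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ctx)) ctx <- self_ctx(grid)
  if (inherits(kernel, "selfbd_adapt")) kernel <- kernel$psf
  if (inherits(kernel, "ulm_psf")) kernel <- kernel$kernel_native
  kernel <- crop_kernel(kernel / max(kernel), ctx$nk)
  if (inherits(xnet, "supbd_fit")) xnet <- xnet$net
  val_idx <- sample(seq_along(frames), n_val)
  tr_idx <- setdiff(seq_along(frames), val_idx)
  # unit conversion for raw likelihood maps: the x-net emits unit-peak
  # blurred blobs of mass 1/w0 per center (the training-reference
  # convention), so the point-scatterer reconstruction includes the fixed
  # gain w0 = the reference blur kernel's peak weight
  gain <- max(reference_blur_kernel())
  frame_loss <- function(net, fr, grad = FALSE) {
    fw <- nn_forward(net, fr, keep_cache = grad)
    ly <- self_loss_y(gain * fw$out, kernel, fr, weights, ctx,
                      grad = if (grad) "x" else "none")
    rx <- reg_x(fw$out, weights, grad = grad)
    if (!grad) return(ly$loss + rx$loss)
    list(loss = ly$loss + rx$loss, fw = fw,
         dout = gain * ly$grad_x + rx$grad)
  }
  validate <- function(net) mean(vapply(val_idx, function(i)
    frame_loss(net, frames[[i]]), numeric(1)))
  state <- adam_state()
  best_val <- validate(xnet)
  best_params <- xnet$params
  stall <- 0L
  n_red <- 0L
  hist <- list(tibble::tibble(iter = 0L, loss = NA_real_,
                              val_loss = best_val, lr = lr))
  for (it in seq_len(max_iter)) {
    bt <- sample(tr_idx, min(minibatch, length(tr_idx)))
    acc <- NULL
    bl <- 0
    for (i in bt) {
      fl <- frame_loss(xnet, frames[[i]], grad = TRUE)
      bl <- bl + fl$loss
      acc <- grad_axpy(acc, nn_backward(xnet, fl$fw$cache, fl$dout,
                                        head_only = TRUE), 1 / length(bt))
    }
    xnet$params <- adam_step(xnet$params, acc, state, lr, it)
    vl <- NA_real_
    if (it %% 5L == 0L) {
      vl <- validate(xnet)
      if (vl < best_val) {
        best_val <- vl; best_params <- xnet$params; stall <- 0L
      } else stall <- stall + 1L
      if (stall >= 5L) {
        lr <- lr * 0.1
        stall <- 0L
        n_red <- n_red + 1L
        if (n_red > 3L) break
      }
    }
    hist[[length(hist) + 1L]] <- tibble::tibble(iter = it,
                                                loss = bl / length(bt),
                                                val_loss = vl, lr = lr)
  }
  xnet$params <- best_params
  structure(list(net = xnet, history = dplyr::bind_rows(hist),
                 best_val = best_val),
            class = "selfbd_refine")
}
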