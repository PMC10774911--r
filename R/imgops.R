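# Finite-difference image operators shared by the evaluation metrics and the
# self-supervised losses. Central differences for measurement channels
# (gradient, Hessian); forward differences for the sparsity surrogate.

# central-difference gradients, replicated edges
grad_central <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  iu <- c(1L, seq_len(nr - 1L)); id <- c(seq_len(nr - 1L) + 1L, nr)
  il <- c(1L, seq_len(nc - 1L)); ir <- c(seq_len(nc - 1L) + 1L, nc)
  list(d = (img[id, ] - img[iu, ]) / 2,   # d/d depth
       l = (img[, ir] - img[, il]) / 2)   # d/d lateral
}

# second central differences: the three distinct Hessian terms
hessian_terms <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  iu <- c(1L, seq_len(nr - 1L)); id <- c(seq_len(nr - 1L) + 1L, nr)
  il <- c(1L, seq_len(nc - 1L)); ir <- c(seq_len(nc - 1L) + 1L, nc)
  g <- grad_central(img)
  list(dd = img[id, ] - 2 * img + img[iu, ],
       ll = img[, ir] - 2 * img + img[, il],
       dl = (g$d[, ir] - g$d[, il]) / 2)
}

# forward differences (last row/col zero)
grad_forward <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gd <- rbind(img[-1, , drop = FALSE] - img[-nr, , drop = FALSE],
              matrix(0, 1, nc))
  gl <- cbind(img[, -1, drop = FALSE] - img[, -nc, drop = FALSE],
              matrix(0, nr, 1))
  list(d = gd, l = gl)
}

# per-pixel eigenvalue magnitudes of the 2x2 finite-difference Hessian,
# ordered |e1| >= |e2|
hessian_eigen_mags <- function(img) {
  H <- hessian_terms(img)
  tr <- H$dd + H$ll
  disc <- sqrt((H$dd - H$ll)^2 + 4 * H$dl^2)
  e1 <- (tr + disc) / 2
  e2 <- (tr - disc) / 2
  a1 <- abs(e1); a2 <- abs(e2)
  list(e1 = pmax(a1, a2), e2 = pmin(a1, a2))
}
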