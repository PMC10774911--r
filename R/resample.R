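# Separable bicubic (Keys, a = -0.5) image resampling implemented as
# precomputed interpolation matrices: out = Wr %*% img %*% t(Wc). Replicated
# edges; pixel-center alignment (output pixel j center maps to input
# coordinate (j - 0.5) * n_in/n_out in um-consistent index space).

keys_kernel <- function(s, a = -0.5) {
  s <- abs(s)
  w <- numeric(length(s))
  i1 <- s <= 1
  i2 <- s > 1 & s < 2
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  w[i2] <- a * s[i2]^3 - 5 * a * s[i2]^2 + 8 * a * s[i2] - 4 * a
  w
}

# Interpolation matrix mapping a length-n_in signal to length n_out.
bicubic_matrix <- function(n_in, n_out) {
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    t <- (j - 0.5) * scale + 0.5   # index space: input pixel i center at i
    base <- floor(t)
    taps <- (base - 1):(base + 2)
    w <- keys_kernel(t - taps)
    taps <- pmin(pmax(taps, 1L), n_in)  # replicate edges
    for (m in seq_along(taps)) W[j, taps[m]] <- W[j, taps[m]] + w[m]
  }
  W
}

#' Bicubic image resampling
#'
#' Resamples a matrix to a new size with Keys cubic-convolution
#' interpolation (a = -0.5), the scheme used for all up/down conversions
#' between the synthesis, native, and super-resolution grids.
#'
#' @param img Numeric matrix.
#' @param nrow_out,ncol_out Output dimensions.
#' @return Numeric matrix of size `nrow_out` x `ncol_out`.
#' @export
resample_bicubic <- function(img, nrow_out, ncol_out = nrow_out) {
  stopifnot(is.matrix(img), nrow_out >= 1, ncol_out >= 1)
  Wr <- bicubic_matrix(nrow(img), nrow_out)
  Wc <- bicubic_matrix(ncol(img), ncol_out)
  Wr %*% img %*% t(Wc)
}

# Gaussian blur with replicate padding, separable.
gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_1d_rows <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(img)
  idx <- pmin(pmax(outer(seq_len(n), (-r):r, `+`), 1L), n)
  out <- matrix(0, n, ncol(img))
  for (m in seq_along(k)) out <- out + k[m] * img[idx[, m], , drop = FALSE]
  out
}

#' Gaussian blur of an image
#'
#' Separable Gaussian filter with replicated edges.
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  t(convolve_1d_rows(t(convolve_1d_rows(img, k)), k))
}

# 2D FFT convolution, 'same' output, zero padding. Kernel center is at
# pixel ((kh+1)/2, (kw+1)/2) for odd-sized kernels.
fft_conv2_same <- function(img, kern) {
  ih <- nrow(img); iw <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  ph <- ih + kh - 1L; pw <- iw + kw - 1L
  A <- matrix(0, ph, pw); A[1:ih, 1:iw] <- img
  B <- matrix(0, ph, pw); B[1:kh, 1:kw] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (ph * pw)
  r0 <- (kh + 1L) %/% 2L; c0 <- (kw + 1L) %/% 2L
  full[r0:(r0 + ih - 1L), c0:(c0 + iw - 1L)]
}
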