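# Frame synthesis: point scatterers on the fine synthesis grid, convolved
# with the high-resolution PSF, bicubically downsampled to the native pitch,
# plus background noise. For on-grid point scatterers the convolution is
# evaluated exactly by accumulating shifted copies of the kernel.

# cache of bicubic interpolation matrices (sizes recur constantly)
.bicubic_cache <- new.env(parent = emptyenv())
bicubic_matrix_cached <- function(n_in, n_out) {
  key <- paste(n_in, n_out)
  W <- .bicubic_cache[[key]]
  if (is.null(W)) {
    W <- bicubic_matrix(n_in, n_out)
    .bicubic_cache[[key]] <- W
  }
  W
}

resample_bicubic_cached <- function(img, nrow_out, ncol_out = nrow_out) {
  Wr <- bicubic_matrix_cached(nrow(img), nrow_out)
  Wc <- bicubic_matrix_cached(ncol(img), ncol_out)
  Wr %*% img %*% t(Wc)
}

#' Bubble list constructor
#'
#' @param depth_um,lateral_um Continuous positions in um from the top-left
#'   image corner.
#' @param intensity Peak intensities, recycled; bubbles in synthetic scenes
#'   draw these uniformly from `[0.6, 1]`.
#' @return A tibble with columns `depth_um`, `lateral_um`, `intensity`.
#' @export
bubbles <- function(depth_um = numeric(), lateral_um = numeric(),
                    intensity = 1) {
  tibble::tibble(depth_um = as.numeric(depth_um),
                 lateral_um = as.numeric(lateral_um),
                 intensity = rep_len(as.numeric(intensity),
                                     length(depth_um)))
}

#' Synthesize one native-resolution CEUS frame
#'
#' Places each bubble as a point scatterer on the synthesis grid (half-open
#' floor pixel convention), convolves with the high-resolution PSF kernel,
#' downsamples bicubically to the native pitch, adds background noise, and
#' clips to `[0, 1]`.
#'
#' @param bub Tibble from [bubbles()]; positions must lie inside the window.
#' @param psf An [make_psf()] model.
#' @param noise An [noise_spec()] or `NULL` for a noise-free frame.
#' @param grid An [grid_spec()].
#' @return A list with `frame` (window x window native matrix) and `truth`
#'   (the input bubble tibble).
#' @examples
#' g <- grid_spec(window = 40)
#' psf <- make_psf(300, 250, grid = g)
#' fr <- synthesize_frame(bubbles(1200, 1200), psf, NULL, g)
#' @export
synthesize_frame <- function(bub, psf, noise = NULL, grid = grid_spec()) {
  ext <- grid_extent_um(grid)
  if (nrow(bub) > 0 &&
      (any(bub$depth_um < 0 | bub$depth_um >= ext) ||
       any(bub$lateral_um < 0 | bub$lateral_um >= ext)))
    stop("bubble positions must lie inside the field of view")
  n_hi <- grid$window * grid$synthesis_factor
  hi <- matrix(0, n_hi, n_hi)
  if (nrow(bub) > 0) {
    k <- psf$kernel_hi
    hk <- (nrow(k) - 1L) %/% 2L
    ii <- um_to_pixel(bub$depth_um, grid$synthesis_pixel)
    jj <- um_to_pixel(bub$lateral_um, grid$synthesis_pixel)
    for (b in seq_len(nrow(bub))) {
      r <- (ii[b] - hk):(ii[b] + hk)
      c <- (jj[b] - hk):(jj[b] + hk)
      rok <- r >= 1L & r <= n_hi
      cok <- c >= 1L & c <= n_hi
      hi[r[rok], c[cok]] <- hi[r[rok], c[cok]] +
        bub$intensity[b] * k[which(rok), which(cok)]
    }
  }
  frame <- resample_bicubic_cached(hi, grid$window, grid$window)
  frame[frame < 0] <- 0
  if (!is.null(noise) && noise$peak_level > 0)
    frame <- frame + make_noise(noise, dim(frame))
  frame[frame > 1] <- 1
  list(frame = frame, truth = bub)
}

#' Center map at a chosen resolution
#'
#' Marks the pixel containing each true center with its intensity (or 1).
#'
#' @param truth Bubble tibble.
#' @param grid An [grid_spec()].
#' @param resolution `"synthesis"` or `"superres"`.
#' @param use_intensity Write bubble intensity instead of 1.
#' @return Matrix at the requested resolution.
#' @export
make_center_map <- function(truth, grid = grid_spec(),
                            resolution = c("synthesis", "superres"),
                            use_intensity = FALSE) {
  resolution <- match.arg(resolution)
  f <- if (resolution == "synthesis") grid$synthesis_factor else grid$superres_factor
  pitch <- grid$native_pixel / f
  n <- grid$window * f
  m <- matrix(0, n, n)
  if (nrow(truth) > 0) {
    i <- um_to_pixel(truth$depth_um, pitch)
    j <- um_to_pixel(truth$lateral_um, pitch)
    if (any(i < 1 | i > n | j < 1 | j > n))
      stop("center outside window")
    v <- if (use_intensity) truth$intensity else rep(1, nrow(truth))
    for (b in seq_along(i)) m[i[b], j[b]] <- max(m[i[b], j[b]], v[b])
  }
  m
}

# fixed 5x5 Gaussian blur kernel (sigma = 1 superres pixel), sum 1
reference_blur_kernel <- function() {
  k1 <- exp(-((-2):2)^2 / 2)
  k <- outer(k1, k1)
  k / sum(k)
}

#' Super-resolution training reference map
#'
#' Builds the blurred center map used as the supervised training reference:
#' super-resolution pixels containing true centers are set to 1, the map is
#' blurred with a fixed 5 x 5 Gaussian kernel (sigma = 1 super-resolution
#' pixel), and rescaled so an isolated blob peaks at exactly 1 (values capped
#' at 1 where blobs overlap).
#'
#' @param truth Bubble tibble with centers in um.
#' @param grid An [grid_spec()].
#' @return Matrix of size `window * superres_factor` squared.
#' @export
make_reference_map <- function(truth, grid = grid_spec()) {
  m <- make_center_map(truth, grid, "superres")
  k <- reference_blur_kernel()
  out <- conv2_shift(m, k) / max(k)
  out[out > 1] <- 1
  out
}

# small-kernel 'same' convolution with zero padding via shifted accumulation
conv2_shift <- function(img, k) {
  hr <- (nrow(k) - 1L) %/% 2L
  hc <- (ncol(k) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (a in -hr:hr) for (b in -hc:hc) {
    w <- k[a + hr + 1L, b + hc + 1L]
    if (w == 0) next
    rs <- max(1L, 1L + a):min(nr, nr + a)
    cs <- max(1L, 1L + b):min(nc, nc + b)
    out[rs, cs] <- out[rs, cs] + w * img[rs - a, cs - b]
  }
  out
}
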