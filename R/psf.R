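#' Parametric point spread function models
#'
#' Builds a spatially invariant PSF model for one interrogation window. The
#' shipped parametric family is a rotated anisotropic Gaussian, optionally
#' modulated by an asymmetric depth-direction tail
#' (`family = "gaussian_with_tails"`), standing in for experimentally
#' estimated CEUS trace shapes. The kernel is sampled both at the native
#' pixel pitch and at the finer synthesis pitch, each normalized to unit
#' peak.
#'
#' Orientation is measured in degrees from the lateral (column) axis, so the
#' default `orientation = 0` elongates the trace laterally, as CEUS traces do
#' perpendicular to the scanline.
#'
#' @param fwhm_major,fwhm_minor Full widths at half maximum along the major
#'   and minor axes, in um. Must resolve to at least two native pixels.
#' @param orientation Rotation of the major axis in degrees from the lateral
#'   axis.
#' @param family `"gaussian"` or `"gaussian_with_tails"`.
#' @param grid An [grid_spec()] object.
#' @return An object of class `ulm_psf` with elements `kernel_native`,
#'   `kernel_hi`, `fwhm_major`, `fwhm_minor`, `orientation`, `S` (FWHM area,
#'   um^2), `AR` (aspect ratio >= 1), and the pixel pitches.
#' @examples
#' psf <- make_psf(400, 400)
#' psf$AR                      # 1
#' psf$S / (pi * 200^2)        # ~1 (half-max disk area)
#' @export
make_psf <- function(fwhm_major, fwhm_minor = fwhm_major, orientation = 0,
                     family = c("gaussian", "gaussian_with_tails"),
                     grid = grid_spec()) {
  family <- match.arg(family)
  if (fwhm_major < fwhm_minor) { # major is by definition the longer one
    tmp <- fwhm_major; fwhm_major <- fwhm_minor; fwhm_minor <- tmp
    orientation <- orientation + 90
  }
  if (fwhm_minor < 2 * grid$native_pixel)
    stop("unresolvable kernel: FWHM below 2 native pixels")
  h_nat <- ceiling(1.5 * fwhm_major / grid$native_pixel)
  eval_kernel <- function(pitch, half_px) {
    n <- 2L * half_px + 1L
    off <- (seq_len(n) - (half_px + 1L)) * pitch
    du <- matrix(off, n, n)            # depth offsets (rows)
    dl <- matrix(off, n, n, byrow = TRUE)  # lateral offsets (cols)
    th <- orientation * pi / 180
    u <- dl * cos(th) + du * sin(th)   # along major axis
    v <- -dl * sin(th) + du * cos(th)  # along minor axis
    k <- exp(-4 * log(2) * (u^2 / fwhm_major^2 + v^2 / fwhm_minor^2))
    if (family == "gaussian_with_tails") {
      # one-sided tail toward increasing depth; fixed shape, peak preserved
      k <- k * (1 + 0.3 * stats::plogis(du / (0.15 * fwhm_major)) *
                  exp(-abs(du) / (0.8 * fwhm_major)))
    }
    k / max(k)
  }
  kernel_native <- eval_kernel(grid$native_pixel, h_nat)
  kernel_hi <- eval_kernel(grid$synthesis_pixel, h_nat * grid$synthesis_factor)
  psf <- structure(list(
    kernel_native = kernel_native,
    kernel_hi = kernel_hi,
    fwhm_major = fwhm_major,
    fwhm_minor = fwhm_minor,
    orientation = orientation %% 180,
    family = family,
    native_pixel = grid$native_pixel,
    hi_pixel = grid$synthesis_pixel,
    S = NA_real_,
    AR = fwhm_major / fwhm_minor
  ), class = "ulm_psf")
  psf$S <- psf_area(psf)
  psf
}

#' Wrap an arbitrary kernel matrix as a PSF model
#'
#' Used for kernels estimated from data (blind deconvolution, k-net), for
#' which FWHM geometry is measured from the sampled intensity rather than
#' taken from analytic parameters.
#'
#' @param kernel_native Nonnegative matrix at native resolution.
#' @param grid An [grid_spec()] object.
#' @param upsample Build `kernel_hi` by bicubic upsampling (default TRUE).
#' @return An `ulm_psf`.
#' @export
psf_from_kernel <- function(kernel_native, grid = grid_spec(),
                            upsample = TRUE) {
  stopifnot(is.matrix(kernel_native))
  if (max(kernel_native) <= 0) stop("kernel has no positive values")
  kernel_native <- kernel_native / max(kernel_native)
  f <- grid$synthesis_factor
  kernel_hi <- if (upsample) {
    kh <- resample_bicubic(kernel_native, nrow(kernel_native) * f,
                           ncol(kernel_native) * f)
    kh[kh < 0] <- 0
    kh / max(kh)
  } else kernel_native
  psf <- structure(list(
    kernel_native = kernel_native,
    kernel_hi = kernel_hi,
    fwhm_major = NA_real_, fwhm_minor = NA_real_,
    orientation = NA_real_, family = "empirical",
    native_pixel = grid$native_pixel,
    hi_pixel = grid$native_pixel / f,
    S = NA_real_, AR = NA_real_
  ), class = "ulm_psf")
  # principal FWHM geometry measured over a direction sweep
  dirs <- seq(0, 175, by = 5)
  lp <- vapply(dirs, function(d) psf_fwhm_length(psf, d), numeric(1))
  imax <- which.max(lp)
  psf$fwhm_major <- lp[imax]
  psf$orientation <- dirs[imax]
  psf$fwhm_minor <- psf_fwhm_length(psf, dirs[imax] + 90)
  psf$AR <- psf$fwhm_major / psf$fwhm_minor
  psf$S <- psf_area(psf)
  psf
}

#' @export
print.ulm_psf <- function(x, ...) {
  cat(sprintf(
    "<ulm_psf %s> FWHM %.0f x %.0f um (AR %.2f), orientation %.0f deg, S %.3g um^2\n",
    x$family, x$fwhm_major, x$fwhm_minor, x$AR, x$orientation, x$S))
  invisible(x)
}

#' FWHM area of a PSF
#'
#' Area of the half-maximum support, measured on the high-resolution kernel.
#'
#' @param psf An `ulm_psf`.
#' @return Area in um^2.
#' @export
psf_area <- function(psf) {
  sum(psf$kernel_hi >= 0.5 * max(psf$kernel_hi)) * psf$hi_pixel^2
}

#' FWHM length of a PSF along a direction
#'
#' Length of the half-maximum chord through the kernel peak along a given
#' direction -- the `L_p` that controls the separability of structures
#' perpendicular to a vessel.
#'
#' @param psf An `ulm_psf`.
#' @param direction Direction in degrees from the lateral axis.
#' @return Length in um.
#' @export
psf_fwhm_length <- function(psf, direction) {
  k <- psf$kernel_hi
  pk <- which(k == max(k), arr.ind = TRUE)[1, ]
  th <- direction * pi / 180
  step <- psf$hi_pixel / 2
  tmax <- max(dim(k)) * psf$hi_pixel
  half_len <- function(sgn) {
    t <- seq(0, tmax, by = step)
    du <- pk[1] + sgn * t * sin(th) / psf$hi_pixel
    dl <- pk[2] + sgn * t * cos(th) / psf$hi_pixel
    v <- bilinear_at(k, du, dl)
    below <- which(v < 0.5)
    if (!length(below)) return(t[length(t)])
    i <- below[1]
    if (i == 1) return(0)
    # linear interpolation to the 0.5 crossing
    t[i - 1] + (0.5 - v[i - 1]) / (v[i] - v[i - 1]) * step
  }
  half_len(1) + half_len(-1)
}

# Bilinear sampling of matrix m at fractional (row, col) positions; zero
# outside.
bilinear_at <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- numeric(length(ri))
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    out
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
}

#' Round-trip resampling error of a PSF
#'
#' Measures the relative RMS intensity change introduced by bicubically
#' upsampling the native-resolution kernel by the synthesis factor and
#' downsampling it back -- the distortion incurred when empirical kernels are
#' moved onto the synthesis grid.
#'
#' @param psf An `ulm_psf`.
#' @param factor Resampling factor (default the synthesis factor, 10).
#' @return Dimensionless relative RMS error.
#' @export
psf_resampling_error <- function(psf, factor = 10L) {
  k <- psf$kernel_native
  rms <- function(x) sqrt(mean(x^2))
  if (rms(k) == 0) stop("all-zero kernel")
  if (factor == 1L) return(0)
  up <- resample_bicubic(k, nrow(k) * factor, ncol(k) * factor)
  khat <- resample_bicubic(up, nrow(k), ncol(k))
  rms(khat - k) / rms(k)
}
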