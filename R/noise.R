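#' Speckle-like background noise specification
#'
#' @param peak_level Peak intensity of the generated noise field, in the
#'   image's 0-1 intensity units. Typical CEUS backgrounds round to
#'   0.10, 0.15 (most common), 0.20; evaluation also uses 0, 0.08, 0.16,
#'   0.24. Any value in `[0, 0.3]` is accepted.
#' @param blur_sigma Gaussian blur applied to the raw speckles, in native
#'   pixels (default 1).
#' @return An object of class `ulm_noise`.
#' @export
noise_spec <- function(peak_level = 0.15, blur_sigma = 1) {
  if (peak_level < 0) stop("peak_level must be >= 0")
  structure(list(peak_level = peak_level, blur_sigma = blur_sigma),
            class = "ulm_noise")
}

#' Generate a speckle-like background noise field
#'
#' Draws i.i.d. exponential speckles per native pixel, blurs them with a 2D
#' Gaussian, and rescales so the field maximum equals `peak_level` exactly.
#' The resulting intensity histogram has the monotonically decaying tail
#' characteristic of sampled CEUS backgrounds.
#'
#' @param spec An [noise_spec()].
#' @param shape Integer vector `c(nrow, ncol)` in native pixels.
#' @return Nonnegative matrix with `max == peak_level` (all zeros for
#'   `peak_level = 0`).
#' @examples
#' n <- make_noise(noise_spec(0.16), c(80, 80))
#' max(n)  # 0.16
#' @export
make_noise <- function(spec, shape) {
  stopifnot(inherits(spec, "ulm_noise"), length(shape) == 2)
  if (spec$peak_level == 0) return(matrix(0, shape[1], shape[2]))
  raw <- matrix(stats::rexp(prod(shape)), shape[1], shape[2])
  sm <- gaussian_blur(raw, spec$blur_sigma)
  sm <- sm * (spec$peak_level / max(sm))
  sm[which.max(sm)] <- spec$peak_level   # exact despite float rescaling
  sm
}
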