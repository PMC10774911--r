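#' Imaging grid specification
#'
#' Describes the geometry shared by all synthetic scenes and localizers: the
#' ultrasound wavelength, the native pixel pitch of the exported CEUS frames,
#' and the two finer grids derived from it -- the super-resolution output grid
#' (default 3x, i.e. 20 um = lambda/14 for the default probe) and the synthesis
#' grid on which point scatterers are placed (default 10x, i.e. 6 um, of the
#' order of the physical microbubble diameter).
#'
#' Coordinate convention used throughout the package: axis 1 (matrix rows) is
#' depth, axis 2 (columns) is lateral; positions are continuous, in microns,
#' measured from the top-left image corner. Pixel `i` (1-based) covers the
#' half-open interval `[(i-1)*delta, i*delta)` and has its center at
#' `(i-0.5)*delta`.
#'
#' @param wavelength Ultrasound wavelength in um (default 280).
#' @param native_pixel Native CEUS pixel pitch in um (default 60).
#' @param superres_factor Integer upscale factor of the localizer output grid
#'   (default 3, giving 20 um pixels).
#' @param synthesis_factor Integer upscale factor of the scatterer placement
#'   grid (default 10, giving 6 um pixels).
#' @param window Interrogation-window side length in native pixels
#'   (default 80, i.e. 4.8 x 4.8 mm^2).
#' @param frame_interval Frame interval in seconds (default 1/48).
#' @return An object of class `ulm_grid`.
#' @examples
#' g <- grid_spec()
#' g$superres_pixel   # 20 um
#' grid_area_mm2(g)   # 23.04 mm^2
#' @export
grid_spec <- function(wavelength = 280, native_pixel = 60,
                      superres_factor = 3L, synthesis_factor = 10L,
                      window = 80L, frame_interval = 1 / 48) {
  stopifnot(wavelength > 0, native_pixel > 0, frame_interval > 0)
  superres_factor <- as.integer(superres_factor)
  synthesis_factor <- as.integer(synthesis_factor)
  window <- as.integer(window)
  if (superres_factor < 1L || synthesis_factor < 1L)
    stop("resolution factors must be integers >= 1")
  if (window < 1L) stop("window must be a positive integer")
  structure(list(
    wavelength = wavelength,
    native_pixel = native_pixel,
    superres_factor = superres_factor,
    synthesis_factor = synthesis_factor,
    superres_pixel = native_pixel / superres_factor,
    synthesis_pixel = native_pixel / synthesis_factor,
    window = window,
    frame_interval = frame_interval
  ), class = "ulm_grid")
}

#' @export
print.ulm_grid <- function(x, ...) {
  cat(sprintf(
    "<ulm_grid> %d x %d native px (%.0f um), window %.1f x %.1f mm, lambda %.0f um\n",
    x$window, x$window, x$native_pixel,
    x$window * x$native_pixel / 1000, x$window * x$native_pixel / 1000,
    x$wavelength))
  cat(sprintf("  superres x%d (%.1f um = lambda/%.1f), synthesis x%d (%.1f um), %.0f fps\n",
              x$superres_factor, x$superres_pixel,
              x$wavelength / x$superres_pixel,
              x$synthesis_factor, x$synthesis_pixel, 1 / x$frame_interval))
  invisible(x)
}

#' Field-of-view area in mm^2
#' @param grid An `ulm_grid`.
#' @return Scalar area in mm^2.
#' @export
grid_area_mm2 <- function(grid) {
  (grid$window * grid$native_pixel / 1000)^2
}

#' Field-of-view side length in um
#' @param grid An `ulm_grid`.
#' @return Scalar length in um.
#' @export
grid_extent_um <- function(grid) grid$window * grid$native_pixel

# Map continuous um coordinates to 1-based pixel indices on a grid with
# pitch `delta`, half-open floor convention: coordinate u falls in pixel
# floor(u/delta) + 1.
um_to_pixel <- function(u, delta) floor(u / delta) + 1L

# Center of pixel i (1-based) in um.
pixel_center_um <- function(i, delta) (i - 0.5) * delta
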