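# External formats: multi-page float TIFF for frame stacks and PSF fields,
# CSV for detections/tracks/truth, YAML for scenario configs, JSON for
# manifests and report bundles.

#' Write a frame stack as multi-page float TIFF
#'
#' @param frames List of matrices (one page per time step), values in
#'   `[0, 1]`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a frame stack from TIFF
#'
#' @param path TIFF file (single or multi page).
#' @return List of matrices.
#' @export
read_frames_tiff <- function(path) {
  x <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(x)) list(x) else x
}

#' Write truth or detection records as CSV
#'
#' Standard column layout `frame, depth_um, lateral_um, intensity`
#' (or `weight`).
#'
#' @param records Tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_centers_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centers_csv
#' @export
read_centers_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write tracks as CSV
#'
#' Columns `track, frame, depth_um, lateral_um, interpolated, status`.
#'
#' @param tracks `ulm_tracks` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("ulm_tracks", class(out))
  out
}

#' Serialize scenario parameters to YAML
#'
#' @param scenario A `ulm_line_scenario` or `ulm_vessel_scenario`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(scenario, path) {
  obj <- unclass(scenario)
  obj$kind <- if (inherits(scenario, "ulm_line_scenario")) "lines"
  else "vessel"
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  kind <- obj$kind
  obj$kind <- NULL
  if (identical(kind, "lines")) do.call(line_scenario, obj)
  else do.call(vessel_scenario, obj)
}
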