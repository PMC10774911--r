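# Experiment orchestration: schema-validated configs, seeded end-to-end
# runs (simulate -> localize -> evaluate), provenance-stamped CSV/JSON
# reports.

#' Experiment configuration
#'
#' Describes one localization-evaluation experiment: which PSFs of the
#' evaluation ladder, which noise peaks and concentrations, which methods,
#' how many frames per cell, and the seed. Validation happens before any
#' compute.
#'
#' @param tag Short experiment name.
#' @param psf_idx Indices into [evaluation_psf_ladder()] (default all 5).
#' @param noise_peaks Noise peak levels (default `c(0, 0.08, 0.16, 0.24)`).
#' @param concentrations Bubble concentrations in mm^-2 (default
#'   `c(0.25, 0.5, 1)`).
#' @param methods Subset of `c("bd", "supbd", "selfbd")`.
#' @param n_frames Frames per cell (default 50).
#' @param window Native window side (default 80).
#' @param seed Integer seed.
#' @param checkpoints Named list of fitted networks (or RDS paths) for the
#'   network methods.
#' @param psf_orientation Ladder orientation in degrees (default 0).
#' @return A validated `ulm_experiment_config`.
#' @export
experiment_config <- function(tag, psf_idx = 1:5,
                              noise_peaks = c(0, 0.08, 0.16, 0.24),
                              concentrations = c(0.25, 0.5, 1),
                              methods = "bd", n_frames = 50L, window = 80L,
                              seed = 1L, checkpoints = list(),
                              psf_orientation = 0) {
  stopifnot(is.character(tag), length(tag) == 1)
  if (!all(psf_idx %in% 1:5))
    stop("psf_idx must index the 5-step evaluation ladder")
  if (any(noise_peaks < 0 | noise_peaks > 0.3))
    stop("noise peaks must lie in [0, 0.3]")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  bad <- setdiff(methods, c("bd", "supbd", "selfbd"))
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  for (m in intersect(methods, c("supbd", "selfbd"))) {
    ck <- checkpoints[[m]]
    if (is.null(ck))
      stop(sprintf("method %s requires a checkpoint", m))
    if (is.character(ck) && !file.exists(ck))
      stop(sprintf("checkpoint file for %s not found: %s", m, ck))
  }
  structure(list(tag = tag, psf_idx = as.integer(psf_idx),
                 noise_peaks = noise_peaks,
                 concentrations = concentrations, methods = methods,
                 n_frames = as.integer(n_frames),
                 window = as.integer(window), seed = as.integer(seed),
                 checkpoints = checkpoints,
                 psf_orientation = psf_orientation),
            class = "ulm_experiment_config")
}

config_hash <- function(config) {
  rlang::hash(unclass(config)[setdiff(names(unclass(config)),
                                      "checkpoints")])
}

resolve_checkpoint <- function(ck) {
  if (is.character(ck)) readRDS(ck) else ck
}

#' Run a localization evaluation experiment
#'
#' For every (PSF, noise, concentration, method) cell: generates
#' `n_frames` random scenes, localizes with the requested method, and
#' accumulates the localization report. Deterministic for a fixed config.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, writes
#'   `report.csv` and `manifest.json` there.
#' @return Tibble of class `ulm_report`: one row per cell with the pooled
#'   [localization_error_frames()] columns plus cell metadata and the
#'   config provenance hash.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "ulm_experiment_config"))
  grid <- grid_spec(window = config$window)
  ladder <- evaluation_psf_ladder(grid, orientation = config$psf_orientation)
  hash <- config_hash(config)
  nets <- lapply(config$checkpoints, resolve_checkpoint)
  rows <- list()
  for (pi in config$psf_idx) {
    psf <- ladder[[pi]]
    for (np in config$noise_peaks) {
      for (conc in config$concentrations) {
        cell_seed <- config$seed + 7L * pi + 101L * match(np, config$noise_peaks) +
          1009L * match(conc, config$concentrations)
        set.seed(cell_seed)
        scenes <- lapply(seq_len(config$n_frames), function(i) {
          b <- random_bubbles(conc, grid)
          while (nrow(b) == 0) b <- random_bubbles(conc, grid)
          list(truth = dplyr::mutate(b, frame = i),
               frame = synthesize_frame(b, psf,
                                        if (np > 0) noise_spec(np),
                                        grid)$frame)
        })
        truth <- dplyr::bind_rows(lapply(scenes, `[[`, "truth"))
        frames <- lapply(scenes, `[[`, "frame")
        for (m in config$methods) {
          det <- switch(
            m,
            bd = bd_localize(frames, bd_config(window = config$window),
                             grid, psf = psf)$detections,
            supbd = ,
            selfbd = {
              net <- nets[[m]]
              dplyr::bind_rows(lapply(seq_along(frames), function(i)
                net_extract_centers(supbd_infer(net, frames[[i]]), grid,
                                    frame = i)))
            })
          rep <- localization_error_frames(truth, det, psf = psf,
                                           grid = grid)
          S_um2 <- psf$S
          AR_val <- psf$AR
          rows[[length(rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(tag = config$tag, method = m, psf_idx = pi,
                           S_um2 = S_um2, AR = AR_val,
                           noise_peak = np, concentration = conc,
                           n_frames = config$n_frames,
                           seed = cell_seed, config_hash = hash),
            rep)
        }
      }
    }
  }
  report <- dplyr::bind_rows(rows)
  class(report) <- c("ulm_report", class(report))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "report.csv"), row.names = FALSE)
    manifest <- list(tag = config$tag, config_hash = hash,
                     config = unclass(config)[setdiff(names(unclass(config)),
                                                      "checkpoints")],
                     n_rows = nrow(report),
                     package_version =
                       as.character(utils::packageVersion("ulmkit")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}
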