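# Motion scenarios: bubbles advected along two parallel lines (microvessel
# resolution studies) or through a tubular vessel with a parabolic velocity
# profile (macrovessel velocimetry studies).

#' Parallel-line scenario parameters
#'
#' @param D_l Line spacing in um; the study ladder is
#'   18, 30, 60, 120, 180, 240, 300, 360.
#' @param orientation `"aligned"` (lines parallel to the PSF major axis) or
#'   `"perpendicular"`.
#' @param speed Advection speed in mm/s (default 5, a typical microvascular
#'   velocity magnitude).
#' @param steps Number of time steps (default 2500).
#' @param arrival_rate Poisson arrival rate per line per frame
#'   (default 1/40).
#' @return A list of class `ulm_line_scenario`.
#' @export
line_scenario <- function(D_l, orientation = c("aligned", "perpendicular"),
                          speed = 5, steps = 2500, arrival_rate = 1 / 40) {
  orientation <- match.arg(orientation)
  if (D_l <= 0) stop("line spacing must be positive")
  structure(list(D_l = D_l, orientation = orientation, speed = speed,
                 steps = as.integer(steps), arrival_rate = arrival_rate),
            class = "ulm_line_scenario")
}

#' Tubular-vessel scenario parameters
#'
#' @param R Vessel radius in um (study range 120-720).
#' @param U_max Centerline speed in cm/s (default 5); the prescribed profile
#'   is parabolic, `U_ref(r) = U_max (1 - (r/R)^2)`.
#' @param steps Number of time steps (default 5000).
#' @param mean_spacing Mean along-axis bubble spacing in um (default 330).
#' @param orientation `"aligned"` or `"perpendicular"` to the PSF major axis.
#' @return A list of class `ulm_vessel_scenario`.
#' @export
vessel_scenario <- function(R, U_max = 5, steps = 5000, mean_spacing = 330,
                            orientation = c("aligned", "perpendicular")) {
  orientation <- match.arg(orientation)
  if (R <= 0) stop("radius must be positive")
  structure(list(R = R, U_max = U_max, steps = as.integer(steps),
                 mean_spacing = mean_spacing, orientation = orientation),
            class = "ulm_vessel_scenario")
}

#' Prescribed parabolic velocity profile
#'
#' @param r Radial coordinate(s) in um.
#' @param scenario A [vessel_scenario()].
#' @return Speed in um/s (`U_max` is given in cm/s); zero at `|r| = R`.
#' @export
vessel_u_ref <- function(r, scenario) {
  u <- scenario$U_max * 1e4 * (1 - (r / scenario$R)^2)
  pmax(u, 0)
}

# direction/normal unit vectors (depth, lateral components) for a scenario
# orientation relative to the PSF major axis
scenario_axes <- function(orientation, psf) {
  phi <- psf$orientation * pi / 180
  if (orientation == "perpendicular") phi <- phi + pi / 2
  list(d = c(sin(phi), cos(phi)), n = c(cos(phi), -sin(phi)))
}

# t-range for which c0 + t*d + off*n stays inside [margin, ext - margin]
segment_range <- function(c0, d, off_vec, ext, margin = 1e-9) {
  lo <- margin; hi <- ext - margin
  tmin <- -Inf; tmax <- Inf
  for (ax in 1:2) {
    p0 <- c0[ax] + off_vec[ax]
    if (abs(d[ax]) < 1e-12) {
      if (p0 < lo || p0 > hi) return(NULL)
    } else {
      t1 <- (lo - p0) / d[ax]; t2 <- (hi - p0) / d[ax]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  c(tmin, tmax)
}

# draw inlet radial coordinates with density proportional to U_ref(r)
# (flux weighting), by rejection from the uniform proposal
vessel_inlet_r <- function(n, scenario) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(2L * (n - length(out)) + 4L, -scenario$R,
                         scenario$R)
    keep <- stats::runif(length(cand)) <
      vessel_u_ref(cand, scenario) / (scenario$U_max * 1e4)
    out <- c(out, cand[keep])
  }
  out[seq_len(n)]
}

new_scene <- function(frames, truth, grid, psf, noise, scenario) {
  structure(list(frames = frames, truth = truth, grid = grid, psf = psf,
                 noise = noise, scenario = scenario), class = "ulm_scene")
}

#' @export
print.ulm_scene <- function(x, ...) {
  cat(sprintf("<ulm_scene> %d frames, %d truth records\n",
              if (is.null(x$frames)) 0L else length(x$frames),
              nrow(x$truth)))
  invisible(x)
}

#' Simulate bubbles moving along two parallel lines
#'
#' Bubbles appear on each line by an independent Poisson arrival process,
#' advect at constant speed, and leave at the far end of the field of view.
#' Per-frame ground-truth positions are recorded; frames are rendered through
#' [synthesize_frame()] unless `render = FALSE`.
#'
#' @param scenario A [line_scenario()].
#' @param psf,noise,grid Scene ingredients; see [synthesize_frame()].
#' @param seed Optional integer seed.
#' @param render Render image frames (default TRUE).
#' @return An `ulm_scene` with `frames` (list of matrices or NULL), `truth`
#'   (tibble: frame, id, line, depth_um, lateral_um, intensity), and the
#'   scenario metadata.
#' @export
simulate_lines <- function(scenario, psf, noise = NULL, grid = grid_spec(),
                           seed = NULL, render = TRUE) {
  stopifnot(inherits(scenario, "ulm_line_scenario"))
  if (!is.null(seed)) set.seed(seed)
  ext <- grid_extent_um(grid)
  ax <- scenario_axes(scenario$orientation, psf)
  c0 <- c(ext / 2, ext / 2)
  offs <- list(-scenario$D_l / 2 * ax$n, scenario$D_l / 2 * ax$n)
  rng <- lapply(offs, function(o) segment_range(c0, ax$d, o, ext))
  if (any(vapply(rng, is.null, logical(1))))
    stop("lines fall outside the field of view")
  step <- scenario$speed * 1000 * grid$frame_interval  # um per frame
  state <- tibble::tibble(id = integer(), line = integer(), t = numeric(),
                          intensity = numeric())
  next_id <- 1L
  frames <- if (render) vector("list", scenario$steps) else NULL
  truth_list <- vector("list", scenario$steps)
  for (f in seq_len(scenario$steps)) {
    state$t <- state$t + step
    # drop bubbles that left their line segment
    keep <- state$t <= vapply(state$line, function(l) rng[[l]][2], numeric(1))
    state <- state[keep, , drop = FALSE]
    for (l in 1:2) {
      n_new <- stats::rpois(1, scenario$arrival_rate)
      if (n_new > 0) {
        state <- dplyr::bind_rows(state, tibble::tibble(
          id = next_id + seq_len(n_new) - 1L, line = l,
          t = rng[[l]][1] + stats::runif(n_new) * step,
          intensity = stats::runif(n_new, 0.6, 1)))
        next_id <- next_id + n_new
      }
    }
    pos_d <- c0[1] + state$t * ax$d[1] +
      vapply(state$line, function(l) offs[[l]][1], numeric(1))
    pos_l <- c0[2] + state$t * ax$d[2] +
      vapply(state$line, function(l) offs[[l]][2], numeric(1))
    tr <- tibble::tibble(frame = f, id = state$id, line = state$line,
                         depth_um = pos_d, lateral_um = pos_l,
                         intensity = state$intensity)
    truth_list[[f]] <- tr
    if (render)
      frames[[f]] <- synthesize_frame(
        bubbles(tr$depth_um, tr$lateral_um, tr$intensity), psf, noise,
        grid)$frame
  }
  new_scene(frames, dplyr::bind_rows(truth_list), grid, psf, noise, scenario)
}

#' Simulate bubbles flowing through a tubular vessel
#'
#' Each bubble keeps its radial coordinate (uniform over the lumen) and moves
#' along the vessel axis at the locally prescribed parabolic speed. Bubbles
#' leaving the field of view are replaced at the inlet so that the mean
#' along-axis spacing stays near `mean_spacing`.
#'
#' @inheritParams simulate_lines
#' @param scenario A [vessel_scenario()].
#' @return An `ulm_scene`; `truth` adds an `r_um` column with the signed
#'   radial coordinate.
#' @export
simulate_vessel <- function(scenario, psf, noise = NULL, grid = grid_spec(),
                            seed = NULL, render = TRUE) {
  stopifnot(inherits(scenario, "ulm_vessel_scenario"))
  if (!is.null(seed)) set.seed(seed)
  if (scenario$R < grid$native_pixel)
    stop("vessel radius below one native pixel")
  ext <- grid_extent_um(grid)
  ax <- scenario_axes(scenario$orientation, psf)
  c0 <- c(ext / 2, ext / 2)
  rng <- segment_range(c0, ax$d, c(0, 0), ext)
  if (is.null(rng)) stop("vessel axis outside the field of view")
  # radial extent must also fit
  if (is.null(segment_range(c0, ax$d, scenario$R * ax$n, ext)) ||
      is.null(segment_range(c0, ax$d, -scenario$R * ax$n, ext)))
    stop("vessel lumen outside the field of view")
  n_b <- max(1L, round((rng[2] - rng[1]) / scenario$mean_spacing))
  state <- tibble::tibble(
    id = seq_len(n_b),
    t = stats::runif(n_b, rng[1], rng[2]),
    r = stats::runif(n_b, -scenario$R, scenario$R),
    intensity = stats::runif(n_b, 0.6, 1))
  next_id <- n_b + 1L
  frames <- if (render) vector("list", scenario$steps) else NULL
  truth_list <- vector("list", scenario$steps)
  for (f in seq_len(scenario$steps)) {
    state$t <- state$t + vessel_u_ref(state$r, scenario) * grid$frame_interval
    gone <- state$t > rng[2]
    if (any(gone)) {  # respawn at the inlet as new bubbles
      n_new <- sum(gone)
      state$id[gone] <- next_id + seq_len(n_new) - 1L
      next_id <- next_id + n_new
      state$t[gone] <- rng[1] + stats::runif(n_new) *
        pmax(state$t[gone] - rng[2], 1)
      # inlet flux density is proportional to U(r) for a spatially uniform
      # bubble concentration (exits are flux-weighted, so uniform respawn
      # would pile bubbles up in the slow near-wall lanes)
      state$r[gone] <- vessel_inlet_r(n_new, scenario)
      state$intensity[gone] <- stats::runif(n_new, 0.6, 1)
    }
    pos_d <- c0[1] + state$t * ax$d[1] + state$r * ax$n[1]
    pos_l <- c0[2] + state$t * ax$d[2] + state$r * ax$n[2]
    tr <- tibble::tibble(frame = f, id = state$id, r_um = state$r,
                         depth_um = pos_d, lateral_um = pos_l,
                         intensity = state$intensity)
    truth_list[[f]] <- tr
    if (render)
      frames[[f]] <- synthesize_frame(
        bubbles(tr$depth_um, tr$lateral_um, tr$intensity), psf, noise,
        grid)$frame
  }
  new_scene(frames, dplyr::bind_rows(truth_list), grid, psf, noise, scenario)
}
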