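# Vessel-level metrology: trajectory heatmaps, cross-sectional line
# profiling by sums of Gaussians (line location error E_l, width eps_l),
# ghost-line classification from area fraction AF and index of detection ID,
# velocity-profile errors E_u, and vessel-radius estimation E_r.

#' Trajectory heatmap
#'
#' Counts, per super-resolution pixel, the number of distinct tracks whose
#' polyline traverses that pixel (each track contributes at most 1 per
#' pixel).
#'
#' @param tracks `ulm_tracks` tibble.
#' @param grid An [grid_spec()].
#' @return Count matrix at super resolution.
#' @export
track_heatmap <- function(tracks, grid = grid_spec()) {
  n <- grid$window * grid$superres_factor
  pitch <- grid$superres_pixel
  hm <- matrix(0, n, n)
  if (nrow(tracks) == 0) return(hm)
  for (s in split(tracks, tracks$track)) {
    s <- s[order(s$frame), ]
    pix <- integer(0)
    for (i in seq_len(nrow(s) - 1L)) {
      p0 <- c(s$depth_um[i], s$lateral_um[i])
      p1 <- c(s$depth_um[i + 1L], s$lateral_um[i + 1L])
      len <- sqrt(sum((p1 - p0)^2))
      nstep <- max(2L, ceiling(len / (pitch / 2)))
      t <- seq(0, 1, length.out = nstep)
      di <- um_to_pixel(p0[1] + t * (p1[1] - p0[1]), pitch)
      li <- um_to_pixel(p0[2] + t * (p1[2] - p0[2]), pitch)
      ok <- di >= 1 & di <= n & li >= 1 & li <= n
      pix <- c(pix, (li[ok] - 1L) * n + di[ok])
    }
    if (nrow(s) == 1L) {
      di <- um_to_pixel(s$depth_um, pitch); li <- um_to_pixel(s$lateral_um, pitch)
      if (di >= 1 && di <= n && li >= 1 && li <= n)
        pix <- c(pix, (li - 1L) * n + di)
    }
    pix <- unique(pix)
    hm[pix] <- hm[pix] + 1
  }
  hm
}

#' Cross-sectional profile of a heatmap
#'
#' Averages the heatmap along the line axis, returning intensity versus the
#' transverse coordinate in um.
#'
#' @param heatmap Super-resolution count matrix.
#' @param grid An [grid_spec()].
#' @param along `"lateral"` for lines running laterally (profile over
#'   depth), `"depth"` for vertical lines.
#' @return Tibble with `pos_um`, `value`.
#' @export
heatmap_profile <- function(heatmap, grid = grid_spec(),
                            along = c("lateral", "depth")) {
  along <- match.arg(along)
  v <- if (along == "lateral") rowMeans(heatmap) else colMeans(heatmap)
  tibble::tibble(pos_um = (seq_along(v) - 0.5) * grid$superres_pixel,
                 value = v)
}

# local maxima of a smoothed profile (interior, strictly greater than both
# neighbors, above a small floor relative to the profile maximum)
profile_peaks <- function(pos, val, smooth_sigma_px = 1, floor_frac = 0.02) {
  if (smooth_sigma_px > 0) {
    k <- gaussian_kernel_1d(smooth_sigma_px)
    val <- as.numeric(convolve_1d_rows(matrix(val, ncol = 1), k))
  }
  n <- length(val)
  # ">=" on the right so a two-sample plateau yields its first sample
  idx <- which(val[2:(n - 1)] > val[1:(n - 2)] &
                 val[2:(n - 1)] >= val[3:n] &
                 val[2:(n - 1)] > floor_frac * max(val)) + 1L
  tibble::tibble(pos_um = pos[idx], value = val[idx])
}

#' Fit a cross-sectional profile with a sum of Gaussians
#'
#' One Gaussian component per detected peak of the smoothed profile (or per
#' `n_peaks` hint), least-squares fitted. The line width is twice the fitted
#' standard deviation; the line location error is the distance between each
#' primary peak and its nearest true line position.
#'
#' @param profile Tibble from [heatmap_profile()] (`pos_um`, `value`).
#' @param n_peaks Optional number of components; default the number of
#'   detected local maxima.
#' @param true_positions Optional true line positions in um for `E_l`.
#' @param smooth_sigma_px Peak-detection smoothing in super-resolution
#'   pixels (default 1).
#' @return An object of class `ulm_line_fit`: list with `components` tibble
#'   (`line`, `amplitude`, `mu_um`, `sigma_um`, `eps_l_um`, `area`,
#'   `E_l_um`), `profile`, `fitted`, and `converged`.
#' @export
line_profile_fit <- function(profile, n_peaks = NULL, true_positions = NULL,
                             smooth_sigma_px = 1) {
  pos <- profile$pos_um; val <- profile$value
  pk <- profile_peaks(pos, val, smooth_sigma_px)
  if (!is.null(n_peaks) && nrow(pk) > n_peaks)
    pk <- pk[order(-pk$value)[seq_len(n_peaks)], ] |> dplyr::arrange(.data$pos_um)
  if (nrow(pk) == 0)
    return(structure(list(components = tibble::tibble(), profile = profile,
                          fitted = rep(0, length(pos)), converged = FALSE),
                     class = "ulm_line_fit"))
  m <- nrow(pk)
  start <- list(a = pk$value, mu = pk$pos_um,
                s = rep(1.5 * mean(diff(pos)) + 10, m))
  model <- function(p) {
    f <- rep(0, length(pos))
    for (i in seq_len(m))
      f <- f + p$a[i] * exp(-(pos - p$mu[i])^2 / (2 * p$s[i]^2))
    f
  }
  fit <- tryCatch({
    par0 <- unlist(start)
    fn <- function(q) {
      p <- list(a = q[1:m], mu = q[(m + 1):(2 * m)], s = q[(2 * m + 1):(3 * m)])
      model(p) - val
    }
    minpack.lm::nls.lm(par = par0, fn = fn,
                       lower = c(rep(0, m), rep(min(pos), m), rep(2, m)),
                       upper = c(rep(Inf, m), rep(max(pos), m),
                                 rep(diff(range(pos)), m)),
                       control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(structure(list(components = tibble::tibble(), profile = profile,
                          fitted = rep(0, length(pos)), converged = FALSE),
                     class = "ulm_line_fit"))
  }
  q <- unname(fit$par)
  comp <- tibble::tibble(line = seq_len(m), amplitude = q[1:m],
                         mu_um = q[(m + 1):(2 * m)],
                         sigma_um = q[(2 * m + 1):(3 * m)]) |>
    dplyr::arrange(.data$mu_um) |>
    dplyr::mutate(line = dplyr::row_number(),
                  eps_l_um = 2 * .data$sigma_um,
                  area = .data$amplitude * .data$sigma_um * sqrt(2 * pi))
  if (!is.null(true_positions)) {
    comp$E_l_um <- vapply(comp$mu_um, function(mu)
      min(abs(mu - true_positions)), numeric(1))
  }
  structure(list(components = comp, profile = profile,
                 fitted = model(list(a = comp$amplitude, mu = comp$mu_um,
                                     s = comp$sigma_um)),
                 converged = TRUE),
            class = "ulm_line_fit")
}

#' @export
print.ulm_line_fit <- function(x, ...) {
  cat(sprintf("<ulm_line_fit> %d component(s), converged: %s\n",
              nrow(x$components), x$converged))
  if (nrow(x$components)) print(x$components)
  invisible(x)
}

#' Ghost-line features AF and ID
#'
#' `AF` is each fitted component's share of the total fitted area, in
#' percent. `ID` (index of detection) is the profile peak value divided by
#' the linewise standard deviation of the heatmap at the peak's transverse
#' position, normalized by the maximum over lines and scaled to 0-100; it
#' measures structural continuity along the line (dim or intermittent
#' structures score low). A zero standard deviation flags an infinite raw
#' ratio, clamped to 100 after normalization.
#'
#' @param fit An `ulm_line_fit`.
#' @param heatmap The heatmap the profile came from.
#' @param grid An [grid_spec()].
#' @param along Line axis as in [heatmap_profile()].
#' @return The components tibble of `fit` with `AF` and `ID` columns added.
#' @export
ghost_features <- function(fit, heatmap, grid = grid_spec(),
                           along = c("lateral", "depth")) {
  along <- match.arg(along)
  stopifnot(inherits(fit, "ulm_line_fit"), fit$converged)
  comp <- fit$components
  comp$AF <- 100 * comp$area / sum(comp$area)
  n <- if (along == "lateral") nrow(heatmap) else ncol(heatmap)
  ratio <- vapply(seq_len(nrow(comp)), function(i) {
    px <- min(max(um_to_pixel(comp$mu_um[i], grid$superres_pixel), 1L), n)
    lv <- if (along == "lateral") heatmap[px, ] else heatmap[, px]
    s <- stats::sd(lv)
    if (s == 0) Inf else mean(lv) / s
  }, numeric(1))
  if (all(is.infinite(ratio))) {
    comp$ID <- rep(100, nrow(comp))
  } else {
    mx <- max(ratio[is.finite(ratio)])
    comp$ID <- pmin(100 * ratio / mx, 100)
    comp$ID[is.infinite(ratio)] <- 100
  }
  comp
}

#' Ghost-line classification rule
#'
#' Linear decision rule `0.10 AF + 0.038 ID - 4.64`, with scores below zero
#' classified as negligible ghost lines (the negative hyperplane of the
#' maximum-margin boundary fitted to labeled synthetic line studies). Both
#' features are on the 0-100 scale.
#'
#' @param AF,ID Numeric vectors on the 0-100 scale.
#' @param rule Coefficients `c(w_AF, w_ID, b)` (default
#'   `c(0.10, 0.038, -4.64)`).
#' @return Tibble with `AF`, `ID`, `score`, `class`
#'   (`negligible`/`nonnegligible`); a score of exactly zero is
#'   nonnegligible.
#' @examples
#' classify_ghost(10, 50)  # score -1.74, negligible
#' classify_ghost(30, 60)  # score  0.64, nonnegligible
#' @export
classify_ghost <- function(AF, ID, rule = c(0.10, 0.038, -4.64)) {
  score <- rule[1] * AF + rule[2] * ID + rule[3]
  tibble::tibble(AF = AF, ID = ID, score = score,
                 class = ifelse(score < 0, "negligible", "nonnegligible"))
}

#' Fit a maximum-margin ghost-line boundary
#'
#' Linear support-vector classifier on labeled (AF, ID) points; the shipped
#' default rule of [classify_ghost()] remains unchanged, this refits the
#' boundary for user data. The returned `negative_hyperplane` is the margin
#' line on the ghost-negligible side.
#'
#' @param points Tibble with `AF`, `ID`, and logical/character `ghost`
#'   column (TRUE / "ghost" for ghost lines).
#' @param cost SVM cost parameter (default 100; large = near-hard margin).
#' @return List of class `ulm_ghost_boundary`: `w`, `b` (decision line
#'   `w[1] AF + w[2] ID + b = 0`), `negative_hyperplane` coefficients, and
#'   the support-vector indices.
#' @export
fit_ghost_boundary <- function(points, cost = 100) {
  y <- points$ghost
  if (is.character(y)) y <- y %in% c("ghost", "TRUE", "nonnegligible")
  if (length(unique(y)) < 2) stop("need both classes to fit a boundary")
  X <- as.matrix(points[, c("AF", "ID")])
  fit <- e1071::svm(X, factor(y, levels = c(FALSE, TRUE)),
                    kernel = "linear", scale = FALSE, cost = cost,
                    type = "C-classification")
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient so that larger AF/ID (ghost side) gives positive scores
  if (w[1] + w[2] < 0) { w <- -w; b <- -b }
  structure(list(w = w, b = b,
                 negative_hyperplane = c(w, b + 1),
                 support = fit$index),
            class = "ulm_ghost_boundary")
}

#' Five-category separation outcome of a line pair
#'
#' Classifies a fitted cross-sectional profile as `unseparated`,
#' `overlapped`, `nonnegligible_ghost`, `negligible_ghost`, or
#' `fully_separated`. Two peaks whose trough exceeds 95% of the primary
#' line intensity count as unseparated; a trough below `floor_frac` of the
#' primary peak is fully separated; interior (ghost) components are judged
#' by [classify_ghost()].
#'
#' @param fit An `ulm_line_fit` (converged).
#' @param heatmap Heatmap used for the ID feature when a ghost is present.
#' @param grid An [grid_spec()].
#' @param along Line axis.
#' @param floor_frac Fully-separated trough floor as a fraction of the
#'   primary peak (default 0.05).
#' @return Character category.
#' @export
classify_separation <- function(fit, heatmap = NULL, grid = grid_spec(),
                                along = "lateral", floor_frac = 0.05) {
  if (!fit$converged || nrow(fit$components) == 0) return("unseparated")
  comp <- fit$components
  m <- nrow(comp)
  if (m == 1) return("unseparated")
  pos <- fit$profile$pos_um; val <- fit$profile$value
  if (m == 2) {
    primary <- min(comp$amplitude)
    between <- pos > min(comp$mu_um) & pos < max(comp$mu_um)
    if (!any(between)) return("unseparated")
    trough <- min(val[between])
    if (trough > 0.95 * primary) return("unseparated")
    if (trough < floor_frac * primary) return("fully_separated")
    return("overlapped")
  }
  # three or more peaks: interior components are ghost candidates
  feats <- ghost_features(fit, heatmap, grid, along)
  interior <- feats[-c(1, nrow(feats)), , drop = FALSE]
  cls <- classify_ghost(interior$AF, interior$ID)
  if (any(cls$class == "nonnegligible")) "nonnegligible_ghost"
  else "negligible_ghost"
}

#' Radial velocity profile and its error
#'
#' Bins per-sample track speeds by the signed radial coordinate relative to
#' the vessel axis and compares with the prescribed parabolic profile.
#' The error proxy `|dU_ref/dr * E_c / U_ref|` is included when a
#' localization error scale is supplied.
#'
#' @param tracks `ulm_tracks` tibble.
#' @param scenario A [vessel_scenario()].
#' @param psf The scene PSF (fixes the vessel axis orientation).
#' @param grid An [grid_spec()].
#' @param bin_width Radial bin width in um (default one super-resolution
#'   pixel, 20 um).
#' @param E_c Optional localization error scale in um for the proxy.
#' @param stat Bin estimator: `"median"` (default; robust against the rare
#'   mis-association outliers of fast-flow tracking) or `"mean"`.
#' @param accel_max Steady-flow consistency bound passed to
#'   [track_speeds()], in um/frame (default 150).
#' @param straight_resid_max Straightness bound passed to
#'   [filter_straight_tracks()], in um (default 30; `Inf` disables).
#' @return Tibble of class `ulm_vessel_profile`: `r_um`, `n`, `U_m`,
#'   `U_ref` (um/s), `E_u`, and `proxy` when `E_c` is given; empty bins are
#'   kept with `n = 0`.
#' @export
velocity_profile <- function(tracks, scenario, psf, grid = grid_spec(),
                             bin_width = NULL, E_c = NULL,
                             stat = c("median", "mean"),
                             accel_max = 150, straight_resid_max = 30) {
  stat <- match.arg(stat)
  if (is.finite(straight_resid_max))
    tracks <- filter_straight_tracks(tracks, straight_resid_max)
  if (is.null(bin_width)) bin_width <- grid$superres_pixel
  ax <- scenario_axes(scenario$orientation, psf)
  ext <- grid_extent_um(grid)
  c0 <- c(ext / 2, ext / 2)
  sp <- track_speeds(tracks, grid, accel_max = accel_max)
  sp$r_um <- (sp$depth_um - c0[1]) * ax$n[1] +
    (sp$lateral_um - c0[2]) * ax$n[2]
  edges <- seq(-scenario$R, scenario$R, by = bin_width)
  if (edges[length(edges)] < scenario$R) edges <- c(edges, scenario$R)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- cut(sp$r_um, edges, include.lowest = TRUE)
  um <- tapply(sp$speed_um_s, bin,
               if (stat == "median") function(v) stats::median(v, na.rm = TRUE)
               else function(v) mean(v, na.rm = TRUE))
  nn <- tapply(!is.na(sp$speed_um_s), bin, sum)
  out <- tibble::tibble(
    r_um = mids,
    n = as.integer(ifelse(is.na(nn), 0L, nn)),
    U_m = as.numeric(um),
    U_ref = vessel_u_ref(mids, scenario))
  out$E_u <- abs((out$U_m - out$U_ref) / out$U_ref)
  if (!is.null(E_c)) {
    dudr <- -2 * scenario$U_max * 1e4 * mids / scenario$R^2
    out$proxy <- abs(dudr * E_c / out$U_ref)
  }
  attr(out, "scenario") <- scenario
  class(out) <- c("ulm_vessel_profile", class(out))
  out
}

#' Estimate the vessel radius from a radial profile
#'
#' Fits `y = a (1 - (r/R)^2)` by least squares and reports the zero
#' crossing as the measured radius (`velocity_parabola` on binned speeds,
#' `trackcount_parabola` on track counts). The `trackcount_gaussian`
#' method fits a Gaussian and reports sigma-based widths for comparison
#' only (`R_m = 2 sigma`).
#'
#' @param r Radial coordinates in um.
#' @param y Profile values (speeds or counts); `NA` bins are dropped.
#' @param method One of `velocity_parabola`, `trackcount_parabola`,
#'   `trackcount_gaussian`.
#' @param R_true Optional prescribed radius for `E_r`.
#' @return One-row tibble: `method`, `R_m_um`, `E_r`, `peak`, `sigma_um`.
#' @export
estimate_radius <- function(r, y,
                            method = c("velocity_parabola",
                                       "trackcount_parabola",
                                       "trackcount_gaussian"),
                            R_true = NULL) {
  method <- match.arg(method)
  ok <- is.finite(r) & is.finite(y)
  r <- r[ok]; y <- y[ok]
  if (length(r) < 3) stop("too few profile points")
  if (method == "trackcount_gaussian") {
    fit <- minpack.lm::nlsLM(y ~ A * exp(-r^2 / (2 * s^2)),
                             start = list(A = max(y),
                                          s = max(abs(r)) / 2),
                             lower = c(0, 1))
    s <- stats::coef(fit)[["s"]]
    Rm <- 2 * s
  } else {
    fit <- stats::lm(y ~ I(r^2))
    a <- stats::coef(fit)[1]; b <- stats::coef(fit)[2]
    if (b >= 0 || a <= 0)
      stop("concave-up parabolic fit: no zero crossing")
    Rm <- sqrt(-a / b)
    s <- NA_real_
    names(Rm) <- NULL
  }
  tibble::tibble(
    method = method, R_m_um = as.numeric(Rm),
    E_r = if (is.null(R_true)) NA_real_ else abs((Rm - R_true) / R_true),
    peak = max(y), sigma_um = as.numeric(s))
}

#' Power-law fit in log-log space
#'
#' Least-squares line on `log(y) ~ log(x)`; used for the scaling of the
#' normalized line errors with the PSF-to-spacing ratio.
#'
#' @param x,y Positive numeric vectors.
#' @return One-row tibble: `coefficient`, `exponent`, `r_squared`.
#' @examples
#' power_law_fit(1:10, 2 * (1:10)^3)  # coefficient 2, exponent 3
#' @export
power_law_fit <- function(x, y) {
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit needs positive data")
  fit <- stats::lm(log(y) ~ log(x))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  tibble::tibble(coefficient = exp(stats::coef(fit)[[1]]),
                 exponent = stats::coef(fit)[[2]],
                 r_squared = r2)
}
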