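# Localization accuracy metrics: center error E_c, false-detection
# percentage eta, normalized pair separation D*, PSF quality Q, and the SNR
# of the intensity / gradient / Hessian measurement channels.

#' Localization error and false-detection rate
#'
#' For each true center the distance to the nearest detection contributes to
#' `E_c`; when one true center attracts several detections (a falsely split
#' pair), every such detection's distance contributes. A true center with no
#' detections contributes its distance to the nearest detection anywhere.
#' `eta` is the percentage of detections left unmatched by the optimal
#' one-to-one truth-detection assignment within the gate (detections are the
#' denominator).
#'
#' @param truth Tibble with `depth_um`, `lateral_um` (one frame).
#' @param detections Tibble with `depth_um`, `lateral_um` (same frame).
#' @param gate Matching gate in um; defaults to half the PSF minor FWHM when
#'   `psf` is given, else 150 um.
#' @param psf Optional `ulm_psf` used to derive the default gate
#'   (`fwhm_minor / 2`).
#' @param grid An [grid_spec()]; supplies the wavelength for the
#'   lambda-fraction error.
#' @return One-row tibble: `E_c_um`, `E_c_lambda`, `E_c_sd_um`, `eta_pct`,
#'   `n_truth`, `n_det`, `n_matched`.
#' @examples
#' tr <- bubbles(c(0, 0), c(0, 100))
#' localization_error(tr, bubbles(0, 0), gate = 50)  # E_c = 50 um
#' @export
localization_error <- function(truth, detections, gate = NULL, psf = NULL,
                               grid = grid_spec()) {
  if (nrow(truth) == 0) stop("empty truth set")
  if (is.null(gate))
    gate <- if (!is.null(psf)) psf$fwhm_minor / 2 else 150
  nt <- nrow(truth); nd <- nrow(detections)
  if (nd == 0) {
    return(tibble::tibble(E_c_um = NA_real_, E_c_lambda = NA_real_,
                          E_c_sd_um = NA_real_, eta_pct = NA_real_,
                          n_truth = nt, n_det = 0L, n_matched = 0L))
  }
  D <- outer(truth$depth_um, detections$depth_um, `-`)^2 +
    outer(truth$lateral_um, detections$lateral_um, `-`)^2
  D <- sqrt(D)  # nt x nd
  # each detection votes for its nearest true center
  owner <- apply(D, 2, which.min)
  dists <- numeric(0)
  for (i in seq_len(nt)) {
    mine <- which(owner == i)
    dists <- c(dists, if (length(mine)) D[i, mine] else min(D[i, ]))
  }
  matched <- hungarian_match(D, gate)
  n_matched <- nrow(matched)
  tibble::tibble(E_c_um = mean(dists),
                 E_c_lambda = mean(dists) / grid$wavelength,
                 E_c_sd_um = stats::sd(dists),
                 eta_pct = 100 * (nd - n_matched) / nd,
                 n_truth = nt, n_det = nd, n_matched = n_matched)
}

#' Pool localization reports over frames
#'
#' Convenience wrapper applying [localization_error()] per frame and
#' averaging with detection/truth counts.
#'
#' @param truth,detections Tibbles with a `frame` column.
#' @inheritParams localization_error
#' @return One-row tibble as [localization_error()], pooled over frames
#'   (`E_c` weighted by per-frame contribution counts).
#' @export
localization_error_frames <- function(truth, detections, gate = NULL,
                                      psf = NULL, grid = grid_spec()) {
  per <- lapply(split(truth, truth$frame), function(tr) {
    det <- detections[detections$frame == tr$frame[1], , drop = FALSE]
    localization_error(tr, det, gate, psf, grid)
  })
  per <- dplyr::bind_rows(per)
  ok <- !is.na(per$E_c_um)
  w <- per$n_truth[ok]
  tibble::tibble(
    E_c_um = sum(per$E_c_um[ok] * w) / sum(w),
    E_c_lambda = sum(per$E_c_um[ok] * w) / sum(w) / grid$wavelength,
    E_c_sd_um = stats::sd(rep(per$E_c_um[ok], w)),
    eta_pct = 100 * (sum(per$n_det) - sum(per$n_matched)) /
      max(sum(per$n_det), 1L),
    n_truth = sum(per$n_truth), n_det = sum(per$n_det),
    n_matched = sum(per$n_matched))
}

#' Normalized separation of a bubble pair
#'
#' Center-to-center distance divided by the PSF FWHM length along the line
#' connecting the two centers.
#'
#' @param c1,c2 Numeric `c(depth_um, lateral_um)` positions.
#' @param psf An `ulm_psf`.
#' @return Dimensionless `D*`.
#' @export
normalized_separation <- function(c1, c2, psf) {
  d <- sqrt(sum((c1 - c2)^2))
  if (d == 0) stop("coincident centers")
  ang <- atan2(c2[1] - c1[1], c2[2] - c1[2]) * 180 / pi
  d / psf_fwhm_length(psf, ang)
}

#' Label a two-bubble trial as separated or not
#'
#' A trial is separated when at least two detections exist and the optimal
#' one-to-one assignment within the gate matches both true centers.
#'
#' @param truth Two-row truth tibble.
#' @param detections Detection tibble for the same frame.
#' @param gate Gate in um (default half the PSF minor FWHM via `psf`).
#' @param psf Optional `ulm_psf` for the default gate.
#' @return Logical.
#' @export
pair_separated <- function(truth, detections, gate = NULL, psf = NULL) {
  stopifnot(nrow(truth) == 2)
  if (is.null(gate))
    gate <- if (!is.null(psf)) psf$fwhm_minor / 2 else 150
  if (nrow(detections) < 2) return(FALSE)
  D <- sqrt(outer(truth$depth_um, detections$depth_um, `-`)^2 +
              outer(truth$lateral_um, detections$lateral_um, `-`)^2)
  nrow(hungarian_match(D, gate)) == 2
}

#' Failure-fraction curve over normalized separation bins
#'
#' Bins pair trials by `D*` and reports the percentage of unseparated pairs
#' per bin with exact binomial confidence intervals.
#'
#' @param trials Tibble with columns `D_star` and `separated` (logical).
#' @param breaks Bin edges for `D*` (default 0 to 2 by 0.1).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble: `bin_lo`, `bin_hi`, `bin_mid`, `n`, `pct_unseparated`,
#'   `ci_lo`, `ci_hi`; empty bins are flagged with `n = 0` and `NA` rates.
#' @export
separation_stats <- function(trials, breaks = seq(0, 2, by = 0.1),
                             conf_level = 0.95) {
  bin <- cut(trials$D_star, breaks, include.lowest = TRUE)
  levs <- levels(bin)
  out <- lapply(seq_along(levs), function(i) {
    sel <- !is.na(bin) & bin == levs[i]
    n <- sum(sel)
    if (n == 0)
      return(tibble::tibble(bin_lo = breaks[i], bin_hi = breaks[i + 1],
                            bin_mid = (breaks[i] + breaks[i + 1]) / 2,
                            n = 0L, pct_unseparated = NA_real_,
                            ci_lo = NA_real_, ci_hi = NA_real_))
    k <- sum(!trials$separated[sel])
    ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
    tibble::tibble(bin_lo = breaks[i], bin_hi = breaks[i + 1],
                   bin_mid = (breaks[i] + breaks[i + 1]) / 2,
                   n = n, pct_unseparated = 100 * k / n,
                   ci_lo = 100 * ci[1], ci_hi = 100 * ci[2])
  })
  dplyr::bind_rows(out)
}

#' PSF estimation quality Q
#'
#' Pearson correlation between the intensity distributions of a true and an
#' estimated PSF, after aligning their intensity centroids on a common grid.
#'
#' @param true,est `ulm_psf` objects sampled at the same native pitch.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
psf_quality <- function(true, est) {
  a <- true$kernel_native
  b <- est$kernel_native
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant kernel image: correlation undefined")
  cen <- function(m) {
    w <- sum(m)
    c(sum(row(m) * m) / w, sum(col(m) * m) / w)
  }
  sh <- round(cen(a) - cen(b))
  # overlap of a with b shifted by sh
  ra <- max(1, 1 + sh[1]):min(nrow(a), nrow(b) + sh[1])
  ca <- max(1, 1 + sh[2]):min(ncol(a), ncol(b) + sh[2])
  if (!length(ra) || !length(ca)) stop("kernels do not overlap")
  stats::cor(as.vector(a[ra, ca]),
             as.vector(b[ra - sh[1], ca - sh[2]]))
}

#' SNR of the intensity, gradient, and Hessian channels
#'
#' For each channel the SNR is the RMS of the clean channel divided by the
#' RMS of the channel difference between clean and noisy images. Hessian
#' channels are the per-pixel eigenvalue magnitudes of the 2 x 2
#' finite-difference Hessian.
#'
#' @param clean,noisy Equal-size matrices.
#' @return Tibble with `channel` (`intensity`, `gradient`, `hessian_e1`,
#'   `hessian_e2`), `snr`, and `infinite` flag (noise-free input).
#' @export
snr_channels <- function(clean, noisy) {
  stopifnot(all(dim(clean) == dim(noisy)))
  rms <- function(x) sqrt(mean(x^2))
  chan <- function(img) {
    gimg <- grad_central(img)
    eig <- hessian_eigen_mags(img)
    list(intensity = img, gradient = sqrt(gimg$d^2 + gimg$l^2),
         e1 = eig$e1, e2 = eig$e2)
  }
  cc <- chan(clean); cn <- chan(noisy)
  snr_of <- function(a, b) {
    d <- rms(b - a)
    if (d == 0) Inf else rms(a) / d
  }
  s <- c(snr_of(cc$intensity, cn$intensity),
         snr_of(cc$gradient, cn$gradient),
         snr_of(cc$e1, cn$e1), snr_of(cc$e2, cn$e2))
  tibble::tibble(channel = c("intensity", "gradient", "hessian_e1",
                             "hessian_e2"),
                 snr = s, infinite = !is.finite(s))
}
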