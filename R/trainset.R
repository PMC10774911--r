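# Training data: random scenes spanning bubble concentration, intensity,
# PSF rotation/resize, and noise-level ranges, paired with blurred
# super-resolution reference center maps.

#' Base PSF pools
#'
#' `training_psf_pool()` returns the base shapes used for training-set
#' augmentation; `evaluation_psf_ladder()` returns the five increasingly
#' elongated evaluation PSFs (FWHM 263-561 um, aspect ratio 1.20-1.81),
#' which are excluded from the training pool.
#'
#' @param grid An [grid_spec()].
#' @param orientation Major-axis orientation in degrees (default 0,
#'   lateral); use 90 for the rotated-PSF generalization studies.
#' @param family PSF family passed to [make_psf()].
#' @return A list of `ulm_psf` objects.
#' @export
training_psf_pool <- function(grid = grid_spec(), orientation = 0,
                              family = "gaussian") {
  majors <- c(250, 350, 450, 550, 650)
  ars <- c(1.15, 1.3, 1.45, 1.6, 1.75)
  purrr::map2(majors, ars, function(m, a)
    make_psf(m, m / a, orientation, family, grid))
}

#' @rdname training_psf_pool
#' @export
evaluation_psf_ladder <- function(grid = grid_spec(), orientation = 0,
                                  family = "gaussian") {
  majors <- c(263, 320, 400, 500, 561)
  ars <- c(1.20, 1.35, 1.50, 1.65, 1.81)
  purrr::map2(majors, ars, function(m, a)
    make_psf(m, m / a, orientation, family, grid))
}

#' Draw a random bubble field at a given concentration
#'
#' Poisson-distributed count at `concentration * area`, uniform positions,
#' intensities uniform in `[0.6, 1]`.
#'
#' @param concentration Bubbles per mm^2.
#' @param grid An [grid_spec()].
#' @return A bubble tibble.
#' @export
random_bubbles <- function(concentration, grid = grid_spec()) {
  ext <- grid_extent_um(grid)
  n <- stats::rpois(1, concentration * grid_area_mm2(grid))
  bubbles(stats::runif(n, 0, ext), stats::runif(n, 0, ext),
          stats::runif(n, 0.6, 1))
}

#' Build a supervised training set
#'
#' Generates `n_pairs` of (native input frame, super-resolution reference
#' map) pairs. Per pair: concentration uniform in `conc_range` mm^-2, bubble
#' intensities in `[0.6, 1]`, PSF drawn from `psf_pool` with a random
#' rotation in `[-20, 20]` degrees and resize factor in `[0.8, 2]`, and a
#' noise peak drawn from `{0.10, 0.15, 0.20, 0.25}` with 0.15 most frequent.
#' Deterministic for a fixed seed.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param psf_pool List of base `ulm_psf` objects
#'   (default [training_psf_pool()]).
#' @param grid An [grid_spec()].
#' @param conc_range Concentration range in mm^-2 (default `c(0.1, 1)`).
#' @param rotation_range Degrees (default `c(-20, 20)`).
#' @param resize_range PSF resize factors (default `c(0.8, 2)`).
#' @param noise_levels,noise_probs Noise-peak choices and sampling weights.
#' @param psf_variants Number of distinct augmented PSFs to prebuild and
#'   sample from (kernel construction is the dominant cost; default 256).
#' @param seed Optional integer seed.
#' @return An `ulm_dataset`: lists `inputs` (window^2 matrices), `refs`
#'   (super-resolution matrices), and a `meta` tibble.
#' @export
build_training_set <- function(n_pairs, psf_pool = NULL, grid = grid_spec(),
                               conc_range = c(0.1, 1),
                               rotation_range = c(-20, 20),
                               resize_range = c(0.8, 2),
                               noise_levels = c(0.10, 0.15, 0.20, 0.25),
                               noise_probs = c(0.2, 0.4, 0.2, 0.2),
                               psf_variants = 256L, seed = NULL) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (is.null(psf_pool)) psf_pool <- training_psf_pool(grid)
  if (!length(psf_pool)) stop("empty PSF pool")
  if (!is.null(seed)) set.seed(seed)
  n_var <- min(as.integer(psf_variants), n_pairs)
  variants <- vector("list", n_var)
  var_meta <- tibble::tibble(base = integer(n_var), rotation = numeric(n_var),
                             resize = numeric(n_var))
  min_fwhm <- 2 * grid$native_pixel
  for (v in seq_len(n_var)) {
    b <- sample.int(length(psf_pool), 1)
    rot <- stats::runif(1, rotation_range[1], rotation_range[2])
    rs <- stats::runif(1, resize_range[1], resize_range[2])
    base <- psf_pool[[b]]
    variants[[v]] <- make_psf(max(base$fwhm_major * rs, min_fwhm),
                              max(base$fwhm_minor * rs, min_fwhm),
                              base$orientation + rot, base$family, grid)
    var_meta$base[v] <- b; var_meta$rotation[v] <- rot; var_meta$resize[v] <- rs
  }
  inputs <- vector("list", n_pairs)
  refs <- vector("list", n_pairs)
  meta <- tibble::tibble(pair = seq_len(n_pairs), psf_variant = integer(n_pairs),
                         concentration = numeric(n_pairs),
                         noise_peak = numeric(n_pairs),
                         n_bubbles = integer(n_pairs))
  for (p in seq_len(n_pairs)) {
    v <- if (n_var == n_pairs) p else sample.int(n_var, 1)
    conc <- stats::runif(1, conc_range[1], conc_range[2])
    peak <- sample(noise_levels, 1, prob = noise_probs)
    bub <- random_bubbles(conc, grid)
    fr <- synthesize_frame(bub, variants[[v]], noise_spec(peak), grid)
    inputs[[p]] <- fr$frame
    refs[[p]] <- make_reference_map(bub, grid)
    meta$psf_variant[p] <- v; meta$concentration[p] <- conc
    meta$noise_peak[p] <- peak; meta$n_bubbles[p] <- nrow(bub)
  }
  structure(list(inputs = inputs, refs = refs, meta = meta,
                 psf_meta = var_meta, grid = grid),
            class = "ulm_dataset")
}

#' @export
print.ulm_dataset <- function(x, ...) {
  cat(sprintf("<ulm_dataset> %d pairs, input %dx%d -> reference %dx%d\n",
              length(x$inputs), nrow(x$inputs[[1]]), ncol(x$inputs[[1]]),
              nrow(x$refs[[1]]), ncol(x$refs[[1]])))
  invisible(x)
}
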