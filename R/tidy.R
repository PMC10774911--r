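# broom-style accessors for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a line-profile fit
#'
#' @param x An `ulm_line_fit`.
#' @param ... Unused.
#' @return The components tibble (one row per Gaussian component).
#' @method tidy ulm_line_fit
#' @export
tidy.ulm_line_fit <- function(x, ...) x$components

#' @rdname tidy.ulm_line_fit
#' @method glance ulm_line_fit
#' @export
glance.ulm_line_fit <- function(x, ...) {
  res <- x$profile$value - x$fitted
  tibble::tibble(n_components = nrow(x$components),
                 converged = x$converged,
                 sigma = stats::sd(res),
                 r_squared = if (stats::var(x$profile$value) > 0)
                   1 - stats::var(res) / stats::var(x$profile$value)
                 else NA_real_)
}

#' Tidy a supervised training fit
#'
#' @param x A `supbd_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @method tidy supbd_fit
#' @export
tidy.supbd_fit <- function(x, ...) x$history

#' @rdname tidy.supbd_fit
#' @method glance supbd_fit
#' @export
glance.supbd_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val)
}

#' Tidy a k-net adaptation
#'
#' @param x A `selfbd_adapt`.
#' @param ... Unused.
#' @return The per-iteration history tibble.
#' @method tidy selfbd_adapt
#' @export
tidy.selfbd_adapt <- function(x, ...) x$history

#' @rdname tidy.selfbd_adapt
#' @method glance selfbd_adapt
#' @export
glance.selfbd_adapt <- function(x, ...) {
  tibble::tibble(iterations = nrow(x$history),
                 final_loss = x$history$loss[nrow(x$history)],
                 fwhm_major = x$psf$fwhm_major,
                 fwhm_minor = x$psf$fwhm_minor,
                 AR = x$psf$AR)
}

#' Tidy a ghost-line boundary fit
#'
#' @param x An `ulm_ghost_boundary`.
#' @param ... Unused.
#' @return One-row tibble with the decision-line coefficients.
#' @method tidy ulm_ghost_boundary
#' @export
tidy.ulm_ghost_boundary <- function(x, ...) {
  tibble::tibble(w_AF = x$w[1], w_ID = x$w[2], intercept = x$b,
                 n_support = length(x$support))
}
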