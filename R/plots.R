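# ggplot2 displays for the main result types.

#' Plot a CEUS frame or map
#'
#' @param img Matrix (native frame, scatter map, likelihood map, heatmap).
#' @param pitch Pixel pitch in um (default 60).
#' @param title Optional title.
#' @return A ggplot object.
#' @export
plot_frame <- function(img, pitch = 60, title = NULL) {
  df <- tidyr::expand_grid(depth = seq_len(nrow(img)),
                           lateral = seq_len(ncol(img)))
  df$value <- as.vector(t(img))  # expand_grid varies the last factor fastest
  df$depth_um <- (df$depth - 0.5) * pitch
  df$lateral_um <- (df$lateral - 0.5) * pitch
  ggplot2::ggplot(df, ggplot2::aes(.data$lateral_um, .data$depth_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (µm)", y = "depth (µm)",
                  fill = "intensity", title = title) +
    ggplot2::theme_minimal()
}

#' @method autoplot ulm_psf
#' @export
autoplot.ulm_psf <- function(object, ...) {
  plot_frame(object$kernel_hi, object$hi_pixel,
             sprintf("PSF: FWHM %.0f x %.0f µm, AR %.2f",
                     object$fwhm_major, object$fwhm_minor, object$AR))
}

#' @method autoplot ulm_tracks
#' @export
autoplot.ulm_tracks <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$lateral_um, .data$depth_um,
                               group = .data$track,
                               color = factor(.data$track))) +
    ggplot2::geom_path(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (µm)", y = "depth (µm)") +
    ggplot2::theme_minimal()
}

#' @method autoplot ulm_line_fit
#' @export
autoplot.ulm_line_fit <- function(object, ...) {
  df <- object$profile
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(.data$pos_um, .data$value)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "red") +
    ggplot2::geom_vline(xintercept = object$components$mu_um,
                        linetype = "dashed", color = "blue") +
    ggplot2::labs(x = "transverse position (µm)",
                  y = "mean trajectory count") +
    ggplot2::theme_minimal()
}

#' @method autoplot ulm_vessel_profile
#' @export
autoplot.ulm_vessel_profile <- function(object, ...) {
  sc <- attr(object, "scenario")
  df <- tidyr::pivot_longer(
    object[, c("r_um", "U_m", "U_ref")],
    cols = c("U_m", "U_ref"), names_to = "which", values_to = "U")
  ggplot2::ggplot(df, ggplot2::aes(.data$r_um, .data$U / 1e4,
                                   color = .data$which)) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$which == "U_ref")) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$which == "U_m")) +
    ggplot2::labs(x = "radial position (µm)", y = "speed (cm/s)",
                  color = NULL,
                  title = if (!is.null(sc))
                    sprintf("R = %.0f µm vessel", sc$R)) +
    ggplot2::theme_minimal()
}

#' @method autoplot ulm_report
#' @export
autoplot.ulm_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$psf_idx), .data$E_c_um,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(noise_peak ~ concentration,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "PSF (increasing size)",
                  y = expression(E[c] ~ (mu * m))) +
    ggplot2::theme_minimal()
}

#' Plot a separation failure-fraction curve
#'
#' @param stats Tibble from [separation_stats()].
#' @return A ggplot object.
#' @export
plot_separation <- function(stats) {
  df <- stats[stats$n > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_mid, .data$pct_unseparated)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "normalized separation D*",
                  y = "unseparated (%)") +
    ggplot2::theme_minimal()
}
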