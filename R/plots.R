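#' Plot methods
#'
#' `autoplot()` methods for every result type: temperature fields and
#' heat solutions as rasters, trajectory snapshots as Fig-style scatter
#' panels, and radial concentration / force profiles as line plots.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @name mst-plots
NULL

#' @rdname mst-plots
#' @method autoplot mst_field
#' @export
autoplot.mst_field <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_um, .data$y_um, fill = .data$dT_K)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * T ~ "[K]")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x ~ "[" * mu * m * "]"),
                  y = expression(y ~ "[" * mu * m * "]"),
                  title = "Mid-plane temperature rise")
}

#' @rdname mst-plots
#' @method autoplot mst_heat
#' @export
autoplot.mst_heat <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$r_um, .data$z_um, fill = .data$dT_K)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * T ~ "[K]")) +
    ggplot2::labs(x = expression(r ~ "[" * mu * m * "]"),
                  y = expression(z ~ "[" * mu * m * "]"),
                  title = "Axisymmetric chamber temperature (upper half)")
}

#' @rdname mst-plots
#' @param times snapshot times \[s\] to facet (nearest recorded frames).
#' @method autoplot mst_trajectories
#' @export
autoplot.mst_trajectories <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- unique(c(0, stats::median(object$times), max(object$times)))
  frames <- vapply(times, function(t) which.min(abs(object$times - t)),
                   integer(1))
  d <- purrr::map_dfr(unique(frames), function(fr) {
    tibble(t_s = object$times[fr],
           x_um = object$x[fr, ] * 1e6, y_um = object$y[fr, ] * 1e6)
  })
  d$t_s <- factor(sprintf("t = %g s", d$t_s),
                  levels = sprintf("t = %g s", sort(unique(object$times[frames]))))
  ggplot2::ggplot(d, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~t_s) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(x ~ "[" * mu * m * "]"),
                  y = expression(y ~ "[" * mu * m * "]"),
                  title = "Particle snapshots")
}

#' @rdname mst-plots
#' @method autoplot mst_radial_profile
#' @export
autoplot.mst_radial_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(dplyr::filter(d, !is.na(.data$ratio)),
                  ggplot2::aes(.data$bin_center_um, .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(r ~ "[" * mu * m * "]"),
                  y = expression(c / c[0]),
                  title = "Radial depletion profile")
}

#' @rdname mst-plots
#' @method autoplot mst_force_profile
#' @export
autoplot.mst_force_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(dplyr::filter(d, !is.na(.data$mean_force_fN)),
                  ggplot2::aes(.data$bin_center_um, .data$mean_force_fN)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(r ~ "[" * mu * m * "]"),
                  y = expression("<|" * F[tph] * "|> [fN]"),
                  title = "Thermophoretic force profile")
}
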