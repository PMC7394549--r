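#' Plot methods
#'
#' `autoplot()` methods for the main result types: velocity fields as
#' arrow (quiver) plots coloured by the transverse velocity, myosin
#' profiles with their step-plus-Gaussian fit, film-model solutions,
#' chiral statistics as instantaneous-velocity histograms, and spindle
#' tracks.
#'
#' @param object the object to plot.
#' @param pair which frame pair of a velocity field to show.
#' @param arrow_scale visual scaling of the velocity arrows (min per
#'   plotted unit).
#' @param ... unused.
#' @return A ggplot object.
#' @name chiralflow-autoplot
NULL

#' @rdname chiralflow-autoplot
#' @method autoplot velocity_field
#' @export
autoplot.velocity_field <- function(object, pair = NULL, arrow_scale = 0.5,
                                    ...) {
  pair <- pair %||% object$pair[1]
  sub <- dplyr::filter(object, .data$pair == !!pair, .data$valid)
  ggplot2::ggplot(sub, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + .data$u * arrow_scale,
                   yend = .data$y + .data$v * arrow_scale,
                   colour = .data$v),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "cm"))
    ) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey80",
                                    high = "red", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "v_y (um/min)",
                  title = sprintf("Cortical flow field, frame pair %d", pair))
}

#' @rdname chiralflow-autoplot
#' @method autoplot myosin_profile
#' @export
autoplot.myosin_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$intensity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "normalised division axis", y = "myosin intensity (a.u.)")
}

#' @rdname chiralflow-autoplot
#' @method autoplot myosin_fit
#' @export
autoplot.myosin_fit <- function(object, ...) {
  xs <- seq(0, 1, length.out = 400)
  p <- object$params
  fit_df <- tibble(position = xs,
                   intensity = myosin_model(xs, p$IA, p$IP, p$IR, p$w, p$xr))
  autoplot.myosin_profile(object$profile) +
    ggplot2::geom_line(data = fit_df, colour = "red") +
    ggplot2::labs(title = sprintf("step+Gaussian fit: ratio IA/IP = %.2f, xr = %.2f",
                                  p$IA / p$IP, p$xr))
}

#' @rdname chiralflow-autoplot
#' @method autoplot film_solution
#' @export
autoplot.film_solution <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(.data$x_norm, .data$v)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "normalised long axis", y = "azimuthal flow v (um/min)")
}

#' @rdname chiralflow-autoplot
#' @method autoplot chiral_stats
#' @export
autoplot.chiral_stats <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$per_frame, ggplot2::aes(.data$vc)) +
    ggplot2::geom_histogram(bins = max(5, nrow(object$per_frame) %/% 2),
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, colour = "black") +
    ggplot2::geom_vline(xintercept = s$vc, colour = "red", linetype = 2) +
    ggplot2::labs(x = "instantaneous v_c (um/min)", y = "count",
                  title = sprintf("v_c = %.2f +/- %.2f um/min (%s)",
                                  s$vc, s$vc_ci95, s$handedness))
}

#' @rdname chiralflow-autoplot
#' @method autoplot spindle_track
#' @export
autoplot.spindle_track <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble(pole = "pole 1", frame = object$frame, x = object$x1, y = object$y1),
    tibble(pole = "pole 2", frame = object$frame, x = object$x2, y = object$y2)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y, colour = .data$pole)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}
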