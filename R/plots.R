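#' Plot the hourly site series of a run
#'
#' Line plot of whole pollen, shells and SPP number at the evaluation site,
#' faceted by tracer (free y scales: SPP numbers exceed shell numbers by
#' around the 700-per-grain factor).
#'
#' @param object An `spp_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spp_run
#' @export
autoplot.spp_run <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~tracer, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "hours since run start", y = expression(m^-3),
      title = sprintf("Site series, experiment '%s'", object$config$name)) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation scatter with its regression line
#'
#' Modelled vs observed hourly values, the fitted regression line and the
#' 1:1 line, annotated with slope and Pearson r.
#'
#' @param object An `eval_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eval_result
#' @export
autoplot.eval_result <- function(object, ...) {
  df <- tibble::tibble(obs = object$obs, model = object$model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$obs, y = .data$model)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "observed", y = "modelled",
      subtitle = sprintf("s = %.2f, r = %.2f (n = %d)", object$slope,
                         object$pearson_r, object$n_hours)) +
    ggplot2::theme_minimal()
}

#' Map a surface tracer field
#'
#' Raster map of a [surface_map()] tibble with an optional front line.
#'
#' @param map Tibble from [surface_map()].
#' @param front_lon Optional front longitude to draw as a vertical line.
#' @return A ggplot.
#' @export
plot_surface_map <- function(map, front_lon = NULL) {
  p <- ggplot2::ggplot(map, ggplot2::aes(x = .data$lon, y = .data$lat,
                                         fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed(1.27) +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
  if (!is.null(front_lon)) {
    p <- p + ggplot2::geom_vline(xintercept = front_lon, linewidth = 1)
  }
  p
}

#' Plot the emission-activity functions
#'
#' The three activity curves over their natural ranges; useful to inspect a
#' re-calibration.
#'
#' @param act An [activity_params()] object.
#' @return A ggplot.
#' @export
plot_activity_functions <- function(act = activity_params()) {
  df <- dplyr::bind_rows(
    tibble::tibble(x = seq(0, 100, 0.5), value = f_rh(seq(0, 100, 0.5), act),
                   fn = "f_RH (x = %RH)"),
    tibble::tibble(x = seq(0, 2, 0.01), value = f_pr(seq(0, 2, 0.01), act),
                   fn = "f_PR (x = mm/h)"),
    tibble::tibble(x = seq(0, 20, 0.1), value = f_ws(seq(0, 20, 0.1), act),
                   fn = "f_WS (x = m/s)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~fn, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "activity factor") +
    ggplot2::theme_minimal()
}
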