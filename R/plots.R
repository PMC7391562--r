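# ggplot2 front-ends for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster grid
#'
#' @param object An `sdm_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sdm_grid
#' @export
autoplot.sdm_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @method autoplot ensemble_surface
#' @export
autoplot.ensemble_surface <- function(object, ...) {
  p <- NextMethod()
  lab <- attr(object, "correction")
  p + ggplot2::labs(fill = "suitability",
                    title = if (is.null(lab)) "Ensemble" else
                      paste("Ensemble -", lab))
}

#' Plot a univariate scaling profile
#'
#' Test AUC against window radius for each variable, with the selected scale
#' marked.
#'
#' @param object A `univariate_scaling` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot univariate_scaling
#' @export
autoplot.univariate_scaling <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$scale, y = .data$auc_test,
                                       colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(object, .data$best), size = 3,
                        shape = 21, fill = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "window radius (m, log scale)", y = "test AUC",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a multi- versus single-scale comparison
#'
#' @param object Output of [single_vs_multiscale()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot_scale_comparison <- function(object, ...) {
  df <- dplyr::mutate(object,
    scale = factor(.data$scale, levels = c("multi",
      sort(unique(as.numeric(.data$scale[.data$scale != "multi"]))))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scale, y = .data$auc_test,
                                   group = .data$model_id,
                                   colour = .data$model_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "forced scale", y = "test AUC", colour = NULL) +
    ggplot2::theme_minimal()
}
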