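#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_raster geom_point
#'   geom_abline geom_boxplot labs scale_fill_viridis_c facet_grid
#'   coord_flip theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a canopy pseudo-waveform
#'
#' Horizontal bar profile of the fraction of canopy returns per height bin.
#'
#' @param object A [canopy_pseudo_waveform()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot canopy_waveform
#' @export
autoplot.canopy_waveform <- function(object, ...) {
  ggplot(object, aes(x = .data$bin_center, y = .data$density)) +
    geom_col(width = attr(object, "bin_width"), fill = "forestgreen") +
    coord_flip() +
    labs(x = "Height (m)", y = "Fraction of canopy returns") +
    theme_minimal()
}

#' Plot a canopy height model
#'
#' Raster map of pixel heights; interpolated and nodata cells are visible
#' through the fill.
#'
#' @param object A `chm_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chm_raster
#' @export
autoplot.chm_raster <- function(object, ...) {
  px <- as_tibble(object)
  ggplot(px, aes(x = .data$x, y = .data$y, fill = .data$h)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey80", name = "Height (m)") +
    labs(x = "x (m)", y = "y (m)") +
    theme_minimal()
}

#' Plot observed vs predicted biomass for a fitted model
#'
#' Scatter of model predictions against observed AGB with the 1:1 line.
#'
#' @param object A [fit_power_model()] result.
#' @param data Optional evaluation data (default: the calibration set).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot power_model_fit
#' @export
autoplot.power_model_fit <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    data <- object$training
    names(data)[names(data) == "x1"] <- object$x1
    if (!is.null(object$x2)) names(data)[names(data) == "x2"] <- object$x2
    data[[object$response]] <- data$y
  }
  df <- tibble(
    observed = data[[object$response]],
    predicted = predict(object, data)
  )
  ggplot(df, aes(x = .data$observed, y = .data$predicted)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "Field AGB (Mg/ha)", y = "LiDAR-estimated AGB (Mg/ha)") +
    theme_minimal()
}

#' Boxplots of a metric across point densities
#'
#' The standard summary of the density experiment: the distribution of one
#' metric over plots, by point density, faceted by data model.
#'
#' @param experiment A [run_grid()] result or a metric table from
#'   [compute_study_metrics()].
#' @param metric Metric column name, default `"MeanH"`.
#' @param plot_size Which plot size (ha) to show; default the largest.
#' @return A ggplot.
#' @export
plot_density_effect <- function(experiment, metric = "MeanH",
                                plot_size = NULL) {
  metrics <- if (inherits(experiment, "density_experiment")) {
    experiment$metrics
  } else {
    experiment
  }
  if (is.null(plot_size)) plot_size <- max(metrics$plot_size)
  df <- dplyr::filter(metrics,
                      abs(.data$plot_size - !!plot_size) < 1e-12)
  ggplot(df, aes(x = factor(.data$point_density), y = .data[[metric]])) +
    geom_boxplot() +
    facet_grid(. ~ .data$data_model) +
    labs(x = expression(Point ~ density ~ (m^-2)), y = metric) +
    theme_minimal()
}
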