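#' Define a field plot footprint
#'
#' A plot is the clipping and density-accounting unit of the analysis:
#' a circular or square footprint centred at (`center_x`, `center_y`).
#' Exactly one of `dimension` (radius for circles, side for squares, in
#' metres) or `area_ha` must be given; the other is back-computed.  The
#' conventional field-plot sizes are 0.09, 0.25, 0.5 and 1.0 ha; a
#' 0.09 ha circle has radius 16.93 m.
#'
#' @param center_x,center_y Plot centre coordinates (m, planar CRS).
#' @param shape `"circle"` or `"square"`.
#' @param dimension Radius (circle) or side length (square), in metres.
#' @param area_ha Plot area in hectares.
#' @param plot_id Optional identifier; defaults to `"plot_1"`.
#' @return A one-row tibble with columns `plot_id`, `center_x`, `center_y`,
#'   `shape`, `dimension`, `area_ha`.
#' @examples
#' plot_geometry(0, 0, "circle", area_ha = 0.09)   # radius 16.93 m
#' plot_geometry(50, 50, "square", dimension = 100) # 1 ha
#' @export
plot_geometry <- function(center_x, center_y, shape = c("circle", "square"),
                          dimension = NULL, area_ha = NULL,
                          plot_id = "plot_1") {
  shape <- match.arg(shape)
  check_number(center_x, "center_x")
  check_number(center_y, "center_y")
  if (is.null(dimension) && is.null(area_ha)) {
    abort("Provide either `dimension` or `area_ha`.")
  }
  if (is.null(dimension)) {
    check_number(area_ha, "area_ha", positive = TRUE)
    area_m2 <- area_ha * 1e4
    dimension <- if (shape == "circle") sqrt(area_m2 / pi) else sqrt(area_m2)
  } else {
    check_number(dimension, "dimension", positive = TRUE)
    area_m2 <- if (shape == "circle") pi * dimension^2 else dimension^2
    computed_ha <- area_m2 / 1e4
    if (!is.null(area_ha) && abs(computed_ha - area_ha) > 1e-9) {
      abort(sprintf(
        "`area_ha` (%g) inconsistent with shape/dimension (implies %g ha).",
        area_ha, computed_ha
      ))
    }
    area_ha <- computed_ha
  }
  tibble(
    plot_id = as.character(plot_id),
    center_x = center_x, center_y = center_y,
    shape = shape, dimension = dimension, area_ha = area_ha
  )
}

# Accept a one-row plot tibble (or a named list) and validate it.
as_plot_geometry <- function(plot) {
  if (is.data.frame(plot)) {
    if (nrow(plot) != 1L) abort("`plot` must be a single plot (one row).")
    plot <- as.list(plot)
  }
  needed <- c("center_x", "center_y", "shape", "dimension", "area_ha")
  missing <- setdiff(needed, names(plot))
  if (length(missing)) {
    abort(paste0("`plot` is missing fields: ", paste(missing, collapse = ", ")))
  }
  if (!plot$shape %in% c("circle", "square")) {
    abort(sprintf("Unknown plot shape '%s'.", plot$shape))
  }
  plot
}

plot_area_m2 <- function(plot) {
  plot <- as_plot_geometry(plot)
  plot$area_ha * 1e4
}

# Closed-region membership test: boundary points are retained.
points_in_plot <- function(x, y, plot) {
  plot <- as_plot_geometry(plot)
  if (plot$shape == "circle") {
    (x - plot$center_x)^2 + (y - plot$center_y)^2 <= plot$dimension^2
  } else {
    half <- plot$dimension / 2
    abs(x - plot$center_x) <= half & abs(y - plot$center_y) <= half
  }
}

# Bounding box as c(xmin, ymin, xmax, ymax).
plot_bbox <- function(plot) {
  plot <- as_plot_geometry(plot)
  half <- if (plot$shape == "circle") plot$dimension else plot$dimension / 2
  c(
    plot$center_x - half, plot$center_y - half,
    plot$center_x + half, plot$center_y + half
  )
}
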