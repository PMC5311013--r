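#' Normalize return heights against a DEM
#'
#' Converts elevations to heights above ground, `h = z - ground(x, y)`,
#' sampling the DEM under each return (bilinear by default, exact on planar
#' terrain).  Returns over nodata DEM cells are dropped with a warning.
#' Slightly sub-ground heights in (-0.5, 0) m - ranging noise and DEM
#' error - are clamped to 0; heights below -0.5 m are dropped with a
#' warning.
#'
#' @param cloud Raw point cloud: tibble with `x`, `y`, `z`, `class`.
#' @param dem A [dem_raster()]; every return must fall inside its extent.
#' @param method DEM sampling, `"bilinear"` (default) or `"nearest"`.
#' @param subground_tolerance Heights in `(-subground_tolerance, 0)` are
#'   clamped to zero; lower heights dropped.  Default 0.5 m.
#' @return Normalized cloud: tibble with `x`, `y`, `h`, `class`.
#' @export
normalize_heights <- function(cloud, dem,
                              method = c("bilinear", "nearest"),
                              subground_tolerance = 0.5) {
  method <- match.arg(method)
  cloud <- normalize_cloud_columns(cloud)
  check_number(subground_tolerance, "subground_tolerance", min = 0)
  if (nrow(cloud) == 0) {
    return(tibble(x = numeric(), y = numeric(), h = numeric(),
                  class = integer()))
  }
  ground <- sample_dem(dem, cloud$x, cloud$y, method = method)
  if (anyNA(ground)) {
    n_bad <- sum(is.na(ground))
    warn(sprintf("%d return(s) over DEM nodata cells dropped.", n_bad))
  }
  h <- cloud$z - ground
  keep <- !is.na(h)
  too_low <- keep & h < -subground_tolerance
  if (any(too_low)) {
    warn(sprintf(
      "%d return(s) more than %g m below ground dropped.",
      sum(too_low), subground_tolerance
    ))
    keep <- keep & !too_low
  }
  h <- pmax(h[keep], 0)
  tibble(x = cloud$x[keep], y = cloud$y[keep], h = h,
         class = cloud$class[keep])
}

#' Clip a point cloud to a plot footprint
#'
#' Retains returns whose planimetric position lies inside the plot
#' (closed region: points exactly on the boundary are kept).
#'
#' @param cloud Normalized cloud (tibble with `x`, `y`, `h`, `class`).
#' @param plot A [plot_geometry()] row.
#' @return The clipped cloud (possibly empty).
#' @export
clip_to_plot <- function(cloud, plot) {
  plot <- as_plot_geometry(plot)
  keep <- points_in_plot(cloud$x, cloud$y, plot)
  dplyr::filter(as_tibble(cloud), keep)
}

#' Thin a plot cloud to a target point density
#'
#' Emulates a lower-density acquisition by randomly removing returns: a
#' uniform random subset of size `round(target_density * area_m2)` is kept,
#' without replacement.  Removal is per return, ignoring pulse structure.
#' If the cloud is already at or below the target density it is returned
#' unchanged with a warning (thinning cannot up-sample).
#'
#' @param cloud Normalized cloud already clipped to `plot`.
#' @param plot The [plot_geometry()] the cloud was clipped to.
#' @param target_density Target density (returns per m^2), > 0.
#' @param seed Integer seed making the subset reproducible; `NULL` uses the
#'   current RNG stream.
#' @return The thinned cloud, with attributes `target_density` and
#'   `thin_seed` recording the lineage.
#' @export
thin_to_density <- function(cloud, plot, target_density, seed = NULL) {
  plot <- as_plot_geometry(plot)
  check_number(target_density, "target_density", positive = TRUE)
  cloud <- as_tibble(cloud)
  n <- nrow(cloud)
  n_keep <- round(target_density * plot_area_m2(plot))
  if (n_keep >= n) {
    if (n_keep > n) {
      warn(sprintf(
        "Target density implies %d returns but only %d available; cloud returned unchanged.",
        n_keep, n
      ))
    }
    out <- cloud
  } else {
    idx <- with_seed_or_current(seed, sort(sample.int(n, n_keep)))
    out <- cloud[idx, , drop = FALSE]
  }
  attr(out, "target_density") <- target_density
  attr(out, "thin_seed") <- seed
  out
}

#' Point density of a plot cloud
#'
#' Returns per square metre over the plot area; all classification classes
#' count in the numerator.
#'
#' @inheritParams thin_to_density
#' @return Density in points per m^2.
#' @export
point_density <- function(cloud, plot) {
  area <- plot_area_m2(plot)
  if (area <= 0) abort("Plot area must be > 0.")
  nrow(cloud) / area
}
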