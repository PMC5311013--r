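#' Simulate a multi-plot study with known biomass truth
#'
#' Generates the synthetic analogue of a field campaign plus LiDAR
#' acquisition: `n_plots` independent stands, each sampled at the original
#' point density, with per-plot "field" AGB derived from a power-law
#' allometry on the simulated stems.  Between-plot structural variation
#' (the AGB-height gradient every LiDAR biomass model relies on) is created
#' by drawing each plot's height-distribution scale and stem density from
#' the stated ranges.  Every plot lives in its own local coordinate system
#' with the stand extent's lower-left corner at (0, 0) and the plot centred
#' in the extent, so nested plot sizes can be clipped concentrically.
#'
#' @param n_plots Number of plots; default 100.
#' @param extent_m Stand extent per plot (m); default `c(100, 100)` (1 ha),
#'   large enough to nest plots up to 1 ha.
#' @param max_plot_area_ha Area of the largest (reference) plot; default 1.
#' @param plot_shape Shape of the reference plot; default `"square"`.
#' @param target_point_density Original acquisition density (returns per
#'   m^2); default 20, typical of a high-density airborne survey.
#' @param height_scale_range Per-plot Weibull scale drawn uniformly from
#'   this range (m); default `c(12, 32)`.
#' @param stem_density_range Per-plot stems per ha, drawn uniformly;
#'   default `c(150, 450)`.
#' @param allometry,agb_noise_sd Passed to [assign_field_agb()]; defaults
#'   `c(0.05, 2.5)` and 0.3.
#' @param seed Master seed; per-plot seeds are derived from it with
#'   [derive_seed()].
#' @param ... Further arguments forwarded to [stand_config()]
#'   (e.g. `ground_fraction`, `penetration`).
#' @return A `lidar_study` list: `plots` (plot-geometry tibble), `clouds`
#'   (named list of normalized clouds at the original density), `field_agb`
#'   (tibble `plot_id`, `agb`), `trees` (named list), and `truth` (the
#'   generating parameters).
#' @examples
#' study <- simulate_study(n_plots = 4, extent_m = c(40, 40),
#'                         max_plot_area_ha = 0.09, plot_shape = "circle",
#'                         target_point_density = 5, seed = 1)
#' @export
simulate_study <- function(n_plots = 100,
                           extent_m = c(100, 100),
                           max_plot_area_ha = 1.0,
                           plot_shape = c("square", "circle"),
                           target_point_density = 20,
                           height_scale_range = c(12, 32),
                           stem_density_range = c(150, 450),
                           allometry = c(0.05, 2.5),
                           agb_noise_sd = 0.3,
                           seed = 1,
                           ...) {
  plot_shape <- match.arg(plot_shape)
  stopifnot(n_plots >= 1)
  center <- extent_m / 2
  ref_dim_half <- if (plot_shape == "circle") {
    sqrt(max_plot_area_ha * 1e4 / pi)
  } else {
    sqrt(max_plot_area_ha * 1e4) / 2
  }
  if (any(center < ref_dim_half)) {
    abort("`extent_m` too small to contain the reference plot.")
  }
  draws <- with_seed_or_current(seed, tibble(
    height_scale = runif(n_plots, height_scale_range[1],
                         height_scale_range[2]),
    stems = runif(n_plots, stem_density_range[1], stem_density_range[2])
  ))
  ids <- sprintf("plot_%03d", seq_len(n_plots))
  trees <- vector("list", n_plots)
  clouds <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    cfg <- stand_config(
      extent_m = extent_m,
      stem_density = draws$stems[i],
      height_distribution = list(family = "weibull", shape = 3,
                                 scale = draws$height_scale[i]),
      target_point_density = target_point_density,
      seed = derive_seed(seed, i),
      ...
    )
    trees[[i]] <- simulate_stand(cfg)
    clouds[[i]] <- sample_returns(trees[[i]], cfg)
  }
  names(trees) <- ids
  names(clouds) <- ids
  plots <- purrr::map2(ids, seq_len(n_plots), function(id, i) {
    plot_geometry(center[1], center[2], plot_shape,
                  area_ha = max_plot_area_ha, plot_id = id)
  })
  plots <- dplyr::bind_rows(plots)
  field_agb <- assign_field_agb(
    trees, area_ha = max_plot_area_ha,
    allometry = allometry, noise_sd = agb_noise_sd,
    seed = derive_seed(seed, n_plots + 1L)
  )
  structure(
    list(
      plots = plots,
      clouds = clouds,
      trees = trees,
      field_agb = field_agb,
      truth = list(
        allometry = allometry, agb_noise_sd = agb_noise_sd,
        target_point_density = target_point_density,
        height_scale_range = height_scale_range,
        stem_density_range = stem_density_range,
        seed = seed
      )
    ),
    class = "lidar_study"
  )
}

#' @export
print.lidar_study <- function(x, ...) {
  cat(sprintf(
    "<lidar_study> %d plots (%s, %.2f ha) at %g points/m^2; AGB %.1f-%.1f Mg/ha\n",
    nrow(x$plots), x$plots$shape[1], x$plots$area_ha[1],
    x$truth$target_point_density,
    min(x$field_agb$agb), max(x$field_agb$agb)
  ))
  invisible(x)
}

#' Derive a condition seed from a master seed
#'
#' A stated counter scheme (multiplicative congruential step per index)
#' mapping a master seed plus any number of integer indices to a
#' reproducible 31-bit seed, so that any single simulated condition - one
#' plot, one density, one repetition - can be re-run in isolation.
#'
#' @param seed Master seed (integer).
#' @param ... Integer indices identifying the condition.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(42, 3, 1)
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  val <- as.double(seed) %% 2147483647
  for (k in idx) {
    val <- (val * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(val)
}

#' Write and read a study directory
#'
#' Serializes a [simulate_study()] result to plain files: one point cloud
#' per plot (CSV `x,y,z,class` dialect by default, or LAS), a flat
#' zero-elevation DEM as Esri ASCII grid (so height normalization can be
#' exercised end to end), and `manifest.json` holding the plot table, the
#' field AGB and the generating-truth block.
#'
#' @param study A `lidar_study`.
#' @param dir Output directory (created if needed).
#' @param cloud_format `"xyz"` (default) or `"las"`.
#' @return `dir` invisibly (`write_study`); a `lidar_study` without the
#'   `trees` element (`read_study`).
#' @export
write_study <- function(study, dir, cloud_format = c("xyz", "las")) {
  cloud_format <- match.arg(cloud_format)
  stopifnot(inherits(study, "lidar_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (cloud_format == "las") "las" else "csv"
  cloud_files <- character(length(study$clouds))
  for (i in seq_along(study$clouds)) {
    f <- sprintf("%s.%s", names(study$clouds)[i], ext)
    write_point_cloud(study$clouds[[i]], file.path(dir, f),
                      format = cloud_format)
    cloud_files[i] <- f
  }
  bbox <- ceiling(max(purrr::map_dbl(study$clouds, ~ max(.x$x, .x$y, 0))))
  dem <- dem_raster(matrix(0, nrow = bbox + 2, ncol = bbox + 2),
                    origin = c(-1, -1))
  write_ascii_grid(dem, file.path(dir, "dem.asc"))
  manifest <- list(
    plots = study$plots,
    field_agb = study$field_agb,
    clouds = tibble(plot_id = names(study$clouds), file = cloud_files,
                    format = cloud_format),
    dem = "dem.asc",
    truth = study$truth
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  dem <- read_ascii_grid(file.path(dir, manifest$dem))
  clouds <- purrr::pmap(manifest$clouds, function(plot_id, file, format) {
    raw <- read_point_cloud(file.path(dir, file), format = format)
    normalize_heights(raw, dem)
  })
  names(clouds) <- manifest$clouds$plot_id
  structure(
    list(
      plots = as_tibble(manifest$plots),
      clouds = clouds,
      trees = NULL,
      field_agb = as_tibble(manifest$field_agb),
      truth = manifest$truth
    ),
    class = "lidar_study"
  )
}
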