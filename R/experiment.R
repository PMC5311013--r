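#' Conventional plot shape for a given area
#'
#' Field convention used by the experiment driver: small 0.09 ha plots are
#' circular; 0.25-1.0 ha plots are square (subdivisions of large
#' rectangular inventory plots).  Any shape can still be forced per plot
#' via [plot_geometry()].
#'
#' @param area_ha Plot area (ha).
#' @return `"circle"` or `"square"`.
#' @export
default_plot_shape <- function(area_ha) {
  ifelse(area_ha <= 0.09 + 1e-12, "circle", "square")
}

#' Compute both data models' metrics over a study
#'
#' The factorial metric engine: for every plot, plot size and point
#' density, clips the original cloud, thins it to the target density
#' (reference density = no thinning), and computes the ten metrics from
#' both the echo-based cloud and the interpolated 1 m CHM.  Thinning seeds
#' are derived per (plot, size, density) from `seed`, so any single
#' condition is re-runnable in isolation.
#'
#' @param study A [simulate_study()] result (or compatible list with
#'   `plots`, `clouds`).
#' @param densities Point densities (returns per m^2), the first/largest
#'   being the original ("Orig"); default `c(20, 10, 5, 1)`.
#' @param plot_sizes Plot areas (ha); default `c(0.09, 0.25, 0.5, 1)`.
#' @param seed Master seed for the thinning draws.
#' @param reference_density Density treated as un-thinned original;
#'   default `max(densities)`.
#' @param canopy_threshold,fc_threshold,bin_width Metric parameters, see
#'   [compute_echo_metrics()].
#' @param resolution CHM cell size (m), default 1.
#' @param shapes Plot shape per size; default [default_plot_shape()].
#' @return Tidy metric table: one row per
#'   (plot_id, data_model, point_density, plot_size) with the ten metric
#'   columns.
#' @export
compute_study_metrics <- function(study,
                                  densities = c(20, 10, 5, 1),
                                  plot_sizes = c(0.09, 0.25, 0.5, 1),
                                  seed = 1,
                                  reference_density = max(densities),
                                  canopy_threshold = 2,
                                  fc_threshold = canopy_threshold,
                                  bin_width = 0.5,
                                  resolution = 1,
                                  shapes = default_plot_shape(plot_sizes)) {
  plots <- study$plots
  shapes <- rep_len(shapes, length(plot_sizes))
  out <- vector("list", nrow(plots) * length(plot_sizes) * length(densities))
  k <- 0L
  for (ip in seq_len(nrow(plots))) {
    id <- plots$plot_id[ip]
    cloud0 <- study$clouds[[id]]
    for (is in seq_along(plot_sizes)) {
      size <- plot_sizes[is]
      geom <- plot_geometry(plots$center_x[ip], plots$center_y[ip],
                            shapes[is], area_ha = size, plot_id = id)
      clipped <- clip_to_plot(cloud0, geom)
      for (idn in seq_along(densities)) {
        d <- densities[idn]
        cloud <- if (d >= reference_density) {
          clipped
        } else {
          thin_to_density(clipped, geom, d,
                          seed = derive_seed(seed, ip, is, idn))
        }
        em <- compute_echo_metrics(
          cloud, canopy_threshold = canopy_threshold,
          fc_threshold = fc_threshold, bin_width = bin_width,
          plot_id = id, point_density = d, plot_size = size
        )
        chm <- interpolate_empty_cells(
          rasterize_max_height(cloud, geom, resolution = resolution)
        )
        cm <- compute_chm_metrics(
          chm, fc_threshold = fc_threshold, bin_width = bin_width,
          plot_id = id, point_density = d, plot_size = size
        )
        k <- k + 1L
        out[[k]] <- dplyr::bind_rows(em, cm)
      }
    }
  }
  dplyr::bind_rows(out)
}

compare_condition <- function(a, b, metric, alpha) {
  d <- paired_differences(a, b, metric)
  n <- nrow(d)
  if (n == 0) {
    return(tibble(metric = metric, n_pairs = 0L, n_dropped =
                    attr(d, "n_dropped"),
                  mean_diff = NA_real_, sd_diff = NA_real_,
                  wilcoxon_p = NA_real_, ttest_p = NA_real_,
                  significant = NA))
  }
  w <- wilcoxon_signed_rank(d)
  tt <- if (n >= 2) one_sample_t(d) else NULL
  tibble(
    metric = metric,
    n_pairs = n,
    n_dropped = attr(d, "n_dropped"),
    mean_diff = mean(d$difference),
    sd_diff = if (n > 1) sd(d$difference) else NA_real_,
    wilcoxon_p = w$p_value,
    ttest_p = if (is.null(tt)) NA_real_ else tt$p_value,
    significant = w$p_value < alpha
  )
}

#' Run the full density x plot-size comparison grid
#'
#' The experiment mirrored by the package: for every plot size, metrics at
#' each thinned density are compared pairwise (per plot) against the
#' reference density; and for every density, metrics at each plot size are
#' compared against the reference plot size.  Each comparison reports the
#' mean and standard deviation of the per-plot differences
#' (reference minus alternative), the two-sided Wilcoxon signed-rank p, a
#' one-sample t p, and a significance flag at `alpha` from the Wilcoxon
#' test.  No multiple-testing correction is applied by default
#' (`p_adjust = "holm"` is available).
#'
#' @inheritParams compute_study_metrics
#' @param study A [simulate_study()] result.
#' @param reference_plot_size Plot size all sizes are compared against;
#'   default `max(plot_sizes)`.
#' @param alpha Significance level, default 0.05.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()],
#'   applied to the Wilcoxon p-values within each comparison family.
#' @param metrics Which study metrics to pre-compute; normally leave
#'   `NULL` and let the function call [compute_study_metrics()]; pass a
#'   metric table to reuse one.
#' @return A `density_experiment` list: `metrics` (the full metric table),
#'   `comparisons` (tidy results, one row per plot size/density
#'   pair/model/metric), and the call parameters.  Use
#'   [significance_matrix()] for the compact significance grid.
#' @export
run_grid <- function(study,
                     densities = c(20, 10, 5, 1),
                     plot_sizes = c(0.09, 0.25, 0.5, 1),
                     reference_density = max(densities),
                     reference_plot_size = max(plot_sizes),
                     alpha = 0.05,
                     seed = 1,
                     p_adjust = "none",
                     metrics = NULL,
                     ...) {
  check_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  if (!reference_density %in% densities) {
    abort("`reference_density` must be one of `densities`.")
  }
  if (!reference_plot_size %in% plot_sizes) {
    abort("`reference_plot_size` must be one of `plot_sizes`.")
  }
  if (is.null(metrics)) {
    metrics <- compute_study_metrics(
      study, densities = densities, plot_sizes = plot_sizes, seed = seed,
      reference_density = reference_density, ...
    )
  }
  grid_rows <- list()
  take <- function(size, dens, model) {
    dplyr::filter(metrics,
                  abs(.data$plot_size - size) < 1e-12,
                  abs(.data$point_density - dens) < 1e-12,
                  .data$data_model == model)
  }
  # density effect at each plot size
  for (size in plot_sizes) {
    for (model in c("echo", "chm")) {
      ref_tbl <- take(size, reference_density, model)
      for (dens in setdiff(densities, reference_density)) {
        alt_tbl <- take(size, dens, model)
        res <- purrr::map(METRIC_COLUMNS, function(m) {
          compare_condition(ref_tbl, alt_tbl, m, alpha)
        })
        grid_rows[[length(grid_rows) + 1L]] <- dplyr::bind_rows(res) |>
          dplyr::mutate(
            comparison = "density",
            plot_size = size, point_density = dens,
            reference = sprintf("orig-%gp", dens),
            data_model = model, .before = 1
          )
      }
    }
  }
  # plot-size effect at each density
  for (dens in densities) {
    for (model in c("echo", "chm")) {
      ref_tbl <- take(reference_plot_size, dens, model)
      for (size in setdiff(plot_sizes, reference_plot_size)) {
        alt_tbl <- take(size, dens, model)
        res <- purrr::map(METRIC_COLUMNS, function(m) {
          compare_condition(ref_tbl, alt_tbl, m, alpha)
        })
        grid_rows[[length(grid_rows) + 1L]] <- dplyr::bind_rows(res) |>
          dplyr::mutate(
            comparison = "plot_size",
            plot_size = size, point_density = dens,
            reference = sprintf("%g-%g ha", reference_plot_size, size),
            data_model = model, .before = 1
          )
      }
    }
  }
  comparisons <- if (length(grid_rows)) {
    dplyr::bind_rows(grid_rows)
  } else {
    tibble(
      comparison = character(), plot_size = numeric(),
      point_density = numeric(), reference = character(),
      data_model = character(), metric = character(), n_pairs = integer(),
      n_dropped = integer(), mean_diff = numeric(), sd_diff = numeric(),
      wilcoxon_p = numeric(), ttest_p = numeric(), significant = logical()
    )
  }
  if (p_adjust != "none") {
    comparisons <- comparisons |>
      dplyr::group_by(.data$comparison) |>
      dplyr::mutate(
        wilcoxon_p = stats::p.adjust(.data$wilcoxon_p, method = p_adjust),
        significant = .data$wilcoxon_p < alpha
      ) |>
      dplyr::ungroup()
  }
  structure(
    list(
      metrics = metrics,
      comparisons = comparisons,
      densities = densities,
      plot_sizes = plot_sizes,
      reference_density = reference_density,
      reference_plot_size = reference_plot_size,
      alpha = alpha,
      seed = seed
    ),
    class = "density_experiment"
  )
}

#' @export
print.density_experiment <- function(x, ...) {
  cat(sprintf(
    "<density_experiment> %d comparisons over densities {%s} p/m^2, plot sizes {%s} ha (alpha = %g)\n",
    nrow(x$comparisons),
    paste(x$densities, collapse = ", "),
    paste(x$plot_sizes, collapse = ", "), x$alpha
  ))
  invisible(x)
}

#' Significance grid of an experiment
#'
#' Compacts the comparison table into the familiar grid: one row per
#' (comparison type, plot size, density pair), one logical column per
#' metric x data model.
#'
#' @param experiment A [run_grid()] result, or its `comparisons` tibble.
#' @return A wide tibble of logicals (`TRUE` = significant).
#' @export
significance_matrix <- function(experiment) {
  comparisons <- if (inherits(experiment, "density_experiment")) {
    experiment$comparisons
  } else {
    experiment
  }
  comparisons |>
    dplyr::mutate(col = paste(.data$metric, .data$data_model, sep = "_")) |>
    dplyr::select("comparison", "plot_size", "point_density", "reference",
                  "col", "significant") |>
    tidyr::pivot_wider(names_from = "col", values_from = "significant")
}

#' Write experiment outputs to CSV
#'
#' Writes `comparisons.csv` (full numbers), `significance_matrix.csv` and
#' `metrics.csv` under `dir`.
#'
#' @param experiment A [run_grid()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "density_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(experiment$comparisons,
                   file.path(dir, "comparisons.csv"), row.names = FALSE)
  utils::write.csv(significance_matrix(experiment),
                   file.path(dir, "significance_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  invisible(dir)
}
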