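#' Rasterize a plot cloud to a canopy height model
#'
#' Builds the 1 m (by default) canopy height model: the grid is aligned to
#' the plot bounding box, each cell holds the maximum return height among
#' the returns falling in it (`status = "direct"`), and the generating
#' highest return of each direct cell is registered (at its true x, y, not
#' the cell centre) for later triangulation.  Cells without returns are
#' `"nodata"` until [interpolate_empty_cells()] fills them.  Only cells
#' whose centre lies inside the plot participate (relevant for circular
#' plots).
#'
#' @param cloud Normalized cloud clipped to `plot`.
#' @param plot A [plot_geometry()] row.
#' @param resolution Cell size (m), default 1, > 0.
#' @return A `chm_raster`: list with `height` and `status` matrices (rows =
#'   y from the south, cols = x from the west), `origin`, `resolution`,
#'   `in_plot` logical matrix, and `source_points` tibble (`x`, `y`, `h`).
#' @export
rasterize_max_height <- function(cloud, plot, resolution = 1) {
  check_number(resolution, "resolution", positive = TRUE)
  plot <- as_plot_geometry(plot)
  bbox <- plot_bbox(plot)
  nc <- max(1L, ceiling((bbox[3] - bbox[1]) / resolution - 1e-9))
  nr <- max(1L, ceiling((bbox[4] - bbox[2]) / resolution - 1e-9))
  origin <- c(bbox[1], bbox[2])
  height <- matrix(NA_real_, nrow = nr, ncol = nc)
  status <- matrix("nodata", nrow = nr, ncol = nc)
  cx <- origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * resolution
  cy <- origin[2] + (rep(seq_len(nr), times = nc) - 0.5) * resolution
  in_plot <- matrix(points_in_plot(cx, cy, plot), nrow = nr, ncol = nc)
  src <- tibble(x = numeric(), y = numeric(), h = numeric())
  if (nrow(cloud) > 0) {
    j <- pmin(pmax(floor((cloud$x - origin[1]) / resolution), 0), nc - 1) + 1
    i <- pmin(pmax(floor((cloud$y - origin[2]) / resolution), 0), nr - 1) + 1
    cell <- (j - 1L) * nr + i
    ord <- order(cell, cloud$h) # last within cell = argmax
    top <- !duplicated(cell[ord], fromLast = TRUE)
    sel <- ord[top]
    keep <- in_plot[cell[sel]]
    sel <- sel[keep]
    height[cell[sel]] <- cloud$h[sel]
    status[cell[sel]] <- "direct"
    src <- tibble(x = cloud$x[sel], y = cloud$y[sel], h = cloud$h[sel])
  }
  status[!in_plot] <- "outside"
  height[!in_plot] <- NA_real_
  structure(
    list(
      height = height, status = status, in_plot = in_plot,
      origin = origin, resolution = resolution,
      source_points = src
    ),
    class = "chm_raster"
  )
}

#' @export
print.chm_raster <- function(x, ...) {
  tab <- table(factor(x$status[x$in_plot],
                      levels = c("direct", "interpolated", "nodata")))
  cat(sprintf(
    "<chm_raster> %d x %d cells @ %g m: %d direct, %d interpolated, %d nodata\n",
    nrow(x$height), ncol(x$height), x$resolution,
    tab[["direct"]], tab[["interpolated"]], tab[["nodata"]]
  ))
  invisible(x)
}

chm_cell_centers <- function(chm, cells) {
  nr <- nrow(chm$height)
  j <- (cells - 1L) %/% nr + 1L
  i <- (cells - 1L) %% nr + 1L
  list(
    x = chm$origin[1] + (j - 0.5) * chm$resolution,
    y = chm$origin[2] + (i - 0.5) * chm$resolution
  )
}

#' Fill empty CHM cells by Delaunay-based interpolation
#'
#' Interpolates the heights of empty (nodata) cells inside the convex hull
#' of the registered per-cell maximum returns, from a Delaunay
#' triangulation of those source points (piecewise-linear barycentric
#' interpolation on the triangulation).  This reproduces constant fields
#' exactly and planar fields to numerical precision inside the hull, and
#' every filled value is a convex combination of its triangle's generators,
#' so it stays within their range.  Cells outside the hull remain nodata
#' and are excluded from metrics.  With fewer than 3 non-collinear source
#' points the raster is returned unchanged with a warning.
#'
#' @param chm A [rasterize_max_height()] result.
#' @return The `chm_raster` with filled cells marked
#'   `status = "interpolated"`.
#' @export
interpolate_empty_cells <- function(chm) {
  stopifnot(inherits(chm, "chm_raster"))
  empty <- which(chm$status == "nodata" & chm$in_plot)
  if (length(empty) == 0) {
    return(chm)
  }
  src <- chm$source_points
  degenerate <- nrow(src) < 3 ||
    qr(cbind(1, src$x, src$y))$rank < 3
  if (degenerate) {
    warn("Fewer than 3 non-collinear source points; CHM returned unfilled.")
    return(chm)
  }
  nr <- nrow(chm$height)
  nc <- ncol(chm$height)
  xo <- chm$origin[1] + (seq_len(nc) - 0.5) * chm$resolution
  yo <- chm$origin[2] + (seq_len(nr) - 0.5) * chm$resolution
  # interp() evaluates on the full cell-centre grid (rows = x there);
  # transpose back to our row = y layout and take only the empty cells.
  est <- t(interp::interp(
    x = src$x, y = src$y, z = src$h,
    xo = xo, yo = yo,
    method = "linear", extrap = FALSE, duplicate = "max"
  )$z)
  filled <- !is.na(est[empty])
  chm$height[empty[filled]] <- est[empty][filled]
  chm$status[empty[filled]] <- "interpolated"
  chm
}

#' Tidy pixel table of a CHM
#'
#' @param x A `chm_raster`.
#' @param ... Unused.
#' @return Tibble `x`, `y` (cell centres), `h`, `status` for in-plot cells.
#' @method as_tibble chm_raster
#' @export
as_tibble.chm_raster <- function(x, ...) {
  cells <- which(x$in_plot)
  ctr <- chm_cell_centers(x, cells)
  h <- x$height[cells]
  status <- x$status[cells]
  tibble(x = ctr$x, y = ctr$y, h = h, status = status)
}

#' Convert a CHM to a writable raster
#'
#' @param chm A `chm_raster`.
#' @return A [dem_raster()] carrying the CHM heights (nodata -9999),
#'   suitable for [write_ascii_grid()].
#' @export
chm_as_raster <- function(chm) {
  stopifnot(inherits(chm, "chm_raster"))
  dem_raster(chm$height, origin = chm$origin, resolution = chm$resolution)
}

#' CHM-based canopy structure metrics
#'
#' The same ten metrics as [compute_echo_metrics()], computed from CHM
#' pixels instead of returns.  Height statistics use all valid (direct or
#' interpolated) pixels with no canopy height cut; fractional cover is the
#' share of valid pixels at or above `fc_threshold`; the pseudo-waveform is
#' built over all valid pixel heights from 0 m up.
#'
#' @param chm A `chm_raster`, normally after [interpolate_empty_cells()].
#' @param fc_threshold FC threshold (m), default 2.
#' @param bin_width Waveform bin width (m), default 0.5.
#' @param plot_id,point_density,plot_size Condition tags.
#' @return One-row tibble in the same schema as [compute_echo_metrics()],
#'   tagged `data_model = "chm"`; `n_returns`/`n_canopy` hold the valid
#'   pixel count.
#' @export
compute_chm_metrics <- function(chm, fc_threshold = 2, bin_width = 0.5,
                                plot_id = NA_character_,
                                point_density = NA_real_,
                                plot_size = NA_real_) {
  stopifnot(inherits(chm, "chm_raster"))
  h <- chm$height[chm$in_plot & chm$status %in% c("direct", "interpolated")]
  stats <- height_stat_metrics(h)
  if (length(h) == 0) {
    fc <- undefined_marker()
    aucw <- 0
  } else {
    fc <- sum(h >= fc_threshold) / length(h)
    aucw <- area_under_canopy_waveform(
      canopy_pseudo_waveform(tibble(h = h), canopy_threshold = 0,
                             bin_width = bin_width)
    )
  }
  tibble(
    plot_id = plot_id, data_model = "chm",
    point_density = point_density, plot_size = plot_size,
    n_returns = length(h), n_canopy = length(h),
    AUCW = aucw, CV = stats$CV, FC = fc,
    MaxH = stats$MaxH, MeanH = stats$MeanH,
    P25H = stats$P25H, P50H = stats$P50H, P75H = stats$P75H,
    P90H = stats$P90H, StdH = stats$StdH
  )
}
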