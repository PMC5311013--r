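METRIC_COLUMNS <- c("AUCW", "CV", "FC", "MaxH", "MeanH",
                    "P25H", "P50H", "P75H", "P90H", "StdH")

#' Fractional cover from a plot cloud
#'
#' The fraction of returns at or above a height threshold, a proxy for
#' canopy density.  All returns (any class) form the denominator; the
#' threshold is site-specific (2 m is the usual canopy cut-off, but e.g.
#' tall moist tropical forest may warrant 27 m).
#'
#' @param cloud Normalized, plot-clipped cloud (column `h`).
#' @param threshold Height threshold (m).
#' @return Fraction in `[0, 1]`; `NA` for an empty cloud.
#' @examples
#' fractional_cover(tibble::tibble(h = c(0, 1, 5, 30)), threshold = 2)
#' @export
fractional_cover <- function(cloud, threshold = 2) {
  check_number(threshold, "threshold")
  n <- nrow(cloud)
  if (n == 0) {
    return(undefined_marker())
  }
  sum(cloud$h >= threshold) / n
}

#' Build the canopy pseudo-waveform
#'
#' A normalized vertical histogram of canopy-return heights: bins of width
#' `bin_width` spanning `[canopy_threshold, hmax]`, each holding the
#' fraction of canopy returns in it (values sum to 1 whenever any canopy
#' return exists).  This is the discrete-return stand-in for a full
#' waveform's vertical energy profile.
#'
#' @param cloud Normalized, plot-clipped cloud (or any tibble with `h`).
#' @param canopy_threshold Lower height bound for canopy returns (m),
#'   default 2.
#' @param bin_width Bin width (m), default 0.5, > 0.
#' @param hmax Upper bound (m); default: the maximum canopy height rounded
#'   up to the next bin edge.
#' @return A tibble of class `canopy_waveform`: `bin_lower`, `bin_upper`,
#'   `bin_center` (m), `density` (fraction per bin), with attributes
#'   `canopy_threshold`, `bin_width`, `hmax`.
#' @export
canopy_pseudo_waveform <- function(cloud, canopy_threshold = 2,
                                   bin_width = 0.5, hmax = NULL) {
  check_number(bin_width, "bin_width", positive = TRUE)
  h <- cloud$h[cloud$h >= canopy_threshold]
  if (is.null(hmax)) {
    hmax <- if (length(h)) {
      canopy_threshold + bin_width * ceiling(
        max(max(h) - canopy_threshold, bin_width) / bin_width
      )
    } else {
      canopy_threshold + bin_width
    }
  }
  if (hmax <= canopy_threshold) {
    abort("`hmax` must exceed `canopy_threshold`.")
  }
  edges <- seq(canopy_threshold, hmax, by = bin_width)
  if (tail(edges, 1) < hmax) edges <- c(edges, hmax)
  counts <- if (length(h)) {
    # right-open bins, last bin closed, so h == hmax is counted
    idx <- pmin(findInterval(h, edges), length(edges) - 1L)
    tabulate(idx, nbins = length(edges) - 1L)
  } else {
    rep(0L, length(edges) - 1L)
  }
  dens <- if (sum(counts) > 0) counts / sum(counts) else rep(0, length(counts))
  wf <- tibble(
    bin_lower = edges[-length(edges)],
    bin_upper = edges[-1],
    bin_center = (edges[-length(edges)] + edges[-1]) / 2,
    density = dens
  )
  attr(wf, "canopy_threshold") <- canopy_threshold
  attr(wf, "bin_width") <- bin_width
  attr(wf, "hmax") <- hmax
  class(wf) <- c("canopy_waveform", class(wf))
  wf
}

#' Area under the canopy pseudo-waveform
#'
#' Trapezoidal integral of the per-bin densities against bin-centre
#' heights, divided by the height range `hmax - canopy_threshold` so the
#' statistic is comparable across plots with different canopy depths.
#' Zero when no canopy return exists.
#'
#' @param waveform A [canopy_pseudo_waveform()].
#' @return Unitless scalar >= 0.
#' @export
area_under_canopy_waveform <- function(waveform) {
  stopifnot(inherits(waveform, "canopy_waveform"))
  v <- waveform$density
  if (sum(v) == 0) {
    return(0)
  }
  x <- waveform$bin_center
  if (length(x) < 2) {
    # single bin: treat the bin itself as the integration support
    return(v[1] * attr(waveform, "bin_width") /
             (attr(waveform, "hmax") - attr(waveform, "canopy_threshold")))
  }
  auc <- sum(diff(x) * (head(v, -1) + tail(v, -1)) / 2)
  auc / (attr(waveform, "hmax") - attr(waveform, "canopy_threshold"))
}

# Shared summary of a height sample: the 8 height-statistics metrics.
height_stat_metrics <- function(h) {
  if (length(h) == 0) {
    u <- undefined_marker()
    return(list(MaxH = u, MeanH = u, P25H = u, P50H = u, P75H = u,
                P90H = u, StdH = u, CV = u))
  }
  q <- quantile(h, c(0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  m <- mean(h)
  s <- if (length(h) > 1) sd(h) else 0
  list(
    MaxH = max(h), MeanH = m,
    P25H = q[1], P50H = q[2], P75H = q[3], P90H = q[4],
    StdH = s,
    CV = if (m > 0) s / m else undefined_marker()
  )
}

#' Echo-based canopy structure metrics
#'
#' The ten standard structure metrics computed directly from the 3D return
#' cloud of one plot: height statistics (maximum, mean, 25/50/75/90th
#' percentiles, standard deviation, coefficient of variation) over canopy
#' returns (`h >= canopy_threshold`), fractional cover, and the area under
#' the canopy pseudo-waveform.  A plot without canopy returns yields `NA`
#' height statistics (so regressions can drop it), `FC = 0` and `AUCW = 0`.
#'
#' @param cloud Normalized cloud clipped to one plot.
#' @param canopy_threshold Canopy height cut-off (m), default 2.
#' @param fc_threshold Fractional-cover threshold (m); defaults to
#'   `canopy_threshold`, configurable for tall-canopy sites (e.g. 27 m).
#' @param bin_width,hmax Passed to [canopy_pseudo_waveform()].
#' @param plot_id,point_density,plot_size Optional condition tags copied
#'   into the output.
#' @return One-row tibble: `plot_id`, `data_model` (`"echo"`),
#'   `point_density`, `plot_size`, `n_returns`, `n_canopy`, then the metric
#'   columns `AUCW, CV, FC, MaxH, MeanH, P25H, P50H, P75H, P90H, StdH`.
#' @examples
#' cloud <- tibble::tibble(h = c(1, 3), x = 0, y = 0, class = 5L)
#' compute_echo_metrics(cloud)  # MeanH = 3, FC = 0.5
#' @export
compute_echo_metrics <- function(cloud, canopy_threshold = 2,
                                 fc_threshold = canopy_threshold,
                                 bin_width = 0.5, hmax = NULL,
                                 plot_id = NA_character_,
                                 point_density = NA_real_,
                                 plot_size = NA_real_) {
  h_canopy <- cloud$h[cloud$h >= canopy_threshold]
  stats <- height_stat_metrics(h_canopy)
  fc <- if (nrow(cloud) == 0) {
    undefined_marker()
  } else if (length(h_canopy) == 0 && fc_threshold >= canopy_threshold) {
    0
  } else {
    fractional_cover(cloud, fc_threshold)
  }
  aucw <- if (length(h_canopy) == 0) {
    0
  } else {
    area_under_canopy_waveform(
      canopy_pseudo_waveform(cloud, canopy_threshold, bin_width, hmax)
    )
  }
  tibble(
    plot_id = plot_id, data_model = "echo",
    point_density = point_density, plot_size = plot_size,
    n_returns = nrow(cloud), n_canopy = length(h_canopy),
    AUCW = aucw, CV = stats$CV, FC = fc,
    MaxH = stats$MaxH, MeanH = stats$MeanH,
    P25H = stats$P25H, P50H = stats$P50H, P75H = stats$P75H,
    P90H = stats$P90H, StdH = stats$StdH
  )
}
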