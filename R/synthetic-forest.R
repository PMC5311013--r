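#' Configure a synthetic forest stand
#'
#' Defines everything needed to simulate a stand and its discrete-return
#' LiDAR sampling: stem density, the tree-height distribution, crown
#' geometry, sampling density, canopy penetration and noise.  Trees are
#' placed by a homogeneous Poisson process; each tree carries a paraboloid
#' (or cone) crown envelope between `crown_base` and its tip, and a
#' synthetic stem diameter (`dbh_proxy`) from which "field" biomass is
#' later derived.
#'
#' @param extent_m Length-2 numeric: stand rectangle dimensions (m).
#' @param stem_density Trees per hectare, > 0.
#' @param height_distribution List: `family` (`"weibull"`, `"lognormal"` or
#'   `"uniform"`) plus its parameters (`shape`/`scale`, `meanlog`/`sdlog`,
#'   or `min`/`max`), in metres.  Default Weibull(shape 3, scale 25),
#'   a right-skewed unimodal height distribution typical of closed forest.
#' @param crown_ratio Fraction of tree height occupied by live crown,
#'   in (0, 1]; default 0.45.
#' @param crown_radius_model Length-2 numeric `c(intercept, slope)` mapping
#'   height to crown radius (m): `radius = intercept + slope * height`;
#'   default `c(0.5, 0.10)`.
#' @param crown_shape `"paraboloid"` (default) or `"cone"` crown envelope.
#' @param target_point_density Returns per m^2, > 0.
#' @param ground_fraction Probability that a pulse reaches the ground
#'   regardless of canopy, in `[0, 1]`; default 0.25.
#' @param penetration Mean exponential penetration depth into the crown,
#'   as a fraction of crown depth; default 0.1.  Deeper penetration makes
#'   the observed canopy top more sensitive to point density.
#' @param dbh_model Length-3 numeric `c(coef, exponent, sdlog)`:
#'   `dbh_proxy = coef * height^exponent * exp(N(0, sdlog^2))` (cm);
#'   default `c(0.8, 1.2, 0.1)`.
#' @param noise_sd_xy,noise_sd_z Positional jitter standard deviations (m);
#'   z-noise is truncated at +/- 3 sd.  Defaults 0.1 and 0.05.
#' @param seed Integer seed; all simulator draws are reproducible given it.
#' @return A `stand_config` list.
#' @examples
#' cfg <- stand_config(extent_m = c(100, 100), stem_density = 300,
#'                     target_point_density = 20, seed = 1)
#' @export
stand_config <- function(extent_m = c(100, 100),
                         stem_density = 300,
                         height_distribution = list(family = "weibull",
                                                    shape = 3, scale = 25),
                         crown_ratio = 0.45,
                         crown_radius_model = c(0.5, 0.10),
                         crown_shape = c("paraboloid", "cone"),
                         target_point_density = 20,
                         ground_fraction = 0.25,
                         penetration = 0.1,
                         dbh_model = c(0.8, 1.2, 0.1),
                         noise_sd_xy = 0.1,
                         noise_sd_z = 0.05,
                         seed = NULL) {
  crown_shape <- match.arg(crown_shape)
  if (length(extent_m) != 2L || any(!is.finite(extent_m)) ||
      any(extent_m <= 0)) {
    abort("`extent_m` must be two positive dimensions (m).")
  }
  check_number(stem_density, "stem_density", positive = TRUE)
  check_number(target_point_density, "target_point_density", positive = TRUE)
  check_number(ground_fraction, "ground_fraction", min = 0, max = 1)
  check_number(crown_ratio, "crown_ratio", min = 1e-9, max = 1)
  check_number(penetration, "penetration", min = 0)
  check_number(noise_sd_xy, "noise_sd_xy", min = 0)
  check_number(noise_sd_z, "noise_sd_z", min = 0)
  if (!is.list(height_distribution) ||
      is.null(height_distribution$family)) {
    abort("`height_distribution` must be a list with a `family` element.")
  }
  structure(
    list(
      extent_m = as.numeric(extent_m),
      stem_density = stem_density,
      height_distribution = height_distribution,
      crown_ratio = crown_ratio,
      crown_radius_model = as.numeric(crown_radius_model),
      crown_shape = crown_shape,
      target_point_density = target_point_density,
      ground_fraction = ground_fraction,
      penetration = penetration,
      dbh_model = as.numeric(dbh_model),
      noise_sd_xy = noise_sd_xy,
      noise_sd_z = noise_sd_z,
      seed = seed
    ),
    class = "stand_config"
  )
}

draw_heights <- function(n, dist) {
  switch(dist$family,
    weibull = rweibull(n, shape = dist$shape, scale = dist$scale),
    lognormal = rlnorm(n, meanlog = dist$meanlog, sdlog = dist$sdlog),
    uniform = runif(n, min = dist$min, max = dist$max),
    abort(sprintf("Unknown height distribution family '%s'.", dist$family))
  )
}

#' Simulate a forest stand
#'
#' Tree count is Poisson with mean `stem_density * area`; positions are
#' uniform over the extent (a homogeneous Poisson process); heights come
#' from the configured distribution; crown base, crown radius and
#' `dbh_proxy` follow the configured deterministic/lognormal models.
#'
#' @param config A [stand_config()].
#' @return A tibble of trees: `x`, `y`, `height`, `crown_base`,
#'   `crown_radius` (m), `dbh_proxy` (cm).
#' @export
simulate_stand <- function(config) {
  stopifnot(inherits(config, "stand_config"))
  with_seed_or_current(config$seed, {
    area_ha <- prod(config$extent_m) / 1e4
    n <- rpois(1, config$stem_density * area_ha)
    heights <- draw_heights(n, config$height_distribution)
    heights <- pmax(heights, 0.5) # no degenerate zero-height trees
    crm <- config$crown_radius_model
    dbm <- config$dbh_model
    tibble(
      tree_id = seq_len(n),
      x = runif(n, 0, config$extent_m[1]),
      y = runif(n, 0, config$extent_m[2]),
      height = heights,
      crown_base = heights * (1 - config$crown_ratio),
      crown_radius = pmax(crm[1] + crm[2] * heights, 0.1),
      dbh_proxy = dbm[1] * heights^dbm[2] *
        exp(rnorm(n, 0, dbm[3]))
    )
  })
}

# Height of the crown envelope of one tree at squared planimetric distance
# d2 from the stem; 0 outside the crown.
crown_envelope_height <- function(d2, height, crown_base, crown_radius,
                                  shape) {
  depth <- height - crown_base
  frac <- d2 / crown_radius^2
  if (shape == "paraboloid") {
    ifelse(frac <= 1, crown_base + depth * (1 - frac), 0)
  } else {
    ifelse(frac <= 1, crown_base + depth * (1 - sqrt(frac)), 0)
  }
}

#' Sample discrete LiDAR returns over a stand
#'
#' Draws `round(target_point_density * area)` pulse positions uniformly
#' over the extent (one return per pulse).  A pulse reaches the ground with
#' probability `ground_fraction`; otherwise, if it falls inside a crown it
#' returns from the local crown-envelope height minus an exponential
#' penetration offset (mean `penetration * crown_depth`, truncated at the
#' crown base); pulses outside all crowns return from the ground.  Ground
#' is flat at height 0.  Gaussian z-noise (truncated at 3 sd) and xy jitter
#' are added.  Denser sampling raises the observed canopy maximum, because
#' more pulses sample near crown apices.
#'
#' @param trees Tibble from [simulate_stand()] (may be empty: the result is
#'   then an all-ground cloud).
#' @param config The same [stand_config()].
#' @param seed Optional seed overriding `config$seed` (used to draw
#'   independent clouds over one stand).
#' @return A normalized point cloud tibble: `x`, `y`, `h`, `class`
#'   (2 = ground, 5 = vegetation).
#' @export
sample_returns <- function(trees, config, seed = config$seed) {
  stopifnot(inherits(config, "stand_config"))
  with_seed_or_current(seed, {
    ex <- config$extent_m
    n <- round(config$target_point_density * prod(ex))
    px <- runif(n, 0, ex[1])
    py <- runif(n, 0, ex[2])
    env_h <- numeric(n)
    env_tree <- integer(n)
    if (nrow(trees) > 0 && n > 0) {
      ord <- order(px)
      pxs <- px[ord]
      pys <- py[ord]
      env_s <- numeric(n)
      tree_s <- integer(n)
      for (t in seq_len(nrow(trees))) {
        r <- trees$crown_radius[t]
        tx <- trees$x[t]
        ty <- trees$y[t]
        lo <- findInterval(tx - r, pxs) + 1L
        hi <- findInterval(tx + r, pxs)
        if (lo > hi) next
        cand <- lo:hi
        dy <- pys[cand] - ty
        near <- abs(dy) <= r
        if (!any(near)) next
        cand <- cand[near]
        d2 <- (pxs[cand] - tx)^2 + dy[near]^2
        inside <- d2 <= r^2
        if (!any(inside)) next
        cand <- cand[inside]
        eh <- crown_envelope_height(d2[inside], trees$height[t],
                                    trees$crown_base[t], r,
                                    config$crown_shape)
        upd <- eh > env_s[cand]
        if (any(upd)) {
          env_s[cand[upd]] <- eh[upd]
          tree_s[cand[upd]] <- t
        }
      }
      env_h[ord] <- env_s
      env_tree[ord] <- tree_s
    }
    to_ground <- runif(n) < config$ground_fraction
    canopy <- env_h > 0 & !to_ground
    h <- numeric(n)
    if (any(canopy)) {
      tt <- env_tree[canopy]
      depth <- trees$height[tt] - trees$crown_base[tt]
      offset <- if (config$penetration > 0) {
        rexp(sum(canopy), rate = 1 / (config$penetration * depth))
      } else {
        0
      }
      h[canopy] <- pmax(env_h[canopy] - offset, trees$crown_base[tt])
    }
    if (config$noise_sd_z > 0) {
      zn <- rnorm(n, 0, config$noise_sd_z)
      zn <- pmin(pmax(zn, -3 * config$noise_sd_z), 3 * config$noise_sd_z)
      h <- h + zn
    }
    if (config$noise_sd_xy > 0) {
      px <- px + rnorm(n, 0, config$noise_sd_xy)
      py <- py + rnorm(n, 0, config$noise_sd_xy)
    }
    tibble(
      x = px, y = py, h = h,
      class = ifelse(canopy, 5L, 2L)
    )
  })
}

#' Assign synthetic field biomass to plots
#'
#' Stands in for the field allometries used in forest inventories: each
#' tree gets `AGB_kg = a * dbh_proxy^b * exp(eps)` with
#' `eps ~ Normal(0, noise_sd^2)`, and plot AGB is the sum expressed in
#' Mg per hectare.
#'
#' @param trees_per_plot Named list of tree tibbles (one per plot), each
#'   with a `dbh_proxy` column.
#' @param area_ha Plot area (ha), scalar or one value per plot.
#' @param allometry Length-2 numeric `c(a, b)`, both > 0; default
#'   `c(0.05, 2.5)`.
#' @param noise_sd Lognormal noise sd on the tree AGB; default 0.3.
#' @param seed Integer seed.
#' @return Tibble `plot_id`, `agb` (Mg per ha).
#' @examples
#' trees <- list(p1 = tibble::tibble(dbh_proxy = 10))
#' assign_field_agb(trees, area_ha = 1, allometry = c(0.05, 2.5),
#'                  noise_sd = 0) # 0.05 * 10^2.5 kg = 0.0158 Mg/ha
#' @export
assign_field_agb <- function(trees_per_plot, area_ha,
                             allometry = c(0.05, 2.5),
                             noise_sd = 0.3, seed = NULL) {
  if (any(allometry <= 0)) {
    abort("Allometry coefficients `a` and `b` must both be > 0.")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  area_ha <- rep_len(area_ha, length(trees_per_plot))
  ids <- names(trees_per_plot) %||% as.character(seq_along(trees_per_plot))
  with_seed_or_current(seed, {
    agb <- purrr::map2_dbl(trees_per_plot, area_ha, function(trees, a_ha) {
      if (nrow(trees) == 0) {
        return(0)
      }
      eps <- rnorm(nrow(trees), 0, noise_sd)
      kg <- allometry[1] * trees$dbh_proxy^allometry[2] * exp(eps)
      sum(kg) / 1000 / a_ha
    })
    tibble(plot_id = ids, agb = unname(agb))
  })
}
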