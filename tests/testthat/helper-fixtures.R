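# Shared fixtures, built in code at test time.

# A plot-clipped cloud with known heights at given positions.
make_cloud <- function(h, x = seq_along(h), y = rep(0, length(h)),
                       class = 5L) {
  tibble::tibble(x = x, y = y, h = h, class = rep_len(class, length(h)))
}

# Nearly closed canopy with deep within-crown penetration: the regime in
# which per-cell maxima (CHM) sit well above individual canopy returns.
dense_config <- function(seed, extent = c(40, 40), density = 12) {
  stand_config(
    extent_m = extent,
    stem_density = 1200,
    target_point_density = density,
    ground_fraction = 0.05,
    penetration = 0.3,
    seed = seed
  )
}

# Sort-based percentile oracle (linear interpolation between order
# statistics, the type-7 rule): p in [0, 1].
oracle_percentile <- function(h, p) {
  s <- sort(h)
  n <- length(s)
  k <- (n - 1) * p + 1
  lo <- floor(k)
  hi <- ceiling(k)
  s[lo] + (k - lo) * (s[hi] - s[lo])
}

# Full 2^n enumeration of the two-sided signed-rank p-value: every sign
# assignment to the absolute differences is equally likely under the null.
oracle_signed_rank_p <- function(d) {
  nz <- d[d != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  w_obs <- sum(r[nz > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# The acceptance-scale synthetic study and its metric grid are expensive;
# build them once per test run and share.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.acceptance_cache$study)) {
    .acceptance_cache$study <- simulate_study(n_plots = 100, seed = 20230101)
  }
  .acceptance_cache$study
}

acceptance_metrics <- function() {
  if (is.null(.acceptance_cache$metrics)) {
    .acceptance_cache$metrics <- compute_study_metrics(
      acceptance_study(), densities = c(20, 10, 5, 1),
      plot_sizes = c(0.09, 0.25, 0.5, 1), seed = 20230102
    )
  }
  .acceptance_cache$metrics
}
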