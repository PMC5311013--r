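# lidarbiomass

Airborne LiDAR is the standard tool for estimating aboveground forest
biomass (AGB, Mg ha⁻¹): structure metrics computed over field plots are
regressed against plot-level AGB from forest inventories, and the fitted
model maps biomass across the survey. Two *data models* are in common use
for deriving those metrics:

- **echo-based** — metrics computed directly from the 3D return ("echo")
  point cloud, using canopy returns (height ≥ 2 m);
- **CHM-based** — metrics computed from a 1 m canopy height model, a
  raster holding the highest return in each cell, with empty cells filled
  by Delaunay-based interpolation.

Point density (returns m⁻²) is the main cost driver of a LiDAR survey, so
a recurring operational question is how far a survey can be thinned before
the metrics — and the biomass estimates built on them — degrade, and
whether the answer depends on the data model. `lidarbiomass` packages that
comparison as a reusable, fully testable pipeline:

- a **synthetic forest simulator** (Poisson stands, paraboloid crown
  envelopes, exponential within-crown penetration, power-law
  tree-to-biomass allometry) that generates point clouds and per-plot
  "field" AGB with known ground truth;
- **point-cloud operations**: LAS/CSV reading, DEM height normalization,
  plot clipping, random thinning to a target density;
- the **ten canopy metrics** used in AGB modelling: mean, maximum,
  25/50/75/90th height percentiles, standard deviation and coefficient of
  variation of canopy height, fractional cover (FC), and the area under
  the canopy pseudo-waveform (AUCW);
- the **CHM pipeline**: per-cell maximum rasterization and
  triangulation-based filling of empty cells;
- a **factorial experiment driver** comparing metrics across point
  densities and plot sizes with paired two-sided Wilcoxon signed-rank
  tests (exact null distribution for small samples), one-sample t tests
  and a Lilliefors normality screen;
- **power-law AGB models** `ŷ = αXᵝ` and `ŷ = αx₁ᵝx₂ᵞ` (X, x₁ = mean
  canopy height; x₂ = FC), fitted by untransformed-scale nonlinear least
  squares with log-log initialization, evaluated by 70/30 holdout or
  leave-one-out jackknife (R², RMSE, relRMSE), plus the **cross-density
  transfer error** of a model calibrated at the original density and
  applied to thinned metrics.

Everything is tibble-in / tibble-out and pipe-friendly; fitted models have
`tidy()`, `glance()`, `predict()` and `autoplot()` methods.

## Worked example

Simulate a 30-plot study at 20 points m⁻², compare mean canopy height
across densities, and fit the one-variable biomass model:

```r
library(lidarbiomass)
library(dplyr)

study <- simulate_study(n_plots = 30, seed = 42)
#> <lidar_study> 30 plots (square, 1.00 ha) at 20 points/m^2; AGB 10.7-402.7 Mg/ha

metrics <- compute_study_metrics(study, densities = c(20, 5, 1),
                                 plot_sizes = 1, seed = 43)
res <- run_grid(study, densities = c(20, 5, 1), plot_sizes = 1,
                seed = 43, metrics = metrics)
res$comparisons |> filter(metric == "MeanH") |>
  select(data_model, point_density, mean_diff, sd_diff, wilcoxon_p)
#>   data_model point_density mean_diff sd_diff wilcoxon_p significant
#> 1       echo             5   -0.0037  0.0604   7.27e-01       FALSE
#> 2       echo             1    0.0286  0.0985   1.33e-01       FALSE
#> 3        chm             5    1.5045  0.4484   1.83e-06        TRUE
#> 4        chm             1    4.4293  1.7183   1.83e-06        TRUE
```

Thinning from 20 to 1 point m⁻² moves the echo-based mean canopy height
by centimetres (not significant), while the CHM-based mean drops by
4.4 m (Wilcoxon p < 1e-5): the CHM "sees" per-cell maxima, and with few
returns per cell the recorded maximum slides down into the crown.

```r
ref <- metrics |> filter(point_density == 20, data_model == "echo") |>
  left_join(study$field_agb, by = "plot_id")
fit <- fit_power_model(ref, "agb", "MeanH")
fit
#> <power_model_fit> y = 0.0102 * MeanH^3.116  (n = 30, natural scale)
glance(fit)
#>   r.squared  rmse rel_rmse  n         form converged
#> 1     0.862  42.3     26.4 30 one-variable      TRUE

thin <- metrics |> filter(point_density == 1, data_model == "echo") |>
  left_join(study$field_agb, by = "plot_id")
cross_density_apply(fit, ref, thin, study$field_agb)
#>   point_density error_pct r_squared  rmse rel_rmse  n
#> 1             1      1.48     0.866  41.6     26.0 30
```

The echo-based model calibrated at 20 points m⁻² predicts AGB from
1 point m⁻² metrics with only a 1.5 % drift relative to its own
reference-density predictions — the practical argument for thinning
surveys when echo-based metrics are used. Repeating the last step with
`data_model == "chm"` shows drifts an order of magnitude larger at
1 point m⁻².

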