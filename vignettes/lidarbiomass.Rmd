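---
title: "Echo-based vs CHM data models for LiDAR biomass estimation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echo-based vs CHM data models for LiDAR biomass estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lidarbiomass)
library(dplyr)
```

`lidarbiomass` implements a comparison framework for the two standard
representations of airborne LiDAR forest structure — the raw return cloud
("echo-based") and the 1 m canopy height model (CHM) — in the context of
aboveground biomass (AGB) estimation, together with the two experimental
axes that matter operationally: point density and field-plot size. This
vignette is the package's methods account: the models, their parameters
and units, the numerical choices, and what the synthetic data generator
does and does not emulate.

## The synthetic forest generator

Real campaigns pair an airborne point cloud with field-measured plot AGB;
neither is generally redistributable. The generator produces both with
known ground truth, so every downstream stage is testable end to end.

**Stand model.** Tree locations follow a homogeneous Poisson process with
intensity `stem_density` (trees ha⁻¹). Heights are drawn from a
configurable family; the default is Weibull with shape 3, a right-skewed
unimodal distribution commonly fitted to closed-forest height data. Each
tree carries:

- a crown from `crown_base = height × (1 − crown_ratio)` to the tip
  (`crown_ratio` defaults to 0.45, a mid-range live-crown ratio);
- a paraboloid-of-revolution crown envelope (a cone is available via
  `crown_shape`); the paraboloid gives realistic behaviour of upper-canopy
  height percentiles under sub-sampling;
- a crown radius linear in height (`0.5 + 0.10 × height` m by default);
- a synthetic stem diameter `dbh_proxy = 0.8 × height^1.2 × e^ε` (cm,
  lognormal ε with sd 0.1), the handle for the biomass allometry.

**Return sampling.** `round(target_point_density × area)` pulse positions
are drawn uniformly (one return per pulse). A pulse reaches the ground
with probability `ground_fraction` (default 0.25); otherwise, inside a
crown it returns from the local envelope height minus an exponential
penetration offset with mean `penetration × crown_depth` (default 0.1),
truncated at the crown base; outside all crowns it is a ground return at
height 0. Gaussian z-noise (sd 0.05 m, truncated at ±3 sd so height
bounds are guaranteed) and xy-jitter (sd 0.1 m) are added. The
penetration model is the mechanism that makes canopy height estimates
density-dependent: with more pulses per crown, the minimum penetration
offset among them shrinks, so the observed canopy top rises — the
behaviour the thinning experiment measures.

**Field AGB.** Tree biomass is `a × dbh_proxy^b × e^ε` (kg) with
`a = 0.05`, `b = 2.5` and lognormal noise sd 0.3 — a generic power-law
allometry standing in for the species-specific inventory equations used
with real field data. Plot AGB is the sum over trees, scaled to Mg ha⁻¹.

**Study-level variation.** `simulate_study()` draws each plot's Weibull
height scale from U(12, 32) m and its stem density from U(150, 450) ha⁻¹,
creating the between-plot AGB–height gradient (AGB roughly 10–400
Mg ha⁻¹) that biomass regression relies on. The default study is 100
plots of 1 ha sampled at 20 points m⁻², the scale at which the package's
acceptance checks run.

**What the generator does not emulate.** Flat terrain only (the DEM is
zero, so normalization is exercised but trivially invertible); one return
per pulse (no multi-return structure — the thinning procedure ignores
pulse structure anyway); no footprint, scan-angle, intensity or waveform
physics; crowns are rotationally symmetric and non-interacting. Passing
tests therefore demonstrate correctness of the pipeline and the
directional behaviour of the data models under thinning, not calibration
against any particular sensor or biome.

## Point-cloud operations

Heights are normalized as `h = z − DEM(x, y)` with bilinear DEM sampling
(exact on planar terrain; nearest-neighbour available). Returns over DEM
nodata are dropped with a warning. Heights in (−0.5, 0) m are clamped to
0 — ranging noise and DEM error routinely produce slightly sub-ground
returns — and anything below −0.5 m is dropped as an outlier.

Plots are circles or squares; clipping keeps the closed region (boundary
returns retained — a deterministic tie rule). The conventional sizes are
0.09 ha (a 16.93 m-radius circle, the common field-plot layout) through
1.0 ha squares; `default_plot_shape()` encodes the circle-below-0.1-ha
convention used by the experiment driver, and both shapes are available
at any size.

Thinning emulates a cheaper acquisition by keeping a uniform random
subset of exactly `round(target_density × area)` returns, without
replacement, per plot. It removes *returns*, not pulses; density
accounting counts all returns regardless of class. The kept subset is a
strict subset with identical fields, seeded and reproducible.

## The ten canopy metrics

Echo-based metrics are computed over canopy returns, `h ≥ 2 m` (the
threshold is configurable; the boundary case `h = 2` counts as canopy):
MaxH, MeanH, P25H/P50H/P75H/P90H, StdH, and CV = StdH/MeanH. Percentiles
use linear interpolation between order statistics (the "type 7" rule —
pinned by a sort-based oracle in the tests). A consequence of
interpolated percentiles worth knowing: duplicating every return leaves
MaxH/MeanH/FC exactly unchanged but shifts percentiles by O(range/n),
the order-statistic spacing; the tests assert exact invariance for the
former and O(1/n) invariance for the latter.

Fractional cover is `#(h ≥ threshold) / #(all returns)`, with all
returns — any class — in the denominator (first-return-only numerators
can be emulated by pre-filtering the cloud). The default threshold equals
the 2 m canopy cut-off; tall closed canopies may warrant a site-specific
threshold such as 27 m, which is why it is a separate argument.

The canopy pseudo-waveform is the normalized histogram of canopy-return
heights (0.5 m bins from the canopy threshold to MaxH rounded up to the
next bin edge), a discrete-return stand-in for a waveform's vertical
energy profile. AUCW is its trapezoidal integral over bin centres divided
by the height range, making the statistic comparable across plots of
different canopy depth. Exact published constructions of this statistic
vary; this package's construction is fully specified here and pinned by
closed-form trapezoid tests. Plots without canopy returns report `NA`
height statistics (so regressions can drop rather than absorb them),
FC = 0 and AUCW = 0.

## The CHM pipeline

The CHM holds the maximum return height per 1 m cell, with the grid
snapped to the plot bounding box; for circular plots a cell participates
if its centre is inside the plot. The *generating return* of each direct
cell is registered at its true (x, y) — not the cell centre — and those
source points are Delaunay-triangulated to fill empty cells by
piecewise-linear (barycentric) interpolation inside their convex hull
(`interp`'s compiled triangulation). This interpolation reproduces
constant fields to machine precision and planar fields to better than
1e-6 inside the hull, and every filled value is a convex combination of
its triangle's vertices, so interpolated cells never leave the range of
their generators. Cells outside the hull remain nodata and are excluded
from metrics — extrapolation beyond the data hull is unsupported. With
fewer than three non-collinear source points the raster is returned
unfilled with a warning. Interpolating an already-complete raster is a
no-op.

CHM metrics use *all* valid pixels with no 2 m cut — the raster is the
canopy surface, and its low pixels carry information the echo threshold
deliberately removes; this asymmetry between the data models is itself
one of the findings the pipeline reproduces (CHM dispersion metrics react
to density when echo ones do not). The CHM waveform is built over pixel
heights from 0 m; CHM FC uses the same 2 m default threshold as the echo
side, configurable.

Two cross-model facts anchor the implementation: the CHM maximum can
never exceed the echo maximum (it is built from the same returns, and
interpolation cannot exceed its generators), and at densities where every
cell is direct the two maxima coincide exactly.

## The experiment driver

`compute_study_metrics()` evaluates both data models over the full
(plot × plot-size × density) grid, thinning per plot after clipping, with
a per-condition seed derived from the master seed by a stated counter
scheme (`derive_seed()`), so any single condition can be re-run in
isolation and the whole grid is bit-reproducible.

`run_grid()` forms per-plot paired differences (reference minus
alternative), pairing by plot id and dropping undefined rows pairwise,
and applies:

- the two-sided Wilcoxon signed-rank test — zeros dropped, mid-ranks for
  ties, the *exact* null distribution (computed by convolution, valid
  under mid-rank ties) for n ≤ 25 after zero removal, and a normal
  approximation with tie and continuity corrections above; all-zero
  differences are reported as the degenerate p = 1;
- a two-sided one-sample t test of the mean difference (degenerate
  zero-variance samples report p = 1 or 0 by the sign of the mean);
- a Lilliefors-corrected Kolmogorov–Smirnov normality screen
  (`nortest::lillie.test`) for reporting only — a plain KS test with
  estimated parameters would be anti-conservative, and the screen never
  gates which paired test runs.

Significance is flagged at α = 0.05 from the Wilcoxon p-value. No
multiple-testing correction is applied by default, matching the common
reporting style for these metric grids; `p_adjust = "holm"` is available.
The type-I error of the Wilcoxon implementation is verified by simulation
(2,000 null replicates at n = 60) to sit within [0.040, 0.060] at
α = 0.05.

## Biomass models

Two power forms are fitted: `ŷ = αXᵝ` on mean canopy height, and
`ŷ = αx₁ᵝx₂ᵞ` adding fractional cover. Fitting is nonlinear least
squares on the untransformed scale (Levenberg–Marquardt via
`minpack.lm`), so the minimized criterion is the same squared error that
RMSE reports in Mg ha⁻¹; starting values come from OLS on the log-log
model, the converged fit never exceeds the SSE of that initialization,
and parameter standard deviations come from the asymptotic covariance. A
log-scale OLS mode exists for sensitivity analysis. Evaluation reports
`R² = 1 − SSE/SST`, `RMSE = √(SSE/n)` and `relRMSE = 100·RMSE/mean(y)`
(the observed mean of the evaluation set — the standard convention).

Validation is a 70/30 plot-level random holdout
(`round(0.7 n)` calibration plots) for adequate samples, or leave-one-out
jackknife below five plots; the jackknife also reports the mean and
standard deviation of the parameters over the n refits, the usual
uncertainty statement for small-sample allometric fits.

`cross_density_apply()` quantifies model transfer across densities: a
model calibrated on reference-density metrics is fed the same plots'
thinned-density metrics, and the headline error is the RMS difference
between thinned-input and reference-input predictions as a percentage of
the mean reference-input prediction (the evaluation against observed AGB
is reported alongside).

## Design choices and known limitations

- **Form choice for the model-similarity property.** At the original
  density the echo and CHM *two-variable* (height + cover) models reach
  nearly identical R² on synthetic studies, and that form carries the
  "both data models perform similarly" property test. The one-variable
  echo model lags the CHM one on this generator: per-tree allometric
  noise (sd 0.3) averages out over the ~300 trees of a 1 ha plot, leaving
  plot AGB almost deterministic in stand structure, and the 2 m canopy
  threshold bends the echo height–AGB relation in a way a single power
  term cannot absorb. Adding cover restores the echo model — the same
  qualitative improvement that motivates including FC with real data.
- **Plot-level AGB noise.** Because allometric noise is independent per
  tree, synthetic R² values at 1 ha are higher than typical field
  studies; the comparison *between* data models and *across* densities is
  the meaningful output, not the absolute R².
- **Thinning is return-wise**, so it changes sample size only; footprint,
  pulse power and penetration physics do not co-vary with density as they
  would when PRF or flying height actually change.
- **Normalization always uses the true (flat) DEM**; re-deriving a DEM
  from thinned ground returns — which would add a second density effect
  through terrain error — is out of scope.
- **Problem sizes.** The package's acceptance checks run a 100-plot,
  1 ha, 20 points m⁻² study over densities 20/10/5/1 and plot sizes
  0.09/0.25/0.5/1.0 ha — about 20 million returns and 3,200 metric
  vectors — chosen as the smallest study at which the paired tests have
  stable power across the full grid.
- **Numerical details.** Exact Wilcoxon enumeration is O(n²·max W) via
  convolution (doubled mid-ranks keep scores integral); quantile type 7
  everywhere; bilinear DEM sampling clamps to edge cell centres, so
  queries in the outer half-cell ring are edge-extended; thinning with a
  target at or above the current density is a warning-level no-op, never
  an up-sample.

## A small end-to-end run

```{r example, eval = FALSE}
study <- simulate_study(n_plots = 30, seed = 42)
metrics <- compute_study_metrics(study, densities = c(20, 5, 1),
                                 plot_sizes = 1, seed = 43)
res <- run_grid(study, densities = c(20, 5, 1), plot_sizes = 1,
                seed = 43, metrics = metrics)
significance_matrix(res)

ref <- metrics |>
  filter(point_density == 20, data_model == "echo") |>
  left_join(study$field_agb, by = "plot_id")
fit <- fit_power_model(ref, "agb", "MeanH")
glance(fit)
autoplot(fit)
```
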