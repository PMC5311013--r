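Package: lidarbiomass
Title: Echo-Based and Canopy-Height-Model LiDAR Data Models for Forest
    Biomass Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to compare the two standard data models for airborne
    LiDAR forest analysis, the 3D return point cloud ("echo-based") and the
    1 m canopy height model (CHM), in the context of aboveground biomass
    (AGB) estimation.  Provides a synthetic forest stand and discrete-return
    point-cloud simulator with known power-law biomass ground truth;
    point-cloud reading, height normalization against a DEM, plot clipping
    and random thinning to target point densities; the ten canopy structure
    metrics commonly used in AGB modelling (height percentiles, mean,
    maximum and dispersion of canopy height, fractional cover, and the area
    under the canopy pseudo-waveform); CHM construction by per-cell maximum
    with Delaunay-based interpolation of empty cells; a factorial experiment
    driver comparing metrics across point densities and plot sizes with
    paired Wilcoxon signed-rank and t tests; and power-law AGB model
    fitting, holdout and jackknife evaluation, and cross-density model
    transfer error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    interp,
    jsonlite,
    minpack.lm,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
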