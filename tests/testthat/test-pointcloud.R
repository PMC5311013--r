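test_that("CSV point clouds read and write faithfully", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z,class", "1,2,3,5", "4.5,5.5,6.5,2", "7,8,9,5"), path)
  cloud <- read_point_cloud(path)
  expect_identical(nrow(cloud), 3L)
  expect_equal(cloud$z, c(3, 6.5, 9))
  expect_equal(cloud$class, c(5L, 2L, 5L))

  # empty file: empty cloud plus warning, not an error
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_warning(c0 <- read_point_cloud(empty), "Empty")
  expect_identical(nrow(c0), 0L)

  # malformed record names the offender
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "1,2,3", "1,oops,3"), bad)
  expect_error(read_point_cloud(bad), "column y, record 2")
})

test_that("LAS round-trips simulator output within format precision", {
  cfg <- stand_config(extent_m = c(15, 15), stem_density = 400,
                      target_point_density = 3, seed = 21)
  cloud <- sample_returns(simulate_stand(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".las")
  write_point_cloud(cloud, path)
  back <- read_point_cloud(path)
  expect_identical(nrow(back), nrow(cloud))
  expect_equal(back$x, cloud$x, tolerance = 1e-3)
  expect_equal(back$y, cloud$y, tolerance = 1e-3)
  expect_equal(back$z, cloud$h, tolerance = 1e-3)
  expect_identical(back$class, cloud$class)
})

test_that("height normalization is exact on flat, offset and tilted DEMs", {
  cloud <- tibble::tibble(x = c(2, 5, 8), y = c(2, 5, 8),
                          z = c(12.4, 3, 112.4), class = 5L)
  flat <- dem_raster(matrix(0, 12, 12))
  n1 <- normalize_heights(cloud, flat)
  expect_equal(n1$h, cloud$z)

  shifted <- dem_raster(matrix(100, 12, 12))
  n2 <- normalize_heights(tibble::tibble(x = 5, y = 5, z = 112.4,
                                         class = 2L), shifted)
  expect_equal(n2$h, 12.4)

  # bilinear sampling reproduces a planar DEM exactly
  grid <- expand.grid(i = 1:30, j = 1:30)
  plane <- function(x, y) 50 + 0.4 * x - 0.25 * y
  dem <- dem_raster(matrix(plane((grid$j - 0.5), (grid$i - 0.5)),
                           nrow = 30, ncol = 30))
  set.seed(4)
  pts <- tibble::tibble(x = runif(20, 2, 28), y = runif(20, 2, 28))
  pts$z <- plane(pts$x, pts$y) + 7
  n3 <- normalize_heights(dplyr::mutate(pts, class = 5L), dem)
  expect_equal(n3$h, rep(7, 20), tolerance = 1e-9)

  # returns outside the DEM extent are an error
  expect_error(
    normalize_heights(tibble::tibble(x = 99, y = 5, z = 1, class = 2L),
                      flat),
    "outside the DEM extent"
  )
})

test_that("sub-ground heights are clamped or dropped by policy", {
  dem <- dem_raster(matrix(10, 12, 12))
  cloud <- tibble::tibble(x = c(5, 5, 5), y = c(5, 5, 5),
                          z = c(9.8, 9.4, 20), class = 2L)
  expect_warning(norm <- normalize_heights(cloud, dem), "below ground")
  expect_equal(norm$h, c(0, 10))     # -0.2 clamped, -0.6 dropped
})

test_that("plot clipping keeps the closed region and matches brute force", {
  circle <- plot_geometry(0, 0, "circle", dimension = 10)
  boundary <- tibble::tibble(x = 10, y = 0, h = 1, class = 5L)
  expect_identical(nrow(clip_to_plot(boundary, circle)), 1L)
  square <- plot_geometry(0, 0, "square", dimension = 10)
  edge <- tibble::tibble(x = 5, y = -5, h = 1, class = 5L)
  expect_identical(nrow(clip_to_plot(edge, square)), 1L)

  # standard 0.09 ha circle: radius ~ 16.9 m
  p09 <- plot_geometry(0, 0, "circle", area_ha = 0.09)
  expect_equal(p09$dimension, sqrt(900 / pi), tolerance = 1e-12)
  expect_equal(p09$dimension, 16.9, tolerance = 0.01)

  set.seed(9)
  cloud <- tibble::tibble(x = runif(100, -12, 12), y = runif(100, -12, 12),
                          h = runif(100), class = 5L)
  for (plt in list(circle, square)) {
    kept <- clip_to_plot(cloud, plt)
    manual <- vapply(seq_len(100), function(i) {
      if (plt$shape == "circle") {
        sqrt(cloud$x[i]^2 + cloud$y[i]^2) <= plt$dimension
      } else {
        abs(cloud$x[i]) <= plt$dimension / 2 &&
          abs(cloud$y[i]) <= plt$dimension / 2
      }
    }, logical(1))
    expect_identical(nrow(kept), sum(manual))
    expect_setequal(paste(kept$x, kept$y),
                    paste(cloud$x[manual], cloud$y[manual]))
  }
})

test_that("normalization and clipping commute on flat terrain", {
  dem <- dem_raster(matrix(25, 40, 40))
  set.seed(10)
  cloud <- tibble::tibble(x = runif(300, 0, 40), y = runif(300, 0, 40),
                          z = 25 + runif(300, 0, 20), class = 5L)
  plt <- plot_geometry(20, 20, "circle", dimension = 12)
  a <- clip_to_plot(normalize_heights(cloud, dem), plt)
  b <- normalize_heights(clip_to_plot(cloud, plt), dem)
  expect_equal(a, b)
})

test_that("thinning keeps an exact-count strict subset, reproducibly", {
  plt <- plot_geometry(5, 5, "square", dimension = 10) # 100 m^2
  set.seed(2)
  cloud <- tibble::tibble(x = runif(1000, 0, 10), y = runif(1000, 0, 10),
                          h = runif(1000, 0, 30), class = 5L)
  thin <- thin_to_density(cloud, plt, 5, seed = 1)
  expect_identical(nrow(thin), 500L)
  expect_equal(point_density(thin, plt), 5)
  # strict subset with identical fields
  key <- function(d) paste(d$x, d$y, d$h, d$class)
  expect_true(all(key(thin) %in% key(cloud)))

  # determinism and seed sensitivity
  expect_identical(thin_to_density(cloud, plt, 5, seed = 1), thin)
  distinct <- vapply(1:10, function(s) {
    !identical(thin_to_density(cloud, plt, 5, seed = 100 + s)$x, thin$x)
  }, logical(1))
  expect_true(all(distinct))

  # cannot up-sample: unchanged cloud with a warning
  expect_warning(same <- thin_to_density(cloud, plt, 11, seed = 1),
                 "unchanged")
  expect_identical(same$x, cloud$x)
  # target equal to current density: no-op
  noop <- thin_to_density(cloud, plt, 10, seed = 1)
  expect_identical(noop$x, cloud$x)
})

test_that("point density is count over area", {
  plt <- plot_geometry(5, 5, "square", dimension = 10)
  cloud <- tibble::tibble(x = runif(500, 0, 10), y = runif(500, 0, 10),
                          h = 1, class = 5L)
  expect_equal(point_density(cloud, plt), 5)
  expect_equal(point_density(cloud[0, ], plt), 0)
  cfg <- stand_config(extent_m = c(50, 50), stem_density = 300,
                      target_point_density = 20, seed = 31)
  cloud2 <- sample_returns(simulate_stand(cfg), cfg)
  full <- plot_geometry(25, 25, "square", dimension = 50)
  expect_gte(point_density(clip_to_plot(cloud2, full), full), 19)
})
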