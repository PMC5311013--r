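square_plot <- function(side, center = side / 2) {
  plot_geometry(center, center, "square", dimension = side)
}

test_that("rasterization keeps the per-cell maximum and its source point", {
  plt <- square_plot(3)
  # one return per cell: CHM equals the heights
  cloud <- tibble::tibble(
    x = rep(c(0.5, 1.5, 2.5), 3),
    y = rep(c(0.5, 1.5, 2.5), each = 3),
    h = 1:9, class = 5L
  )
  chm <- rasterize_max_height(cloud, plt)
  expect_equal(sort(as.vector(chm$height)), 1:9)
  expect_true(all(chm$status == "direct"))

  # a multi-return cell reports its maximum
  cloud2 <- tibble::tibble(x = c(0.2, 0.3, 0.8), y = 0.5,
                           h = c(3.2, 7.9, 5.1), class = 5L)
  chm2 <- rasterize_max_height(cloud2, square_plot(1))
  expect_equal(chm2$height[1, 1], 7.9)
  expect_equal(chm2$source_points$h, 7.9)
  expect_equal(chm2$source_points$x, 0.3)

  expect_error(rasterize_max_height(cloud, plt, resolution = 0),
               "resolution")
})

test_that("rasterization matches a brute-force per-cell max scan", {
  plt <- square_plot(50)
  for (rep in 1:3) {
    set.seed(100 + rep)
    n <- 2000
    cloud <- tibble::tibble(x = runif(n, 0, 50), y = runif(n, 0, 50),
                            h = runif(n, 0, 40), class = 5L)
    chm <- rasterize_max_height(cloud, plt)
    brute <- matrix(NA_real_, 50, 50)
    for (k in seq_len(n)) {
      i <- min(floor(cloud$y[k]), 49) + 1
      j <- min(floor(cloud$x[k]), 49) + 1
      brute[i, j] <- max(brute[i, j], cloud$h[k], na.rm = TRUE)
    }
    expect_identical(chm$height, brute)
  }
})

test_that("empty-cell interpolation reproduces constants and planes", {
  plt <- square_plot(30)
  set.seed(11)
  base <- tibble::tibble(x = runif(250, 0, 30), y = runif(250, 0, 30),
                         class = 5L)
  # constant field
  cloud_c <- dplyr::mutate(base, h = 7)
  chm_c <- interpolate_empty_cells(rasterize_max_height(cloud_c, plt))
  px <- tibble::as_tibble(chm_c)
  expect_gt(sum(px$status == "interpolated"), 0)
  expect_equal(px$h[px$status != "nodata"],
               rep(7, sum(px$status != "nodata")))

  # planar field, interior cells match the plane to 1e-6
  cloud_p <- dplyr::mutate(base, h = 5 + 0.2 * x + 0.1 * y)
  chm_p <- interpolate_empty_cells(rasterize_max_height(cloud_p, plt))
  pp <- tibble::as_tibble(chm_p)
  ii <- pp$status == "interpolated"
  expect_gt(sum(ii), 0)
  expect_lt(max(abs(pp$h[ii] - (5 + 0.2 * pp$x[ii] + 0.1 * pp$y[ii]))),
            1e-6)

  # interpolated values never leave the source range
  expect_gte(min(pp$h[ii]), min(chm_p$source_points$h))
  expect_lte(max(pp$h[ii]), max(chm_p$source_points$h))
})

test_that("cells outside the convex hull stay nodata; degenerate inputs warn", {
  plt <- square_plot(20)
  # returns confined to the lower-left: far corner has no hull coverage
  set.seed(13)
  cloud <- tibble::tibble(x = runif(100, 0, 8), y = runif(100, 0, 8),
                          h = runif(100, 5, 10), class = 5L)
  chm <- interpolate_empty_cells(rasterize_max_height(cloud, plt))
  expect_identical(chm$status[20, 20], "nodata")

  few <- tibble::tibble(x = c(1, 2), y = c(1, 2), h = c(5, 6), class = 5L)
  expect_warning(
    chm2 <- interpolate_empty_cells(rasterize_max_height(few, plt)),
    "non-collinear"
  )
  expect_true(all(chm2$status %in% c("direct", "nodata", "outside")))

  # collinear source points are degenerate too
  lin <- tibble::tibble(x = c(1.5, 5.5, 9.5), y = c(1.5, 5.5, 9.5),
                        h = c(5, 6, 7), class = 5L)
  expect_warning(interpolate_empty_cells(rasterize_max_height(lin, plt)),
                 "non-collinear")
})

test_that("interpolating a complete raster changes nothing", {
  plt <- square_plot(4)
  cloud <- tibble::tibble(
    x = rep(seq(0.5, 3.5), 4), y = rep(seq(0.5, 3.5), each = 4),
    h = runif(16, 3, 9), class = 5L
  )
  chm <- rasterize_max_height(cloud, plt)
  expect_identical(interpolate_empty_cells(chm), chm)
})

test_that("CHM metrics summarise all valid pixels with no height cut", {
  plt <- square_plot(10)
  grid <- expand.grid(x = seq(0.5, 9.5), y = seq(0.5, 9.5))
  uniform <- tibble::tibble(x = grid$x, y = grid$y, h = 10, class = 5L)
  m <- compute_chm_metrics(rasterize_max_height(uniform, plt))
  expect_equal(m$MeanH, 10)
  expect_equal(m$MaxH, 10)
  expect_equal(m$StdH, 0)
  expect_equal(m$FC, 1)

  half <- tibble::tibble(x = grid$x, y = grid$y,
                         h = rep(c(0, 10), each = 50), class = 5L)
  m2 <- compute_chm_metrics(rasterize_max_height(half, plt))
  expect_equal(m2$FC, 0.5)
  expect_equal(m2$MeanH, 5) # sub-2 m pixels stay in the height stats

  empty <- rasterize_max_height(uniform[0, ], plt)
  m3 <- compute_chm_metrics(empty)
  expect_true(is.na(m3$MeanH) && is.na(m3$FC))
})

test_that("echo and CHM agree where the data models must coincide", {
  cfg <- dense_config(seed = 55, extent = c(30, 30), density = 25)
  cloud <- sample_returns(simulate_stand(cfg), cfg)
  plt <- square_plot(30)
  clipped <- clip_to_plot(cloud, plt)
  chm <- interpolate_empty_cells(rasterize_max_height(clipped, plt))
  me <- compute_echo_metrics(clipped)
  mc <- compute_chm_metrics(chm)
  # every cell direct at 25 points/m^2: both models see the global maximum
  expect_true(all(chm$status[chm$in_plot] == "direct"))
  expect_equal(mc$MaxH, me$MaxH)
})

test_that("CHM maxima never exceed echo maxima; CHM means exceed echo means on dense canopies", {
  diffs_max <- c()
  diffs_mean <- c()
  for (s in 1:8) {
    cfg <- dense_config(seed = 200 + s, extent = c(30, 30), density = 8)
    cloud <- sample_returns(simulate_stand(cfg), cfg)
    plt <- square_plot(30)
    clipped <- clip_to_plot(cloud, plt)
    chm <- interpolate_empty_cells(rasterize_max_height(clipped, plt))
    me <- compute_echo_metrics(clipped)
    mc <- compute_chm_metrics(chm)
    expect_lte(mc$MaxH, me$MaxH)
    diffs_mean <- c(diffs_mean, mc$MeanH - me$MeanH)
  }
  expect_gt(mean(diffs_mean), 0)
})
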