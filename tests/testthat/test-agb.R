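test_that("noiseless power-law data are recovered exactly", {
  X <- c(5, 10, 15, 20, 25)
  d1 <- tibble::tibble(MeanH = X, agb = 2 * X^1.5)
  f1 <- fit_power_model(d1, "agb", "MeanH")
  expect_equal(unname(f1$coefficients["a"]), 2, tolerance = 1e-6)
  expect_equal(unname(f1$coefficients["b"]), 1.5, tolerance = 1e-6)
  g1 <- glance(f1)
  expect_equal(g1$r.squared, 1, tolerance = 1e-9)
  expect_equal(g1$rmse, 0, tolerance = 1e-6)

  d2 <- tibble::tibble(x1 = c(5, 8, 11, 14, 17),
                       x2 = c(0.3, 0.5, 0.6, 0.8, 0.9))
  d2$agb <- 3 * d2$x1^1.2 * d2$x2^-0.5
  f2 <- fit_power_model(d2, "agb", "x1", "x2")
  expect_equal(unname(f2$coefficients), c(3, 1.2, -0.5), tolerance = 1e-6)

  # guards
  expect_error(fit_power_model(tibble::tibble(MeanH = c(1, -2, 3),
                                              agb = c(1, 2, 3)),
                               "agb", "MeanH"),
               "Non-positive")
  expect_error(fit_power_model(d1[1:2, ], "agb", "MeanH"), "at least 3")
})

test_that("parameter recovery under lognormal noise is unbiased", {
  reps <- 100
  betas <- numeric(reps)
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(3000 + r)
    X <- runif(100, 5, 30)
    y <- 2.5 * X^1.6 * exp(rnorm(100, 0, 0.2))
    f <- fit_power_model(tibble::tibble(MeanH = X, agb = y), "agb", "MeanH")
    betas[r] <- f$coefficients[["b"]]
    covered[r] <- abs(f$coefficients[["b"]] - 1.6) <=
      2 * f$std_errors[["b"]]
  }
  mc_se <- sd(betas) / sqrt(reps)
  expect_lt(abs(mean(betas) - 1.6), 3 * mc_se)
  expect_gte(mean(covered), 0.90)
})

test_that("converged NLS never exceeds the SSE of its log-OLS start", {
  for (r in 1:10) {
    set.seed(4000 + r)
    X <- runif(40, 5, 30)
    y <- 3 * X^1.4 * exp(rnorm(40, 0, 0.35))
    d <- tibble::tibble(MeanH = X, agb = y)
    f_nls <- fit_power_model(d, "agb", "MeanH")
    f_log <- fit_power_model(d, "agb", "MeanH", scale = "log")
    sse <- function(f) sum((y - predict(f, d))^2)
    expect_lte(sse(f_nls), sse(f_log) + 1e-8)
  }
})

test_that("evaluation statistics match their definitions", {
  y <- c(100, 200, 300)
  pred <- c(110, 190, 310)
  ev <- lidarbiomass:::evaluate_predictions(y, pred)
  expect_equal(ev$rmse, 10)
  expect_equal(ev$rel_rmse, 5)
  expect_equal(ev$r_squared, 1 - 300 / 20000)

  d <- tibble::tibble(MeanH = c(5, 10, 15), agb = 2 * c(5, 10, 15)^1.5)
  f <- fit_power_model(d, "agb", "MeanH")
  ev2 <- evaluate_power_model(f, d, protocol = "insample")
  expect_equal(ev2$r_squared, 1, tolerance = 1e-9)
  expect_equal(ev2$rmse, 0, tolerance = 1e-6)
  expect_equal(ev2$rel_rmse, 0, tolerance = 1e-6)
})

test_that("scale equivariance: rescaling AGB rescales only a and RMSE", {
  set.seed(21)
  X <- runif(50, 5, 30)
  y <- 2 * X^1.5 * exp(rnorm(50, 0, 0.2))
  d <- tibble::tibble(MeanH = X, agb = y)
  dc <- tibble::tibble(MeanH = X, agb = 10 * y)
  f <- fit_power_model(d, "agb", "MeanH")
  fc <- fit_power_model(dc, "agb", "MeanH")
  expect_equal(fc$coefficients[["a"]], 10 * f$coefficients[["a"]],
               tolerance = 1e-4)
  expect_equal(fc$coefficients[["b"]], f$coefficients[["b"]],
               tolerance = 1e-5)
  g <- glance(f)
  gc <- glance(fc)
  expect_equal(gc$rmse, 10 * g$rmse, tolerance = 1e-5)
  expect_equal(gc$r.squared, g$r.squared, tolerance = 1e-8)
  expect_equal(gc$rel_rmse, g$rel_rmse, tolerance = 1e-6)
})

test_that("holdout split is seeded, disjoint and exhaustive", {
  ids <- sprintf("p%02d", 1:65)
  sp <- holdout_split(ids, seed = 5)
  expect_identical(length(sp$calibration), 46L) # round(0.7 * 65)
  expect_identical(length(sp$validation), 19L)
  expect_identical(holdout_split(ids, seed = 5), sp)
  set.seed(22)
  for (r in 1:50) {
    n <- sample(5:120, 1)
    s <- holdout_split(sprintf("q%d", 1:n), seed = r)
    expect_identical(length(s$calibration), round(0.7 * n) |> as.integer())
    expect_length(intersect(s$calibration, s$validation), 0)
    expect_setequal(c(s$calibration, s$validation), sprintf("q%d", 1:n))
  }
  expect_error(holdout_split(ids[1:4]), "jackknife")
})

test_that("jackknife recovers noiseless fits exactly and is pessimistic on noise", {
  X <- c(4, 6, 8, 10, 12, 14, 16, 18, 20)
  d <- tibble::tibble(plot_id = letters[1:9], MeanH = X, agb = 2 * X^1.5)
  jk <- jackknife_evaluate(d, "agb", "MeanH")
  expect_identical(nrow(jk$parameters), 9L)
  expect_equal(jk$evaluation$rmse, 0, tolerance = 1e-6)
  expect_equal(jk$parameter_summary$sd, c(0, 0), tolerance = 1e-6)
  expect_equal(jk$parameter_summary$mean[jk$parameter_summary$term == "a"],
               2, tolerance = 1e-6)

  worse <- 0
  for (r in 1:20) {
    set.seed(5000 + r)
    Xn <- runif(20, 5, 30)
    dn <- tibble::tibble(MeanH = Xn,
                         agb = 2 * Xn^1.5 * exp(rnorm(20, 0, 0.25)))
    jkn <- jackknife_evaluate(dn, "agb", "MeanH")
    fn <- fit_power_model(dn, "agb", "MeanH")
    worse <- worse + (jkn$evaluation$rmse >= glance(fn)$rmse)
  }
  # out-of-fit predictions cannot beat in-sample fits systematically
  expect_gte(worse, 19)
})

test_that("cross-density application measures prediction drift", {
  set.seed(23)
  ref <- tibble::tibble(plot_id = sprintf("p%d", 1:40),
                        MeanH = runif(40, 8, 28),
                        point_density = 20)
  agb <- tibble::tibble(plot_id = ref$plot_id,
                        agb = 2 * ref$MeanH^1.5 * exp(rnorm(40, 0, 0.15)))
  fit <- fit_power_model(dplyr::left_join(ref, agb, by = "plot_id"),
                         "agb", "MeanH")
  # identical metrics: zero drift
  same <- cross_density_apply(fit, ref, ref, agb)
  expect_equal(same$error_pct, 0)
  # downward-biased heights: positive drift, larger for larger bias
  thin5 <- dplyr::mutate(ref, MeanH = MeanH * 0.98, point_density = 5)
  thin1 <- dplyr::mutate(ref, MeanH = MeanH * 0.85, point_density = 1)
  e5 <- cross_density_apply(fit, ref, thin5, agb)
  e1 <- cross_density_apply(fit, ref, thin1, agb)
  expect_gt(e5$error_pct, 0)
  expect_gt(e1$error_pct, e5$error_pct)
  expect_error(
    cross_density_apply(fit, ref, dplyr::slice(thin5, 1:10), agb),
    "different plots"
  )
})
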