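#' Fit a power-law biomass model
#'
#' Fits `y = a * x1^b` (one-variable: AGB on mean canopy height) or
#' `y = a * x1^b * x2^g` (two-variable: adding fractional cover) by
#' nonlinear least squares on the untransformed scale
#' (Levenberg-Marquardt), so the minimized criterion matches the RMSE
#' reported in Mg/ha.  Starting values come from ordinary least squares on
#' the log-log model; the converged fit never has a higher SSE than that
#' initialization.  Set `scale = "log"` to instead keep the log-log OLS fit
#' (a sensitivity-analysis mode).
#'
#' @param data Data frame of calibration plots.
#' @param response,x1,x2 Column names (strings): observed AGB (Mg/ha),
#'   mean canopy height (m), and optionally fractional cover.  All values
#'   must be positive.  `x2 = NULL` selects the one-variable form.
#' @param scale `"natural"` (default, NLS) or `"log"` (log-log OLS).
#' @param data_model,calibration_density Optional provenance tags.
#' @return A `power_model_fit` with [generics::tidy()] /
#'   [generics::glance()] / [predict()] methods.
#' @examples
#' d <- tibble::tibble(MeanH = c(5, 10, 15, 20, 25),
#'                     agb = 2 * c(5, 10, 15, 20, 25)^1.5)
#' fit <- fit_power_model(d, "agb", "MeanH")
#' generics::tidy(fit)  # recovers a = 2, b = 1.5
#' @export
fit_power_model <- function(data, response = "agb", x1 = "MeanH", x2 = NULL,
                            scale = c("natural", "log"),
                            data_model = NA_character_,
                            calibration_density = NA_real_) {
  scale <- match.arg(scale)
  cols <- c(response, x1, x2)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  two_var <- !is.null(x2)
  keep <- complete.cases(data[, cols])
  df <- data.frame(
    y = data[[response]][keep],
    x1 = data[[x1]][keep]
  )
  if (two_var) df$x2 <- data[[x2]][keep]
  bad <- df$y <= 0 | df$x1 <= 0 | (if (two_var) df$x2 <= 0 else FALSE)
  if (any(bad)) {
    ids <- if ("plot_id" %in% names(data)) {
      paste(data$plot_id[keep][bad], collapse = ", ")
    } else {
      paste(which(bad), collapse = ", ")
    }
    abort(paste0("Non-positive response/predictor values for plots: ", ids))
  }
  n_min <- if (two_var) 4L else 3L
  if (nrow(df) < n_min) {
    abort(sprintf("Need at least %d plots to fit this form.", n_min))
  }
  log_fit <- if (two_var) {
    lm(log(y) ~ log(x1) + log(x2), data = df)
  } else {
    lm(log(y) ~ log(x1), data = df)
  }
  lc <- coef(log_fit)
  start <- if (two_var) {
    list(a = unname(exp(lc[1])), b = unname(lc[2]), g = unname(lc[3]))
  } else {
    list(a = unname(exp(lc[1])), b = unname(lc[2]))
  }
  formula <- if (two_var) y ~ a * x1^b * x2^g else y ~ a * x1^b
  if (scale == "log") {
    coefs <- unlist(start)
    se <- summary(log_fit)$coefficients[, 2]
    se[1] <- se[1] * coefs[1] # delta method for a = exp(intercept)
    fit <- log_fit
    converged <- TRUE
  } else {
    fit <- NULL
    for (attempt in 1:3) {
      st <- start
      if (attempt > 1) { # restart policy: perturb the initialization
        st <- purrr::map(start, ~ .x * (1 + 0.1 * (attempt - 1)))
      }
      fit <- tryCatch(
        minpack.lm::nlsLM(
          formula, data = df, start = st,
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      abort(paste0(
        "Power-model fit did not converge after restarts; ",
        "log-linear fallback: ",
        paste(sprintf("%s = %.4g", names(start), unlist(start)),
              collapse = ", ")
      ))
    }
    coefs <- coef(fit)
    se <- summary(fit)$coefficients[, 2]
    converged <- fit$convInfo$isConv %||% TRUE
  }
  structure(
    list(
      fit = fit,
      form = if (two_var) "two-variable" else "one-variable",
      scale = scale,
      coefficients = coefs,
      std_errors = se,
      response = response, x1 = x1, x2 = x2,
      n = nrow(df),
      data_model = data_model,
      calibration_density = calibration_density,
      converged = isTRUE(converged),
      training = df
    ),
    class = "power_model_fit"
  )
}

#' @export
print.power_model_fit <- function(x, ...) {
  cf <- x$coefficients
  eq <- if (x$form == "two-variable") {
    sprintf("y = %.4g * %s^%.4g * %s^%.4g", cf[["a"]], x$x1, cf[["b"]],
            x$x2, cf[["g"]])
  } else {
    sprintf("y = %.4g * %s^%.4g", cf[["a"]], x$x1, cf[["b"]])
  }
  cat(sprintf("<power_model_fit> %s  (n = %d, %s scale)\n",
              eq, x$n, x$scale))
  invisible(x)
}

#' Predict from a power-law biomass model
#'
#' @param object A [fit_power_model()] result.
#' @param newdata Data frame with the fit's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predicted AGB (Mg/ha).
#' @export
predict.power_model_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  x1 <- newdata[[object$x1]]
  if (is.null(x1)) abort(sprintf("`newdata` lacks column '%s'.", object$x1))
  pred <- cf[["a"]] * x1^cf[["b"]]
  if (object$form == "two-variable") {
    x2 <- newdata[[object$x2]]
    if (is.null(x2)) abort(sprintf("`newdata` lacks column '%s'.", object$x2))
    pred <- pred * x2^cf[["g"]]
  }
  unname(pred)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficients of a power-law biomass model
#'
#' @param x A `power_model_fit`.
#' @param ... Unused.
#' @return Tibble `term` (`a`, `b`, `g`), `estimate`, `std.error`.
#' @method tidy power_model_fit
#' @export
tidy.power_model_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors)
  )
}

#' One-row summary of a power-law biomass model
#'
#' In-sample evaluation statistics plus fit metadata.
#'
#' @param x A `power_model_fit`.
#' @param ... Unused.
#' @return Tibble `r.squared`, `rmse`, `rel_rmse`, `n`, `form`,
#'   `converged`.
#' @method glance power_model_fit
#' @export
glance.power_model_fit <- function(x, ...) {
  nd <- x$training
  names(nd)[names(nd) == "x1"] <- x$x1
  if (!is.null(x$x2)) names(nd)[names(nd) == "x2"] <- x$x2
  ev <- evaluate_predictions(x$training$y, predict(x, nd))
  tibble(
    r.squared = ev$r_squared, rmse = ev$rmse, rel_rmse = ev$rel_rmse,
    n = x$n, form = x$form, converged = x$converged
  )
}

evaluate_predictions <- function(y, pred) {
  n <- length(y)
  if (n == 0) abort("Cannot evaluate on zero plots.")
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  rmse <- sqrt(sse / n)
  list(
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
    rmse = rmse,
    rel_rmse = 100 * rmse / mean(y),
    n = n
  )
}

#' Evaluate a fitted biomass model on a plot set
#'
#' Computes `R^2 = 1 - SSE/SST` (about the observed mean),
#' `RMSE = sqrt(SSE/n)` (Mg/ha) and `relRMSE = 100 * RMSE / mean(y)` (%).
#'
#' @param fit A [fit_power_model()] result.
#' @param data Evaluation plots (must contain the fit's predictor columns
#'   and the response).
#' @param protocol Tag recorded in the output (`"holdout"`, `"insample"`,
#'   `"cross-density"`, ...).
#' @return One-row tibble: `r_squared`, `rmse`, `rel_rmse`, `n`,
#'   `protocol`, `data_model`, `point_density`.
#' @examples
#' d <- tibble::tibble(MeanH = c(5, 10, 15), agb = 2 * c(5, 10, 15)^1.5)
#' fit <- fit_power_model(d, "agb", "MeanH")
#' evaluate_power_model(fit, d)  # R^2 = 1, RMSE = 0
#' @export
evaluate_power_model <- function(fit, data, protocol = "holdout") {
  y <- data[[fit$response]]
  if (is.null(y)) abort(sprintf("`data` lacks column '%s'.", fit$response))
  keep <- complete.cases(data[, c(fit$response, fit$x1, fit$x2)])
  y <- y[keep]
  pred <- predict(fit, data[keep, , drop = FALSE])
  ev <- evaluate_predictions(y, pred)
  tibble(
    r_squared = ev$r_squared, rmse = ev$rmse, rel_rmse = ev$rel_rmse,
    n = ev$n, protocol = protocol,
    data_model = fit$data_model, point_density = fit$calibration_density
  )
}

#' Split plots into calibration and validation sets
#'
#' Simple random plot-level split with `round(calibration_fraction * n)`
#' calibration plots.
#'
#' @param plot_ids Vector of plot identifiers, `n >= 5`.
#' @param calibration_fraction Default 0.7.
#' @param seed Integer seed.
#' @return List with `calibration` and `validation` id vectors (disjoint,
#'   exhaustive).
#' @export
holdout_split <- function(plot_ids, calibration_fraction = 0.7, seed = NULL) {
  n <- length(plot_ids)
  if (n < 5) {
    abort("Fewer than 5 plots: use jackknife_evaluate() instead.")
  }
  check_number(calibration_fraction, "calibration_fraction",
               min = 1e-9, max = 1)
  n_cal <- round(calibration_fraction * n)
  idx <- with_seed_or_current(seed, sample.int(n, n_cal))
  list(
    calibration = plot_ids[sort(idx)],
    validation = plot_ids[sort(setdiff(seq_len(n), idx))]
  )
}

#' Jackknife (leave-one-out) evaluation of a power-law model
#'
#' For small samples: each plot is predicted by a model fitted on the other
#' `n - 1` plots.  Reports the out-of-fit evaluation statistics plus the
#' mean and standard deviation of the parameters over the n refits (the
#' parameter uncertainty usually quoted for small-sample fits).
#'
#' @inheritParams fit_power_model
#' @return List of class `jackknife_fit`: `evaluation` (one-row tibble as
#'   in [evaluate_power_model()], protocol `"jackknife"`), `parameters`
#'   (per-fold tibble), `parameter_summary` (term, mean, sd), and
#'   `predictions`.
#' @export
jackknife_evaluate <- function(data, response = "agb", x1 = "MeanH",
                               x2 = NULL, data_model = NA_character_,
                               calibration_density = NA_real_) {
  keep <- complete.cases(data[, c(response, x1, x2)])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  if (n < 4) abort("Need at least 4 complete plots for the jackknife.")
  folds <- purrr::map(seq_len(n), function(i) {
    fit <- tryCatch(
      fit_power_model(data[-i, , drop = FALSE], response, x1, x2,
                      data_model = data_model,
                      calibration_density = calibration_density),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(NULL)
    }
    list(
      pred = predict(fit, data[i, , drop = FALSE]),
      coefs = fit$coefficients
    )
  })
  failed <- purrr::map_lgl(folds, is.null)
  if (any(failed)) {
    warn(sprintf("%d jackknife fold(s) failed to fit; statistics use %d folds.",
                 sum(failed), sum(!failed)))
  }
  ok <- which(!failed)
  preds <- purrr::map_dbl(folds[ok], "pred")
  y <- data[[response]][ok]
  ev <- evaluate_predictions(y, preds)
  params <- purrr::map(folds[ok], "coefs")
  param_tbl <- dplyr::bind_rows(purrr::map(params, ~ as.list(.x))) |>
    dplyr::mutate(fold = ok, .before = 1)
  param_summary <- param_tbl |>
    tidyr::pivot_longer(-"fold", names_to = "term") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value))
  structure(
    list(
      evaluation = tibble(
        r_squared = ev$r_squared, rmse = ev$rmse, rel_rmse = ev$rel_rmse,
        n = ev$n, protocol = "jackknife",
        data_model = data_model, point_density = calibration_density
      ),
      parameters = param_tbl,
      parameter_summary = param_summary,
      predictions = tibble(
        plot_id = if ("plot_id" %in% names(data)) data$plot_id[ok] else ok,
        observed = y, predicted = preds
      )
    ),
    class = "jackknife_fit"
  )
}

#' @export
print.jackknife_fit <- function(x, ...) {
  ev <- x$evaluation
  cat(sprintf(
    "<jackknife_fit> n = %d folds: R^2 = %.3f, RMSE = %.2f (%.2f%%)\n",
    ev$n, ev$r_squared, ev$rmse, ev$rel_rmse
  ))
  invisible(x)
}

#' Apply a calibrated model to thinned-density metrics
#'
#' Quantifies the cross-density transfer error: a model calibrated on
#' reference-density metrics is fed the same plots' metrics derived at a
#' lower density.  The headline `error_pct` is the RMS difference between
#' the thinned-input and reference-input predictions, as a percentage of
#' the mean reference-input prediction; the standard evaluation against
#' observed AGB is also reported.
#'
#' @param fit A [fit_power_model()] calibrated at the reference density.
#' @param reference_metrics,thinned_metrics Metric tables (with `plot_id`
#'   and the fit's predictors) for the same plots at the reference and the
#'   thinned density.
#' @param field_agb Tibble `plot_id`, `agb` of observed AGB.
#' @return One-row tibble: `point_density` (of the thinned metrics, if
#'   tagged), `error_pct`, `r_squared`, `rmse`, `rel_rmse`, `n`.
#' @export
cross_density_apply <- function(fit, reference_metrics, thinned_metrics,
                                field_agb) {
  ids <- reference_metrics$plot_id
  if (!setequal(ids, thinned_metrics$plot_id)) {
    abort("Reference and thinned metric tables cover different plots.")
  }
  thinned <- thinned_metrics[match(ids, thinned_metrics$plot_id), ,
                             drop = FALSE]
  keep <- complete.cases(reference_metrics[, c(fit$x1, fit$x2)]) &
    complete.cases(thinned[, c(fit$x1, fit$x2)])
  ref_pred <- predict(fit, reference_metrics[keep, , drop = FALSE])
  thin_pred <- predict(fit, thinned[keep, , drop = FALSE])
  error_pct <- 100 * sqrt(mean((thin_pred - ref_pred)^2)) / mean(ref_pred)
  obs <- field_agb$agb[match(ids[keep], field_agb$plot_id)]
  ev <- evaluate_predictions(obs, thin_pred)
  tibble(
    point_density = thinned$point_density[1] %||% NA_real_,
    error_pct = error_pct,
    r_squared = ev$r_squared, rmse = ev$rmse, rel_rmse = ev$rel_rmse,
    n = ev$n
  )
}
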