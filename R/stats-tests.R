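#' Per-plot paired differences between two metric tables
#'
#' Pairs the two tables by `plot_id` (row order is irrelevant) and returns
#' the per-plot difference `a - b` for one metric.  Rows where either side
#' is undefined (`NA`) are dropped pairwise; the number dropped is recorded
#' in the `n_dropped` attribute.
#'
#' @param a,b Metric tables (tibbles with `plot_id` and the metric column),
#'   e.g. from [compute_echo_metrics()] rows bound together.
#' @param metric Metric column name (string).
#' @return Tibble `plot_id`, `difference`, with attribute `n_dropped`.
#' @export
paired_differences <- function(a, b, metric) {
  for (tbl in list(a, b)) {
    if (!all(c("plot_id", metric) %in% names(tbl))) {
      abort(sprintf("Both tables need `plot_id` and `%s` columns.", metric))
    }
  }
  unmatched <- c(setdiff(a$plot_id, b$plot_id), setdiff(b$plot_id, a$plot_id))
  if (length(unmatched)) {
    abort(paste0("Unmatched plot ids: ",
                 paste(unique(unmatched), collapse = ", ")))
  }
  if (anyDuplicated(a$plot_id) || anyDuplicated(b$plot_id)) {
    abort("Duplicate plot ids in a metric table.")
  }
  merged <- dplyr::inner_join(
    dplyr::select(a, "plot_id", a_val = dplyr::all_of(metric)),
    dplyr::select(b, "plot_id", b_val = dplyr::all_of(metric)),
    by = "plot_id"
  )
  ok <- complete.cases(merged)
  out <- tibble(
    plot_id = merged$plot_id[ok],
    difference = merged$a_val[ok] - merged$b_val[ok]
  )
  attr(out, "n_dropped") <- sum(!ok)
  out
}

as_difference_vector <- function(d) {
  if (is.data.frame(d)) {
    if (!"difference" %in% names(d)) {
      abort("Difference table must have a `difference` column.")
    }
    d <- d$difference
  }
  d[!is.na(d)]
}

# Exact null distribution of 2*W+ for signed ranks with (doubled, integer)
# scores s: probability vector over 0..sum(s), by polynomial convolution of
# (1 + x^s_i)/2 terms.
signed_rank_null <- function(s) {
  g <- 1
  for (si in s) {
    g2 <- numeric(length(g) + si)
    g2[seq_along(g)] <- g
    idx <- seq_along(g) + si
    g2[idx] <- g2[idx] + g
    g <- g2
  }
  g / sum(g)
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Tests whether the median of paired differences is zero.  Zeros are
#' dropped before ranking; tied absolute differences receive mid-ranks.
#' For `n <= exact_max_n` non-zero differences the exact null distribution
#' of the statistic is computed by convolution (valid under mid-rank ties);
#' above that, a normal approximation with tie correction and continuity
#' correction is used.  All differences zero is a degenerate case reported
#' as `p = 1`.
#'
#' @param d Numeric vector of differences, or a [paired_differences()]
#'   tibble.
#' @param exact_max_n Largest n for the exact path; default 25.
#' @return One-row tibble: `statistic` (W+, the positive-rank sum),
#'   `p_value`, `n` (non-zero differences used), `method`
#'   (`"exact"`/`"normal"`), `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))  # exact p = 0.0625
#' @export
wilcoxon_signed_rank <- function(d, exact_max_n = 25) {
  d <- as_difference_vector(d)
  if (length(d) < 1) abort("Need at least one difference.")
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) {
    return(tibble(statistic = 0, p_value = 1, n = 0L,
                  method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(nz))
  w <- sum(r[nz > 0])
  if (n <= exact_max_n) {
    s <- as.integer(round(2 * r))
    probs <- signed_rank_null(s)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_counts <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_counts^3 - tie_counts) / 48
    cc <- if (w != mu) 0.5 * sign(w - mu) else 0
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  tibble(statistic = w, p_value = p, n = n, method = method,
         degenerate = FALSE)
}

#' Two-sided one-sample t test of paired differences
#'
#' Tests whether the mean difference is zero (`n - 1` degrees of freedom).
#' Zero-variance samples are a degenerate case: `p = 1` if the common value
#' is 0, else `p = 0`.
#'
#' @inheritParams wilcoxon_signed_rank
#' @return One-row tibble: `statistic` (t), `p_value`, `n`, `degenerate`.
#' @export
one_sample_t <- function(d) {
  d <- as_difference_vector(d)
  if (length(d) < 2) abort("Need at least two differences for a t test.")
  if (sd(d) == 0) {
    return(tibble(statistic = NA_real_,
                  p_value = if (mean(d) == 0) 1 else 0,
                  n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         n = length(d), degenerate = FALSE)
}

#' Normality screen (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample KS test against a normal distribution with mean and sd
#' estimated from the sample, using the Lilliefors correction (a plain KS
#' test with estimated parameters would be anti-conservative).  Used for
#' reporting which metric-difference distributions look non-normal; it does
#' not gate which paired test runs.
#'
#' @param values Numeric vector, `n >= 5`.
#' @return One-row tibble: `statistic` (D), `p_value`, `n`, `degenerate`
#'   (constant sample, reported as `p = 0`).
#' @export
ks_normality_screen <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5) abort("Need at least 5 values.")
  if (sd(values) == 0) {
    return(tibble(statistic = NA_real_, p_value = 0,
                  n = length(values), degenerate = TRUE))
  }
  kt <- nortest::lillie.test(values)
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n = length(values), degenerate = FALSE)
}
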