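#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a one-tailed t-test
#' @param x an [ttest_one_tailed()] result.
#' @param ... unused.
#' @return A one-row tibble with `estimate_a`, `estimate_b`, `statistic`,
#'   `df`, `p.value`, `significant`.
#' @export
tidy.erk_ttest <- function(x, ...) {
  tibble::tibble(
    estimate_a = x$mean_a, estimate_b = x$mean_b,
    statistic = x$t_stat, df = x$df, p.value = x$p_one_tailed,
    significant = x$significant
  )
}

#' @rdname tidy.erk_ttest
#' @export
glance.erk_ttest <- function(x, ...) {
  tibble::tibble(statistic = x$t_stat, df = x$df, p.value = x$p_one_tailed,
                 alpha = x$alpha, n_a = x$n_a, n_b = x$n_b)
}

#' Tidy the interval-size fit
#' @param x an [interval_size_correlation()] result.
#' @param ... unused.
#' @return `tidy()`: per-term coefficient table of the OLS fit;
#'   `glance()`: one-row model summary with slope, intercept, Pearson r
#'   and n.
#' @export
tidy.interval_size_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.interval_size_fit
#' @export
glance.interval_size_fit <- function(x, ...) {
  tibble::tibble(
    slope_um_per_min = x$slope, intercept_um = x$intercept,
    pearson_r = x$pearson_r, r.squared = summary(x$lm)$r.squared,
    n = x$n
  )
}

#' Summaries of a selected border trajectory
#' @param x a [select_border()] result.
#' @param ... unused.
#' @return A one-row tibble: selected level, its velocity variance, and
#'   the number of candidate levels considered.
#' @export
glance.border_trajectory <- function(x, ...) {
  tibble::tibble(
    level = attr(x, "level"),
    velocity_variance = attr(x, "velocity_variance"),
    n_candidates = nrow(attr(x, "candidates")),
    n_frames = nrow(x)
  )
}

#' Per-lag interval summary as tidy output
#' @param x an [all_pairs_intervals()] result.
#' @param ... unused.
#' @return The [interval_lag_summary()] tibble.
#' @export
tidy.interval_distribution <- function(x, ...) interval_lag_summary(x)
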