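#' Compute a FRET/CFP ratio movie from two channels
#'
#' Divides the acceptor (YPet) stack by the donor (CFP) stack pixel-wise.
#' Pixels whose CFP intensity falls below `min_cfp` carry no usable ratio
#' and are masked out rather than producing unstable or infinite values.
#'
#' @param ypet,cfp [channel_movie()] objects with identical shape and
#'   calibration.
#' @param min_cfp minimum donor intensity for a valid ratio.
#' @return A [ratio_movie()].
#' @export
compute_ratio <- function(ypet, cfp, min_cfp = 1e-6) {
  stopifnot(inherits(ypet, "channel_movie"), inherits(cfp, "channel_movie"))
  if (!identical(dim(ypet$data), dim(cfp$data))) {
    stop("YPet and CFP stacks have different shapes")
  }
  if (ypet$frame_dt != cfp$frame_dt ||
      ypet$pixel_size_um != cfp$pixel_size_um) {
    stop("YPet and CFP stacks have different calibration")
  }
  stopifnot(min_cfp > 0)
  mask <- is.finite(cfp$data) & is.finite(ypet$data) & cfp$data >= min_cfp
  data <- array(NA_real_, dim(ypet$data))
  data[mask] <- ypet$data[mask] / cfp$data[mask]
  bad <- mask & !is.finite(data)
  if (any(bad)) {
    mask[bad] <- FALSE
    data[bad] <- NA_real_
  }
  if (!any(mask)) warning("all pixels are masked in the ratio movie")
  ratio_movie(data, ypet$frame_dt, ypet$pixel_size_um, mask = mask)
}

#' Median-filter every frame of a ratio movie
#'
#' Each frame is filtered independently with a square `window_px` x
#' `window_px` median taken over *valid* pixels only (reflect padding at
#' the frame edges). The validity mask is propagated unchanged, matching
#' the pre-processing applied to ratio images before kymograph
#' extraction.
#'
#' @param movie a [ratio_movie()].
#' @param window_px odd window side length in pixels (default 15).
#' @return The filtered [ratio_movie()].
#' @export
median_filter_frames <- function(movie, window_px = 15L) {
  stopifnot(inherits(movie, "ratio_movie"))
  window_px <- as.integer(window_px)
  if (window_px < 1L || window_px %% 2L == 0L) {
    stop("window_px must be an odd integer >= 1")
  }
  out <- movie$data
  for (k in seq_len(n_frames(movie))) {
    out[, , k] <- masked_median_filter(movie$data[, , k], movie$mask[, , k],
                                       window_px)
  }
  ratio_movie(out, movie$frame_dt, movie$pixel_size_um, mask = movie$mask)
}

#' Mean ratio inside a circular region of interest, over time
#'
#' Averages the valid pixels whose centres satisfy
#' `(row - center[1])^2 + (col - center[2])^2 <= radius^2`, frame by
#' frame — the circular-ROI readout used to follow Erk activity under
#' pathway inhibition.
#'
#' @param movie a [ratio_movie()].
#' @param center `(row, col)` pixel coordinates of the ROI centre.
#' @param radius ROI radius in pixels (0.5 selects the single centre
#'   pixel).
#' @return A `roi_series` tibble with columns `frame`, `t_min`, `mean`
#'   and `n_valid`.
#' @export
roi_mean_series <- function(movie, center, radius) {
  stopifnot(inherits(movie, "ratio_movie"), length(center) == 2L,
            radius >= 0)
  d <- dim(movie$data)
  rows <- seq_len(d[1]); cols <- seq_len(d[2])
  in_disc <- outer((rows - center[1])^2, (cols - center[2])^2, `+`) <= radius^2
  if (!any(in_disc)) stop("ROI does not intersect the field")
  n_px <- sum(in_disc)
  means <- numeric(d[3]); n_valid <- integer(d[3])
  for (k in seq_len(d[3])) {
    v <- movie$data[, , k][in_disc]
    m <- movie$mask[, , k][in_disc]
    n_valid[k] <- sum(m)
    means[k] <- if (n_valid[k] > 0) mean(v[m]) else NA_real_
  }
  if (all(n_valid == 0L)) stop("ROI is fully masked in every frame")
  out <- tibble::tibble(
    frame = seq_len(d[3]),
    t_min = (seq_len(d[3]) - 1) * movie$frame_dt,
    mean = means,
    n_valid = n_valid
  )
  structure(out, center = center, radius = radius, n_px = n_px,
            class = c("roi_series", class(out)))
}

#' One-tailed pooled-variance two-sample t-test
#'
#' Student's (equal-variance) two-sample t-test of the alternative
#' `mean(sample_a) > mean(sample_b)`, with `df = n_a + n_b - 2`.
#' Significance is called at `alpha` (default the P < 0.01 rule).
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param alpha significance level for the `significant` flag.
#' @return An `erk_ttest` object with `t_stat`, `df`, `p_one_tailed`,
#'   `significant` and the two sample means; see [tidy()] / [glance()].
#' @export
ttest_one_tailed <- function(sample_a, sample_b, alpha = 0.01) {
  stopifnot(is.numeric(sample_a), is.numeric(sample_b))
  n_a <- length(sample_a); n_b <- length(sample_b)
  if (n_a < 2L || n_b < 2L) stop("each sample needs at least 2 values")
  df <- n_a + n_b - 2L
  pooled_var <- ((n_a - 1) * stats::var(sample_a) +
                 (n_b - 1) * stats::var(sample_b)) / df
  if (pooled_var == 0) {
    # degenerate: constant samples; by convention equal means are wholly
    # uninformative (p = 0.5), unequal means are infinitely separated
    delta <- mean(sample_a) - mean(sample_b)
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 0.5 else if (delta > 0) 0 else 1
  } else {
    ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE,
                        alternative = "greater")
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(
    list(t_stat = t_stat, df = df, p_one_tailed = p,
         significant = p < alpha, alpha = alpha,
         mean_a = mean(sample_a), mean_b = mean(sample_b),
         n_a = n_a, n_b = n_b),
    class = "erk_ttest"
  )
}

#' @export
print.erk_ttest <- function(x, ...) {
  cat(sprintf(
    "One-tailed Student's t-test (mean_a > mean_b)\n t = %.4g, df = %d, p = %.4g (%ssignificant at P < %g)\n",
    x$t_stat, x$df, x$p_one_tailed, if (x$significant) "" else "not ",
    x$alpha))
  invisible(x)
}

#' Intensity-modulated display rendering of a ratio frame
#'
#' Maps ratio values over `range = c(lo, hi)` to a blue-to-red heat map
#' (3-color: continuous blue/white/red with white at mid-range, so the
#' activity border appears white; 8-color: eight discrete hues) and
#' modulates brightness by an intensity proxy. Masked pixels are black.
#'
#' @param movie a [ratio_movie()].
#' @param frame frame index to render.
#' @param mode `"3color"` or `"8color"`.
#' @param range `c(lo, hi)` ratio range mapped onto the hue scale.
#' @param intensity optional brightness matrix (e.g. mean of the two raw
#'   channels), same shape as the frame; defaults to the ratio frame
#'   normalised to `[0, 1]`.
#' @return An `nrow x ncol x 3` RGB array with values in `[0, 1]`.
#' @export
imd_render <- function(movie, frame = 1L, mode = c("3color", "8color"),
                       range = NULL, intensity = NULL) {
  stopifnot(inherits(movie, "ratio_movie"))
  mode <- match.arg(mode)
  fr <- movie$data[, , frame]
  msk <- movie$mask[, , frame]
  if (is.null(range)) {
    range <- stats::quantile(fr[msk], c(0.02, 0.98), names = FALSE)
  }
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) stop("range must satisfy hi > lo")
  u <- pmin(pmax((fr - lo) / (hi - lo), 0), 1)
  u[!msk] <- 0
  if (mode == "3color") {
    # odd palette length puts exact white at u = 0.5, the border colour
    pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(255)
    idx <- as.integer(round(u * 254)) + 1L
  } else {
    pal <- grDevices::colorRampPalette(
      c("blue", "cyan", "green", "yellowgreen", "yellow", "orange",
        "orangered", "red"))(8)
    idx <- pmin(7L, as.integer(u * 8)) + 1L
  }
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  if (is.null(intensity)) {
    rng <- range(fr[msk])
    intensity <- if (diff(rng) > 0) (fr - rng[1]) / diff(rng) else
      matrix(1, nrow(fr), ncol(fr))
  }
  stopifnot(identical(dim(intensity), dim(fr)))
  bright <- pmin(pmax(intensity, 0), 1)
  bright[!msk] <- 0
  out <- array(0, c(nrow(fr), ncol(fr), 3))
  for (ch in 1:3) {
    out[, , ch] <- matrix(rgb[ch, ], nrow(fr), ncol(fr)) * bright
  }
  out
}
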