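#' Peak detection with prominences
#'
#' Strict local maxima of a numeric vector, each with its topographic
#' prominence (peak height above the higher of the two bounding valleys,
#' where each side extends to the nearest higher point or the signal
#' end). Plateau maxima report their first index.
#' @noRd
find_peaks_prominence <- function(x) {
  n <- length(x)
  if (n < 3L) return(tibble::tibble(index = integer(), height = numeric(),
                                    prominence = numeric()))
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  # keep only strict maxima (exclude flat ramps)
  idx <- idx[x[idx] > x[pmax(idx - 1L, 1L)] | x[idx] > x[pmin(idx + 1L, n)]]
  if (length(idx) == 0L) {
    return(tibble::tibble(index = integer(), height = numeric(),
                          prominence = numeric()))
  }
  prom <- vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(left[(max(higher_l) + 1L):(i - 1L)]) else
      min(left)
    right <- x[(i + 1L):n]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)]) else
      min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  tibble::tibble(index = idx, height = x[idx], prominence = prom)
}

#' Detect change-points of the border trajectory
#'
#' The border velocity (forward first difference of the position, in
#' kymograph image space) is taken to its smoothed second derivative
#' with a Savitzky-Golay filter, and the peaks of the *negative* second
#' derivative are the change-points: the velocity of a stepping border
#' is a train of sharp spikes, and the negative curvature of the
#' velocity is maximal exactly at each spike. A detected spike between
#' frames `k` and `k + 1` is reported at frame `k + 1`, the first frame
#' on the new plateau. Peaks with prominence below `prominence_frac` of
#' the largest prominence are discarded, and peaks closer than 2 frames
#' are merged to the earlier one.
#'
#' @param traj a [select_border()] trajectory (or any tibble with
#'   `frame`, `t_min`, `position_um`).
#' @param window_frames odd Savitzky-Golay window length in frames.
#' @param polyorder Savitzky-Golay polynomial order, `< window_frames`.
#' @param prominence_frac relative prominence threshold in `(0, 1]`.
#' @param sign `"negative"` (default: peaks of the negative second
#'   derivative of velocity, i.e. velocity maxima — the posterior jumps)
#'   or `"positive"` (velocity minima — the plateau centres).
#' @return A `change_points` tibble (`time_min`, `frame`, `score`) with
#'   the detection parameters attached as attributes.
#' @export
detect_change_points <- function(traj, window_frames = 5L, polyorder = 2L,
                                 prominence_frac = 0.25,
                                 sign = c("negative", "positive")) {
  sign <- match.arg(sign)
  stopifnot(window_frames %% 2L == 1L, polyorder < window_frames,
            prominence_frac > 0, prominence_frac <= 1)
  pos <- traj$position_um
  t_min <- traj$t_min
  n <- length(pos)
  if (n < window_frames + 1L) stop("trajectory shorter than the filter window")
  if (anyNA(pos)) {
    pos <- zoo::na.approx(pos, na.rm = FALSE)
    pos <- zoo::na.locf(zoo::na.locf(pos, na.rm = FALSE), fromLast = TRUE)
    if (anyNA(pos)) stop("trajectory has no finite positions")
  }
  frame_dt <- attr(traj, "frame_dt") %||% diff(t_min[1:2])
  # 3-point running median: step-preserving denoising (exact on ideal
  # staircases) that keeps single-frame position outliers out of the
  # curvature signal
  # endrule "keep": a jump into the final frame must survive the filter
  pos_f <- stats::runmed(pos, 3, endrule = "keep")
  vel <- diff(pos_f)  # kymograph image space: px-per-frame up to calibration
  nv <- length(vel)
  h <- (window_frames - 1L) %/% 2L
  # replicate-pad so a step at either end of the record still produces a
  # well-formed curvature extremum at its velocity spike
  vel_pad <- c(rep(vel[1], h), vel, rep(vel[nv], h))
  d2v <- signal::sgolayfilt(vel_pad, p = polyorder, n = window_frames,
                            m = 2)[(h + 1L):(h + nv)]
  curve <- if (sign == "negative") -d2v else d2v
  # sentinel ends at the global minimum admit boundary peaks
  cpad <- c(min(curve), curve, min(curve))
  peaks <- find_peaks_prominence(cpad)
  peaks$index <- peaks$index - 1L
  peaks <- peaks[peaks$index >= 1L & peaks$index <= nv, ]
  # a genuine jump has strictly negative velocity curvature (positive
  # `curve`); plateau mid-points sit near zero between deep lobes and can
  # carry large topographic prominence, so both height and prominence are
  # thresholded. Two absolute floors apply: a numerical floor for flat
  # trajectories (where rounding ripple would otherwise count as the
  # largest peak), and a noise floor at 3 sigma of the curvature noise,
  # with sigma propagated from a robust (MAD) estimate of the velocity
  # noise through the Savitzky-Golay derivative gain.
  floor_abs <- 1e-8 * max(diff(range(pos)), .Machine$double.eps)
  mid_row <- (window_frames + 1L) %/% 2L
  sg_gain <- sqrt(sum(signal::sgolay(polyorder, window_frames,
                                     m = 2)[mid_row, ]^2))
  floor_noise <- 3 * sg_gain * stats::mad(vel)
  floor_all <- max(floor_abs, floor_noise)
  peaks <- peaks[peaks$height > floor_all & peaks$prominence > floor_abs, ]
  if (nrow(peaks) > 0) {
    thr_p <- prominence_frac * max(peaks$prominence)
    thr_h <- prominence_frac * max(peaks$height)
    peaks <- peaks[peaks$prominence >= thr_p & peaks$height >= thr_h, ]
  }
  peaks <- peaks[order(peaks$index), ]
  # merge peaks closer than 2 frames, keeping the earlier
  keep <- logical(nrow(peaks))
  last_kept <- -Inf
  for (i in seq_len(nrow(peaks))) {
    if (peaks$index[i] - last_kept >= 2L) {
      keep[i] <- TRUE
      last_kept <- peaks$index[i]
    }
  }
  peaks <- peaks[keep, ]
  # velocity sample k sits between position frames k and k+1; the new
  # plateau starts at frame k+1
  cp_frame <- pmin(peaks$index + 1L, n)
  out <- tibble::tibble(
    time_min = t_min[cp_frame],
    frame = cp_frame,
    score = peaks$prominence
  )
  structure(out,
            params = list(window_frames = window_frames,
                          polyorder = polyorder,
                          prominence_frac = prominence_frac, sign = sign,
                          frame_dt = frame_dt),
            class = c("change_points", class(out)))
}

#' Sequential step intervals
#'
#' Differences between consecutive change-point times — the step period
#' of the border regression.
#'
#' @param cps a [detect_change_points()] result (or its `time_min`).
#' @return Numeric vector of intervals in minutes (empty for fewer than
#'   two change-points).
#' @export
sequential_intervals <- function(cps) {
  times <- if (is.data.frame(cps)) cps$time_min else as.numeric(cps)
  if (length(times) < 2L) return(numeric(0))
  diff(times)
}

#' All-pairs interval distribution
#'
#' Intervals between every ordered pair of change-points, annotated with
#' the lag (number of steps separating the pair) — lag 1 is the
#' sequential interval, lag k spans k consecutive steps.
#'
#' @inheritParams sequential_intervals
#' @return An `interval_distribution` tibble with columns `t_i`, `t_j`,
#'   `interval_min`, `lag` (n(n-1)/2 rows for n change-points).
#' @export
all_pairs_intervals <- function(cps) {
  times <- if (is.data.frame(cps)) cps$time_min else as.numeric(cps)
  n <- length(times)
  if (n < 2L) stop("need at least 2 change-points")
  pairs <- utils::combn(n, 2L)
  out <- tibble::tibble(
    t_i = times[pairs[1, ]],
    t_j = times[pairs[2, ]],
    interval_min = times[pairs[2, ]] - times[pairs[1, ]],
    lag = pairs[2, ] - pairs[1, ]
  )
  structure(out, class = c("interval_distribution", class(out)))
}

#' Per-lag summary of an interval distribution
#' @param dist an [all_pairs_intervals()] result.
#' @return A tibble with `lag`, `n`, `mean_min`, `sd_min`, `cv`.
#' @export
interval_lag_summary <- function(dist) {
  dist |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_min = mean(.data$interval_min),
      sd_min = stats::sd(.data$interval_min),
      cv = .data$sd_min / .data$mean_min,
      .groups = "drop"
    )
}

#' Interval summary statistics
#'
#' Mean, sample SD (n - 1 denominator) and coefficient of variation
#' CV = SD / mean of a set of intervals.
#'
#' @param intervals numeric vector of intervals, minutes; must be
#'   non-empty.
#' @return A one-row tibble: `mean_min`, `sd_min`, `cv`, `n`.
#' @export
interval_stats <- function(intervals) {
  stopifnot(is.numeric(intervals))
  if (length(intervals) == 0L) stop("no intervals supplied")
  m <- mean(intervals)
  s <- if (length(intervals) >= 2L) stats::sd(intervals) else NA_real_
  tibble::tibble(
    mean_min = m,
    sd_min = s,
    cv = if (is.na(s) || m <= 0) NA_real_ else s / m,
    n = length(intervals)
  )
}

#' Periodicity estimate from an interval distribution
#'
#' Base period = median of the lag-1 (sequential) intervals; regularity
#' = 1 - CV of the lag-1 intervals; lag consistency = mean over lags k
#' of `|median(lag-k intervals) - k * base| / base` (0 for a perfectly
#' periodic pattern).
#'
#' @param dist an [all_pairs_intervals()] result with at least 3 lag-1
#'   records.
#' @return A one-row tibble: `period_min`, `regularity`,
#'   `lag_consistency`, `n_lag1`.
#' @export
periodicity_estimate <- function(dist) {
  lag1 <- dist$interval_min[dist$lag == 1L]
  if (length(lag1) < 3L) stop("need at least 3 sequential intervals")
  base <- stats::median(lag1)
  reg <- 1 - stats::sd(lag1) / mean(lag1)
  lag_med <- dist |>
    dplyr::group_by(.data$lag) |>
    dplyr::summarise(med = stats::median(.data$interval_min),
                     .groups = "drop")
  consistency <- mean(abs(lag_med$med - lag_med$lag * base) / base)
  tibble::tibble(period_min = base, regularity = reg,
                 lag_consistency = consistency, n_lag1 = length(lag1))
}
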