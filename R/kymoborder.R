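#' Line of interest along the anterior-posterior axis
#'
#' A straight, axis-aligned line given by two pixel endpoints, with a
#' perpendicular averaging band of `2 * band_halfwidth_px` pixels (the
#' 16-pixel band of the kymograph construction, by default). The first
#' endpoint is the anterior end: kymograph position 0.
#'
#' @param from,to `(row, col)` pixel endpoints; must share a row
#'   (horizontal line) or a column (vertical line).
#' @param band_halfwidth_px half-width of the perpendicular band, pixels.
#' @return A `line_of_interest` object.
#' @export
line_of_interest <- function(from, to, band_halfwidth_px = 8L) {
  stopifnot(length(from) == 2L, length(to) == 2L, band_halfwidth_px >= 1L)
  from <- as.integer(from); to <- as.integer(to)
  if (identical(from, to)) stop("endpoints must be distinct")
  horizontal <- from[1] == to[1]
  vertical <- from[2] == to[2]
  if (!horizontal && !vertical) {
    stop("only axis-aligned lines of interest are supported")
  }
  structure(
    list(from = from, to = to,
         band_halfwidth_px = as.integer(band_halfwidth_px),
         axis = if (horizontal) "horizontal" else "vertical"),
    class = "line_of_interest"
  )
}

#' Default line of interest for a movie: the horizontal mid-line
#' @param movie a [ratio_movie()].
#' @param band_halfwidth_px half-width of the perpendicular band, pixels.
#' @return A [line_of_interest()].
#' @export
midline_loi <- function(movie, band_halfwidth_px = 8L) {
  d <- dim(movie$data)
  r <- as.integer(ceiling(d[1] / 2))
  line_of_interest(c(r, 1L), c(r, d[2]), band_halfwidth_px)
}

#' Build a kymograph along a line of interest
#'
#' For every frame and every point along the line, averages the valid
#' pixels of the perpendicular band (2 x `band_halfwidth_px` pixels
#' centred on the point, clipped to the field). Rows of the result are
#' time, columns are position along the line (position 0 at the first
#' endpoint, increasing posteriorly).
#'
#' @param movie a (typically median-filtered) [ratio_movie()].
#' @param loi a [line_of_interest()]; default: horizontal mid-line.
#' @return A `kymograph` object wrapping the `frames x positions` matrix
#'   plus calibration.
#' @export
build_kymograph <- function(movie, loi = midline_loi(movie)) {
  stopifnot(inherits(movie, "ratio_movie"), inherits(loi, "line_of_interest"))
  d <- dim(movie$data)
  hw <- loi$band_halfwidth_px
  if (loi$axis == "horizontal") {
    r <- loi$from[1]
    cols <- seq(min(loi$from[2], loi$to[2]), max(loi$from[2], loi$to[2]))
    band <- max(1L, r - hw + 1L):min(d[1], r + hw)
    get_slab <- function(k) list(v = movie$data[band, cols, k],
                                 m = movie$mask[band, cols, k])
    npos <- length(cols)
  } else {
    cc <- loi$from[2]
    rows <- seq(min(loi$from[1], loi$to[1]), max(loi$from[1], loi$to[1]))
    band <- max(1L, cc - hw + 1L):min(d[2], cc + hw)
    get_slab <- function(k) list(v = t(movie$data[rows, band, k]),
                                 m = t(movie$mask[rows, band, k]))
    npos <- length(rows)
  }
  nt <- d[3]
  kym <- matrix(NA_real_, nt, npos)
  any_gap <- FALSE
  for (k in seq_len(nt)) {
    s <- get_slab(k)
    v <- s$v; m <- s$m
    v[!m] <- 0
    cnt <- colSums(m)
    tot <- colSums(v)
    kym[k, ] <- ifelse(cnt > 0, tot / cnt, NA_real_)
    if (any(cnt == 0)) any_gap <- TRUE
  }
  if (any_gap) warning("fully masked band at some kymograph points; gaps left as NA")
  structure(
    list(data = kym, frame_dt = movie$frame_dt,
         pixel_size_um = movie$pixel_size_um,
         position_um = (seq_len(npos) - 1) * movie$pixel_size_um,
         t_min = (seq_len(nt) - 1) * movie$frame_dt),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d positions (%g min x %g um)\n",
              nrow(x$data), ncol(x$data), max(x$t_min), max(x$position_um)))
  invisible(x)
}

#' Default isoline level set of a kymograph
#'
#' `n` levels evenly spaced between the 2nd and 98th percentile of the
#' kymograph values; the middle third of the levels is the
#' "intermediate Erk activity" candidate set used for border selection.
#'
#' @param kym a [build_kymograph()] result.
#' @param n number of levels (default 9).
#' @return Numeric vector of levels, ascending.
#' @export
kymo_levels <- function(kym, n = 9L) {
  q <- stats::quantile(kym$data, c(0.02, 0.98), na.rm = TRUE, names = FALSE)
  seq(q[1], q[2], length.out = n)
}

# one row of the kymograph -> interpolated crossing positions of `level`
row_crossings <- function(vals, pos, level) {
  ok <- which(is.finite(vals))
  if (length(ok) < 2L) return(numeric(0))
  v <- vals[ok]; x <- pos[ok]
  d <- v - level
  out <- numeric(0)
  exact <- which(d == 0)
  out <- c(out, x[exact])
  s <- d[-length(d)] * d[-1]
  idx <- which(s < 0)
  if (length(idx)) {
    frac <- d[idx] / (d[idx] - d[idx + 1])
    out <- c(out, x[idx] + frac * (x[idx + 1] - x[idx]))
  }
  sort(unique(out))
}

#' Extract isoline trajectories from a kymograph
#'
#' For each level and each time row, the crossing position is found by
#' linear interpolation between adjacent columns. Rows with several
#' crossings are resolved by continuity (the crossing nearest the
#' previous frame's position; first frame: the most posterior crossing,
#' the border being the anterior limit of the posterior high-activity
#' domain). Interior gaps of up to `max_gap_frames` frames are filled by
#' linear interpolation; a level crossed in fewer than half of the rows
#' is flagged unusable.
#'
#' @param kym a [build_kymograph()] result.
#' @param levels isoline levels (default [kymo_levels()]); levels outside
#'   the kymograph's value range are skipped with a warning.
#' @param max_gap_frames longest interior gap filled by interpolation.
#' @return An `isoline_set`: list with `trajectories` (tibble: `level`,
#'   `frame`, `t_min`, `position_um`, `velocity_um_min`) and `summary`
#'   (tibble: `level`, `coverage`, `usable`, `velocity_variance`).
#' @export
extract_isolines <- function(kym, levels = kymo_levels(kym),
                             max_gap_frames = 2L) {
  stopifnot(inherits(kym, "kymograph"))
  rng <- range(kym$data, na.rm = TRUE)
  keep <- levels >= rng[1] & levels <= rng[2]
  if (!all(keep)) {
    warning(sprintf("%d level(s) outside the kymograph value range skipped",
                    sum(!keep)))
  }
  levels <- sort(levels[keep])
  nt <- nrow(kym$data)
  trajs <- vector("list", length(levels))
  summ <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    lev <- levels[li]
    posn <- rep(NA_real_, nt)
    prev <- NA_real_
    for (k in seq_len(nt)) {
      cr <- row_crossings(kym$data[k, ], kym$position_um, lev)
      if (length(cr) == 0) next
      posn[k] <- if (is.na(prev)) max(cr) else cr[which.min(abs(cr - prev))]
      prev <- posn[k]
    }
    coverage <- mean(!is.na(posn))
    filled <- fill_small_gaps(posn, max_gap_frames)
    vel <- c(diff(filled), NA_real_) / kym$frame_dt
    vv <- if (sum(is.finite(vel)) >= 2) stats::var(vel, na.rm = TRUE) else NA_real_
    trajs[[li]] <- tibble::tibble(
      level = lev, frame = seq_len(nt), t_min = kym$t_min,
      position_um = filled, velocity_um_min = vel
    )
    summ[[li]] <- tibble::tibble(
      level = lev, coverage = coverage,
      usable = coverage >= 0.5, velocity_variance = vv
    )
  }
  structure(
    list(trajectories = dplyr::bind_rows(trajs),
         summary = dplyr::bind_rows(summ),
         frame_dt = kym$frame_dt, pixel_size_um = kym$pixel_size_um),
    class = "isoline_set"
  )
}

# linear interpolation across interior NA runs of length <= max_gap
fill_small_gaps <- function(x, max_gap) {
  if (!any(is.na(x)) || all(is.na(x))) return(x)
  filled <- zoo::na.approx(x, na.rm = FALSE, maxgap = max_gap)
  as.numeric(filled)
}

#' Select the Erk activity border among intermediate-level isolines
#'
#' Among the usable candidate trajectories at intermediate activity
#' levels, selects the one with the largest velocity variance — the
#' clearest stepwise trajectory, since a constant-velocity drift has
#' zero velocity variance while a staircase alternates stalls and jumps.
#' Exact ties go to the lowest level.
#'
#' @param iso an [extract_isolines()] result.
#' @param intermediate levels to consider; default the middle third of
#'   the level set (at least 3 when available).
#' @return A `border_trajectory` tibble (`frame`, `t_min`, `position_um`,
#'   `velocity_um_min`) with attributes `level`, `velocity_variance` and
#'   `candidates` (the full selection record).
#' @export
select_border <- function(iso, intermediate = NULL) {
  stopifnot(inherits(iso, "isoline_set"))
  s <- iso$summary
  if (is.null(intermediate)) {
    nl <- nrow(s)
    if (nl >= 3L) {
      k <- max(3L, floor(nl / 3))
      lo <- floor((nl - k) / 2) + 1L
      intermediate <- s$level[lo:(lo + k - 1L)]
    } else {
      intermediate <- s$level
    }
  }
  cand <- s[s$level %in% intermediate & s$usable & is.finite(s$velocity_variance), ]
  if (nrow(cand) == 0L) stop("no usable intermediate isoline candidate")
  best <- cand[order(-cand$velocity_variance, cand$level), ][1, ]
  traj <- iso$trajectories[iso$trajectories$level == best$level,
                           c("frame", "t_min", "position_um", "velocity_um_min")]
  structure(
    traj,
    level = best$level,
    velocity_variance = best$velocity_variance,
    candidates = cand,
    frame_dt = iso$frame_dt,
    pixel_size_um = iso$pixel_size_um,
    class = c("border_trajectory", class(traj))
  )
}
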