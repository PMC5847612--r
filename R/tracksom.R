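#' Detect nuclear spots in one frame
#'
#' Local maxima of the Gaussian-smoothed frame above `min_intensity`,
#' refined to sub-pixel precision by a quadratic fit to the 3x3
#' neighbourhood. Coordinates follow the movie convention: `x_um` along
#' columns (anterior-posterior), `y_um` along rows.
#'
#' @param frame numeric matrix (one frame of a nuclei [channel_movie()]).
#' @param pixel_size_um pixel size, um.
#' @param sigma_um Gaussian smoothing width, um.
#' @param min_intensity detection threshold on the smoothed frame.
#' @return A tibble with `x_um`, `y_um`, `intensity` (possibly empty).
#' @export
detect_spots <- function(frame, pixel_size_um, sigma_um = 2,
                         min_intensity = 1) {
  stopifnot(is.matrix(frame), pixel_size_um > 0, sigma_um > 0)
  sm <- gaussian_smooth(frame, sigma_um / pixel_size_um)
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3L || nc < 3L) return(tibble::tibble(x_um = numeric(),
                                                y_um = numeric(),
                                                intensity = numeric()))
  ctr <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr >= min_intensity
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- sm[2:(nr - 1) + di, 2:(nc - 1) + dj]
    is_max <- is_max & (ctr > nb | (ctr == nb & (di > 0 | (di == 0 & dj > 0))))
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(x_um = numeric(), y_um = numeric(),
                          intensity = numeric()))
  }
  rows <- hits[, 1] + 1L; cols <- hits[, 2] + 1L
  refine <- function(f_m, f_0, f_p) {
    den <- f_m - 2 * f_0 + f_p
    off <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (f_m - f_p) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  dr <- refine(sm[cbind(rows - 1L, cols)], sm[cbind(rows, cols)],
               sm[cbind(rows + 1L, cols)])
  dc <- refine(sm[cbind(rows, cols - 1L)], sm[cbind(rows, cols)],
               sm[cbind(rows, cols + 1L)])
  tibble::tibble(
    x_um = (cols - 1 + dc) * pixel_size_um,
    y_um = (rows - 1 + dr) * pixel_size_um,
    intensity = sm[cbind(rows, cols)]
  )
}

# separable Gaussian convolution with edge replication
gaussian_smooth <- function(frame, sigma_px) {
  h <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-h:h, sd = sigma_px)
  k <- k / sum(k)
  conv_rows <- function(m) {
    # pad columns by edge replication, convolve along each row
    padded <- cbind(m[, rep(1L, h), drop = FALSE], m,
                    m[, rep(ncol(m), h), drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_len(ncol(m))) {
      out[, j] <- padded[, j:(j + 2L * h), drop = FALSE] %*% k
    }
    out
  }
  t(conv_rows(t(conv_rows(frame))))
}

#' Detect spots in every frame of a nuclei movie
#'
#' @param nuclei a nuclei [channel_movie()].
#' @inheritParams detect_spots
#' @return A tibble with `frame`, `t_min`, `x_um`, `y_um`, `intensity`.
#' @export
detect_spots_movie <- function(nuclei, sigma_um = 2, min_intensity = 1) {
  stopifnot(inherits(nuclei, "channel_movie"))
  times <- frame_times(nuclei)
  purrr::map_dfr(seq_len(n_frames(nuclei)), function(k) {
    det <- detect_spots(nuclei$data[, , k], nuclei$pixel_size_um,
                        sigma_um, min_intensity)
    if (nrow(det) == 0L) return(det[0, ])
    dplyr::mutate(det, frame = k, t_min = times[k], .before = 1L)
  })
}

#' Retrograde nearest-neighbour tracking
#'
#' Starting from seed positions at the final frame, links detections
#' backwards in time by greedy nearest-neighbour assignment (the
#' reversed-stack equivalent of manual backward tracking). A link is
#' made only when the displacement is at most `max_disp_um`; otherwise
#' the track terminates at that frame. Within one frame each detection
#' is claimed at most once, in seed order.
#'
#' @param detections a [detect_spots_movie()] tibble (`frame`, `t_min`,
#'   `x_um`, `y_um`).
#' @param seeds tibble/data frame with `x_um`, `y_um`: positions at the
#'   final frame (e.g. cells on a forming somite boundary).
#' @param max_disp_um maximum per-frame displacement, um.
#' @return A `cell_tracks` tibble (`cell_id`, `frame`, `t_min`, `x_um`,
#'   `y_um`), in increasing frame order per cell, with attribute
#'   `direction = "retrograde"`.
#' @export
retrograde_track <- function(detections, seeds, max_disp_um = 10) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)),
            all(c("x_um", "y_um") %in% names(seeds)), max_disp_um > 0)
  frames <- sort(unique(detections$frame))
  last <- max(frames)
  by_frame <- split(detections, detections$frame)
  t_of <- vapply(by_frame, function(d) d$t_min[1], numeric(1))

  det_last <- by_frame[[as.character(last)]]
  cur <- matrix(NA_real_, nrow(seeds), 2)
  for (s in seq_len(nrow(seeds))) {
    d2 <- (det_last$x_um - seeds$x_um[s])^2 + (det_last$y_um - seeds$y_um[s])^2
    j <- which.min(d2)
    if (length(j) == 0L || sqrt(d2[j]) > max_disp_um) {
      stop(sprintf("seed %d matches no detection at the final frame", s))
    }
    cur[s, ] <- c(det_last$x_um[j], det_last$y_um[j])
  }
  active <- rep(TRUE, nrow(seeds))
  recs <- list(tibble::tibble(cell_id = seq_len(nrow(seeds)), frame = last,
                              t_min = t_of[as.character(last)],
                              x_um = cur[, 1], y_um = cur[, 2]))
  for (fr in rev(frames[frames < last])) {
    det <- by_frame[[as.character(fr)]]
    taken <- rep(FALSE, nrow(det))
    for (s in seq_len(nrow(seeds))) {
      if (!active[s]) next
      d2 <- (det$x_um - cur[s, 1])^2 + (det$y_um - cur[s, 2])^2
      d2[taken] <- Inf
      j <- which.min(d2)
      if (length(j) == 0L || !is.finite(d2[j]) || sqrt(d2[j]) > max_disp_um) {
        active[s] <- FALSE
        next
      }
      taken[j] <- TRUE
      cur[s, ] <- c(det$x_um[j], det$y_um[j])
      recs[[length(recs) + 1L]] <- tibble::tibble(
        cell_id = s, frame = fr, t_min = t_of[as.character(fr)],
        x_um = cur[s, 1], y_um = cur[s, 2])
    }
    if (!any(active)) break
  }
  out <- dplyr::arrange(dplyr::bind_rows(recs), .data$cell_id, .data$frame)
  structure(out, direction = "retrograde",
            class = c("cell_tracks", class(out)))
}

#' Overlap of cell tracks with the activity border
#'
#' For each cell, finds maximal runs of consecutive frames in which the
#' cell sits within `tol_um` of the border position, and reports each
#' run as an overlap window of duration `(run length - 1) * frame_dt`
#' minutes. A two-frame coincidence at 5-min frames is the "maintained
#' for at least 5 min" criterion.
#'
#' @param tracks a [retrograde_track()] (or ground-truth) tibble with
#'   `cell_id`, `frame`, `t_min`, `x_um`.
#' @param border a [select_border()] trajectory.
#' @param tol_um spatial tolerance, um (default 5, about one cell
#'   radius).
#' @return An `overlap_result` tibble: one row per cell with
#'   `cell_id`, `n_windows`, `max_overlap_min` and a `windows`
#'   list-column of `(t_start_min, t_end_min, overlap_min)` tibbles.
#' @export
border_overlap <- function(tracks, border, tol_um = 5) {
  stopifnot(all(c("cell_id", "frame", "x_um") %in% names(tracks)),
            inherits(border, "border_trajectory"), tol_um >= 0)
  joined <- dplyr::inner_join(
    tracks, dplyr::select(border, "frame", border_um = "position_um",
                          border_t = "t_min"),
    by = "frame")
  if (nrow(joined) == 0L) stop("tracks and border share no frames")
  frame_dt <- attr(border, "frame_dt") %||%
    (diff(border$t_min[1:2]))
  per_cell <- joined |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_map(function(df, key) {
      hit <- abs(df$x_um - df$border_um) <= tol_um &
        is.finite(df$border_um)
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      wi <- which(r$values)
      windows <- tibble::tibble(
        t_start_min = df$t_min[starts[wi]],
        t_end_min = df$t_min[ends[wi]],
        overlap_min = (r$lengths[wi] - 1L) * frame_dt
      )
      tibble::tibble(
        cell_id = key$cell_id,
        n_windows = nrow(windows),
        max_overlap_min = if (nrow(windows)) max(windows$overlap_min) else 0,
        windows = list(windows)
      )
    }) |>
    dplyr::bind_rows()
  structure(per_cell, tol_um = tol_um,
            class = c("overlap_result", class(per_cell)))
}

#' Somite sizes from border plateaus
#'
#' Each inter-change-point span (and the span after the last
#' change-point) is a border plateau; its position is the median border
#' position over the span's interior frames. Somite `i` is bounded by
#' plateaus `i` and `i + 1`; its size is their difference and its
#' preceding interval is the time between the two change-points that set
#' its boundaries.
#'
#' @param border a [select_border()] trajectory.
#' @param cps a [detect_change_points()] result with >= 2 change-points.
#' @return A `somite_records` tibble: `somite_index`, `size_um`,
#'   `preceding_interval_min`, `anterior_um`, `posterior_um`.
#' @export
somite_sizes_from_border <- function(border, cps) {
  stopifnot(inherits(border, "border_trajectory"))
  times <- cps$time_min
  frames <- cps$frame
  n <- length(times)
  if (n < 2L) stop("need at least 2 change-points")
  last_frame <- max(border$frame)
  bounds <- c(frames, last_frame + 1L)
  plateaus <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (bounds[i + 1L] - bounds[i] < 2L) next
    span <- (bounds[i] + 1L):(bounds[i + 1L] - 1L)
    span <- span[span >= min(border$frame) & span <= last_frame]
    if (length(span) < 1L) next
    plateaus[i] <- stats::median(border$position_um[match(span, border$frame)],
                                 na.rm = TRUE)
  }
  recs <- list()
  for (i in seq_len(n - 1L)) {
    if (is.na(plateaus[i]) || is.na(plateaus[i + 1L])) {
      warning(sprintf("plateau span around somite %d too short; record skipped", i))
      next
    }
    recs[[length(recs) + 1L]] <- tibble::tibble(
      somite_index = i,
      size_um = plateaus[i + 1L] - plateaus[i],
      preceding_interval_min = times[i + 1L] - times[i],
      anterior_um = plateaus[i],
      posterior_um = plateaus[i + 1L]
    )
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(somite_index = integer(), size_um = numeric(),
                          preceding_interval_min = numeric(),
                          anterior_um = numeric(), posterior_um = numeric())
  }
  structure(out, class = c("somite_records", class(out)))
}

#' Interval-somite-size correlation
#'
#' Ordinary least-squares fit of somite size against the preceding step
#' interval, with the Pearson correlation — the clock-and-wavefront
#' prediction is a positive linear relation with slope equal to the
#' wavefront speed.
#'
#' @param records a [somite_sizes_from_border()] tibble (needs columns
#'   `size_um` and `preceding_interval_min`), n >= 2 with at least two
#'   distinct intervals.
#' @return An `interval_size_fit` object (slope um/min, intercept um,
#'   `pearson_r`, `n`, and the underlying `lm`); see [tidy()] /
#'   [glance()].
#' @export
interval_size_correlation <- function(records) {
  stopifnot(all(c("size_um", "preceding_interval_min") %in% names(records)))
  if (nrow(records) < 2L) stop("need at least 2 somite records")
  if (length(unique(records$preceding_interval_min)) < 2L) {
    stop("all intervals identical; slope undefined")
  }
  fit <- stats::lm(size_um ~ preceding_interval_min, data = records)
  r <- if (stats::sd(records$size_um) == 0) 0 else
    stats::cor(records$preceding_interval_min, records$size_um)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         pearson_r = r, n = nrow(records), lm = fit,
         records = tibble::as_tibble(records)),
    class = "interval_size_fit"
  )
}

#' @export
print.interval_size_fit <- function(x, ...) {
  cat(sprintf(
    "Somite size ~ step interval: slope %.3f um/min, intercept %.2f um, r = %.3f (n = %d)\n",
    x$slope, x$intercept, x$pearson_r, x$n))
  invisible(x)
}
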