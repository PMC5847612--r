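#' Simulation configuration for the clock-and-wavefront movie generator
#'
#' The generator emulates the dynamics the kymograph analysis assumes: a
#' sharp sigmoid anterior-posterior Erk activity gradient whose border
#' jumps posteriorly at renewal-process event times onto a posteriorly
#' drifting wavefront, so that each somite's size is (up to noise)
#' proportional to the preceding step interval. Defaults reproduce the
#' control regime: step intervals 29.4 +/- 4.6 min, 5-min frames, a
#' 1.65 um/min wavefront, giving ~48.5 um somites.
#'
#' @param duration_min total imaged time, minutes.
#' @param frame_dt frame interval, minutes.
#' @param field_height_px,field_width_px field size in pixels; columns are
#'   the anterior-posterior axis.
#' @param pixel_size_um pixel size, um/pixel.
#' @param interval_mean,interval_sd step-interval mean and SD, minutes
#'   (pre-truncation moments of the renewal distribution).
#' @param interval_dist `"truncated-normal"` (default) or `"gamma"`; both
#'   are truncated below at `frame_dt` so every drawn gap is positive and
#'   resolvable.
#' @param wavefront_speed posterior drift speed of the wavefront, um/min.
#' @param size_noise_sd additive Gaussian noise on border plateau
#'   positions, um.
#' @param border_sharpness_um sigmoid length scale of the activity border,
#'   um.
#' @param ratio_low,ratio_high FRET/CFP ratio levels anterior/posterior of
#'   the border (dimensionless).
#' @param noise_sd imaging noise SD, in ratio units (and, for rendered
#'   channels, as a fraction of the baseline intensity).
#' @param n_cells number of nuclear spots to simulate.
#' @param cell_spot_sigma_um Gaussian width of a rendered nuclear spot, um.
#' @param cell_jitter_um per-frame Brownian positional jitter of cells, um
#'   (0 = static cells).
#' @param border_start_um border position at time 0, um from the anterior
#'   end of the line.
#' @param cells_on_boundaries if `TRUE`, cells are seeded exactly at the
#'   border plateau positions (somite boundaries) instead of uniformly.
#' @return A validated `sim_config` list.
#' @seealso [regime_preset()], [build_truth()], [render_ratio_movie()]
#' @export
sim_config <- function(duration_min = 240,
                       frame_dt = 5,
                       field_height_px = 64,
                       field_width_px = 512,
                       pixel_size_um = 1.0,
                       interval_mean = 29.4,
                       interval_sd = 4.6,
                       interval_dist = c("truncated-normal", "gamma"),
                       wavefront_speed = 1.65,
                       size_noise_sd = 0,
                       border_sharpness_um = 5,
                       ratio_low = 1.0,
                       ratio_high = 2.0,
                       noise_sd = 0.05,
                       n_cells = 30,
                       cell_spot_sigma_um = 2,
                       cell_jitter_um = 0,
                       border_start_um = 60,
                       cells_on_boundaries = FALSE) {
  interval_dist <- match.arg(interval_dist)
  cfg <- list(
    duration_min = duration_min, frame_dt = frame_dt,
    field_height_px = as.integer(field_height_px),
    field_width_px = as.integer(field_width_px),
    pixel_size_um = pixel_size_um,
    interval_mean = interval_mean, interval_sd = interval_sd,
    interval_dist = interval_dist,
    wavefront_speed = wavefront_speed, size_noise_sd = size_noise_sd,
    border_sharpness_um = border_sharpness_um,
    ratio_low = ratio_low, ratio_high = ratio_high, noise_sd = noise_sd,
    n_cells = as.integer(n_cells), cell_spot_sigma_um = cell_spot_sigma_um,
    cell_jitter_um = cell_jitter_um, border_start_um = border_start_um,
    cells_on_boundaries = isTRUE(cells_on_boundaries)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$frame_dt > 0,
    cfg$duration_min > 0,
    cfg$interval_mean > cfg$frame_dt,
    cfg$interval_sd >= 0,
    cfg$ratio_high > cfg$ratio_low,
    cfg$field_height_px >= 1, cfg$field_width_px >= 1,
    cfg$pixel_size_um > 0,
    cfg$wavefront_speed > 0,
    cfg$border_sharpness_um > 0,
    cfg$size_noise_sd >= 0, cfg$noise_sd >= 0,
    cfg$n_cells >= 0, cfg$cell_spot_sigma_um > 0,
    cfg$cell_jitter_um >= 0, cfg$border_start_um >= 0
  )
  invisible(cfg)
}

#' Regime presets for the printed study conditions
#'
#' `"control"` uses the control interval statistics (29.4 +/- 4.6 min);
#' `"clockless"` the clock-deficient (her1/her7 knockdown) statistics
#' (36.9 +/- 12.5 min) together with 3 um somite-size noise.
#'
#' @param regime `"control"` or `"clockless"`.
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
regime_preset <- function(regime = c("control", "clockless"), ...) {
  regime <- match.arg(regime)
  base <- switch(regime,
    control   = list(interval_mean = 29.4, interval_sd = 4.6,
                     size_noise_sd = 0),
    clockless = list(interval_mean = 36.9, interval_sd = 12.5,
                     size_noise_sd = 3)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_config, base)
}

## Renewal-gap samplers: both truncated below at `a` so gaps are positive.

rtrunc_normal <- function(n, mean, sd, a) {
  if (sd == 0) return(rep(max(mean, a), n))
  p_a <- stats::pnorm((a - mean) / sd)
  if (p_a >= 1 - 1e-12) stop("truncation point leaves no probability mass")
  u <- stats::runif(n, p_a, 1)
  mean + sd * stats::qnorm(u)
}

rtrunc_gamma <- function(n, mean, sd, a) {
  if (sd == 0) return(rep(max(mean, a), n))
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  p_a <- stats::pgamma(a, shape = shape, rate = rate)
  if (p_a >= 1 - 1e-12) stop("truncation point leaves no probability mass")
  u <- stats::runif(n, p_a, 1)
  stats::qgamma(u, shape = shape, rate = rate)
}

draw_gaps <- function(cfg, n) {
  switch(cfg$interval_dist,
    "truncated-normal" = rtrunc_normal(n, cfg$interval_mean, cfg$interval_sd,
                                       cfg$frame_dt),
    "gamma" = rtrunc_gamma(n, cfg$interval_mean, cfg$interval_sd,
                           cfg$frame_dt)
  )
}

#' Draw renewal-process step times
#'
#' Inter-event gaps are i.i.d. draws from the configured interval
#' distribution truncated below at `frame_dt`; event times accumulate
#' from 0 and events are kept while they fall in `(0, duration_min]`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the same seed always yields the same times.
#' @return Strictly increasing event times in minutes (possibly empty,
#'   with a warning, if the duration is shorter than the first gap).
#' @export
draw_step_times <- function(cfg, seed) {
  validate_sim_config(cfg)
  set.seed(seed)
  times <- numeric(0)
  t <- 0
  repeat {
    gaps <- draw_gaps(cfg, 16L)
    for (g in gaps) {
      t <- t + g
      if (t > cfg$duration_min) {
        if (length(times) == 0L) {
          warning("duration too short for a single step event")
        }
        return(times)
      }
      times <- c(times, t)
    }
  }
}

#' Build the ground truth of one simulated embryo
#'
#' Draws step times, places border plateaus on the drifting wavefront
#' `w(t) = border_start_um + wavefront_speed * t` (plus optional plateau
#' noise), derives intervals and somite sizes, and lays down cell tracks.
#' Cells are static in the PSM-anterior reference frame (optionally with
#' Brownian jitter); the regressing border sweeps past them, which is what
#' makes retrograde boundary-cell tracking land on the border.
#'
#' @inheritParams draw_step_times
#' @return A `ground_truth` list with `step_times`, `border_positions`,
#'   `intervals`, `somite_sizes` (all in minutes / um), a `cell_tracks`
#'   tibble (`cell_id`, `frame`, `t_min`, `x_um`, `y_um`) and the `cfg`.
#' @export
build_truth <- function(cfg, seed) {
  validate_sim_config(cfg)
  step_times <- draw_step_times(cfg, seed)
  # draw_step_times consumed the stream from set.seed(seed); continue it
  n_steps <- length(step_times)
  plateau_noise <- if (cfg$size_noise_sd > 0 && n_steps > 0) {
    stats::rnorm(n_steps, 0, cfg$size_noise_sd)
  } else {
    numeric(n_steps)
  }
  border_positions <- cfg$border_start_um +
    cfg$wavefront_speed * step_times + plateau_noise
  if (is.unsorted(border_positions, strictly = TRUE)) {
    # plateau noise may not reorder plateaus; resolve by sorting noise out
    border_positions <- sort(border_positions)
  }
  intervals <- diff(step_times)
  somite_sizes <- diff(border_positions)

  times <- seq(0, cfg$duration_min, by = cfg$frame_dt)
  width_um <- (cfg$field_width_px - 1) * cfg$pixel_size_um
  height_um <- (cfg$field_height_px - 1) * cfg$pixel_size_um
  n <- cfg$n_cells
  cell_tracks <- if (n > 0) {
    if (cfg$cells_on_boundaries && n_steps > 0) {
      x0 <- rep_len(border_positions, n)
      y0 <- stats::runif(n, 0.25 * height_um, 0.75 * height_um)
    } else {
      # keep spots fully inside the field, and keep nuclei apart (cells
      # exclude each other physically) so each renders as a resolvable
      # interior intensity maximum
      mx <- min(2 * cfg$cell_spot_sigma_um, width_um / 4)
      my <- min(2 * cfg$cell_spot_sigma_um, height_um / 4)
      min_sep <- 4 * cfg$cell_spot_sigma_um
      x0 <- numeric(0); y0 <- numeric(0)
      tries <- 0L
      while (length(x0) < n && tries < 5000L) {
        tries <- tries + 1L
        cx <- stats::runif(1, mx, width_um - mx)
        cy <- stats::runif(1, my, height_um - my)
        if (length(x0) == 0L ||
            min((x0 - cx)^2 + (y0 - cy)^2) >= min_sep^2) {
          x0 <- c(x0, cx); y0 <- c(y0, cy)
        }
      }
      if (length(x0) < n) {
        stop("could not place ", n, " cells at the required separation; ",
             "reduce n_cells or cell_spot_sigma_um")
      }
    }
    tracks <- tidyr::expand_grid(cell_id = seq_len(n),
                                 frame = seq_along(times))
    tracks$t_min <- times[tracks$frame]
    if (cfg$cell_jitter_um > 0) {
      jit <- function(n0) {
        steps <- matrix(stats::rnorm((length(times) - 1) * n0,
                                     0, cfg$cell_jitter_um),
                        nrow = n0)
        cbind(0, t(apply(steps, 1, cumsum)))
      }
      dx <- jit(n); dy <- jit(n)
      tracks$x_um <- x0[tracks$cell_id] +
        dx[cbind(tracks$cell_id, tracks$frame)]
      tracks$y_um <- y0[tracks$cell_id] +
        dy[cbind(tracks$cell_id, tracks$frame)]
      tracks$x_um <- pmin(pmax(tracks$x_um, 0), width_um)
      tracks$y_um <- pmin(pmax(tracks$y_um, 0), height_um)
    } else {
      tracks$x_um <- x0[tracks$cell_id]
      tracks$y_um <- y0[tracks$cell_id]
    }
    tracks
  } else {
    tibble::tibble(cell_id = integer(), frame = integer(),
                   t_min = numeric(), x_um = numeric(), y_um = numeric())
  }

  structure(
    list(step_times = step_times, border_positions = border_positions,
         intervals = intervals, somite_sizes = somite_sizes,
         cell_tracks = cell_tracks, cfg = cfg, seed = seed),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d steps over %g min, %d cells (seed %s)\n",
              length(x$step_times), x$cfg$duration_min,
              length(unique(x$cell_tracks$cell_id)), format(x$seed)))
  invisible(x)
}

#' Border position as a function of time
#'
#' Piecewise-constant border trajectory: `border_start_um` before the
#' first step, then the plateau set at the most recent step.
#'
#' @param truth a [build_truth()] result.
#' @param t_min times in minutes.
#' @return Positions in um, one per time.
#' @export
true_border_at <- function(truth, t_min) {
  idx <- findInterval(t_min, truth$step_times)
  out <- c(truth$cfg$border_start_um, truth$border_positions)[idx + 1]
  out
}

#' Render the analytic ratio field of one frame (no noise)
#' @noRd
ratio_field_frame <- function(truth, t, noise = NULL) {
  cfg <- truth$cfg
  x <- (seq_len(cfg$field_width_px) - 1) * cfg$pixel_size_um
  b <- true_border_at(truth, t)
  prof <- cfg$ratio_low + (cfg$ratio_high - cfg$ratio_low) *
    stats::plogis((x - b) / cfg$border_sharpness_um)
  matrix(prof, nrow = cfg$field_height_px, ncol = cfg$field_width_px,
         byrow = TRUE)
}

#' Render a synthetic FRET/CFP ratio movie
#'
#' `ratio(x, t) = ratio_low + (ratio_high - ratio_low) *
#' sigmoid((x - b(t)) / border_sharpness_um) + N(0, noise_sd)`, where
#' `b(t)` is the piecewise-constant ground-truth border and `x` the
#' position along the anterior-posterior (column) axis. The imaging noise
#' stream is seeded from the ground truth's seed, so re-rendering the
#' same truth gives a bit-identical movie.
#'
#' @param truth a [build_truth()] result.
#' @param cfg the same [sim_config()] used to build `truth`.
#' @return A [ratio_movie()].
#' @export
render_ratio_movie <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "ground_truth"))
  validate_sim_config(cfg)
  set.seed(truth$seed + 1L)
  times <- seq(0, cfg$duration_min, by = cfg$frame_dt)
  data <- array(0, c(cfg$field_height_px, cfg$field_width_px, length(times)))
  for (k in seq_along(times)) {
    data[, , k] <- ratio_field_frame(truth, times[k])
  }
  if (cfg$noise_sd > 0) {
    data <- data + stats::rnorm(length(data), 0, cfg$noise_sd)
  }
  ratio_movie(data, cfg$frame_dt, cfg$pixel_size_um)
}

#' Render the raw CFP / YPet / nuclei channels
#'
#' CFP is a uniform positive baseline (plus optional noise), YPet is the
#' analytic ratio field times CFP (so `compute_ratio(YPet, CFP)` recovers
#' the ratio exactly when noise is off), and the nuclei channel is a sum
#' of Gaussian spots centred on the ground-truth cell positions.
#'
#' @inheritParams render_ratio_movie
#' @param baseline CFP baseline intensity (arbitrary units).
#' @param spot_amplitude peak intensity of one nuclear spot.
#' @return A list with elements `cfp`, `ypet`, `nuclei`, each a
#'   [channel_movie()].
#' @export
render_channels <- function(truth, cfg = truth$cfg, baseline = 100,
                            spot_amplitude = 1000) {
  stopifnot(inherits(truth, "ground_truth"))
  validate_sim_config(cfg)
  set.seed(truth$seed + 2L)
  times <- seq(0, cfg$duration_min, by = cfg$frame_dt)
  dims <- c(cfg$field_height_px, cfg$field_width_px, length(times))
  cfp <- array(baseline, dims)
  ypet <- array(0, dims)
  nuc <- array(0, dims)

  x_um <- (seq_len(cfg$field_width_px) - 1) * cfg$pixel_size_um
  y_um <- (seq_len(cfg$field_height_px) - 1) * cfg$pixel_size_um
  sig <- cfg$cell_spot_sigma_um
  tracks <- truth$cell_tracks

  for (k in seq_along(times)) {
    ypet[, , k] <- ratio_field_frame(truth, times[k]) * cfp[, , k]
    if (nrow(tracks) > 0) {
      fr <- tracks[tracks$frame == k, ]
      acc <- matrix(0, dims[1], dims[2])
      for (i in seq_len(nrow(fr))) {
        gx <- exp(-(x_um - fr$x_um[i])^2 / (2 * sig^2))
        gy <- exp(-(y_um - fr$y_um[i])^2 / (2 * sig^2))
        acc <- acc + spot_amplitude * outer(gy, gx)
      }
      nuc[, , k] <- acc
    }
  }
  if (cfg$noise_sd > 0) {
    add <- function(a) {
      a <- a + stats::rnorm(length(a), 0, cfg$noise_sd * baseline)
      a[a < 0] <- 0
      a
    }
    cfp <- add(cfp); ypet <- add(ypet); nuc <- add(nuc)
  }
  list(
    cfp = channel_movie(cfp, cfg$frame_dt, cfg$pixel_size_um, "CFP"),
    ypet = channel_movie(ypet, cfg$frame_dt, cfg$pixel_size_um, "YPet"),
    nuclei = channel_movie(nuc, cfg$frame_dt, cfg$pixel_size_um, "nuclei")
  )
}

#' Write ground truth to JSON + CSV
#'
#' @param truth a [build_truth()] result.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(step_times_min = truth$step_times,
         border_positions_um = truth$border_positions,
         intervals_min = truth$intervals,
         somite_sizes_um = truth$somite_sizes,
         seed = truth$seed),
    file.path(dir, "ground_truth.json"), digits = NA
  )
  readr::write_csv(truth$cell_tracks, file.path(dir, "cell_tracks.csv"))
  invisible(dir)
}
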