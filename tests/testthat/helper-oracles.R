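# Independent brute-force oracles and small fixture builders.
# Every oracle here is written against the definitions, not against the
# package implementation paths it checks.

# small, fast simulation configuration for imaging tests
small_cfg <- function(...) {
  defaults <- list(duration_min = 60, frame_dt = 5, field_height_px = 24,
                   field_width_px = 96, interval_mean = 20, interval_sd = 0,
                   wavefront_speed = 1.0, noise_sd = 0, n_cells = 0,
                   border_sharpness_um = 2, border_start_um = 30)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# brute-force 2D median filter: nested loops, reflect padding (half-sample
# symmetric: index -1 -> 0, n -> n-1), median over valid pixels only
bf_median_filter <- function(x, mask, window) {
  h <- (window - 1) / 2
  nr <- nrow(x); nc <- ncol(x)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n - i + 1
    }
    i
  }
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    vals <- c()
    for (di in -h:h) for (dj in -h:h) {
      ii <- refl(i + di, nr); jj <- refl(j + dj, nc)
      if (mask[ii, jj]) vals <- c(vals, x[ii, jj])
    }
    out[i, j] <- stats::median(vals)
  }
  out
}

# brute-force band-mean kymograph for a horizontal mid-line
bf_kymograph <- function(movie, band_halfwidth) {
  d <- dim(movie$data)
  r <- as.integer(ceiling(d[1] / 2))
  band <- max(1, r - band_halfwidth + 1):min(d[1], r + band_halfwidth)
  out <- matrix(NA_real_, d[3], d[2])
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
    v <- movie$data[band, j, k]
    m <- movie$mask[band, j, k]
    if (any(m)) out[k, j] <- mean(v[m])
  }
  out
}

# brute-force circular-ROI mean by explicit pixel enumeration
bf_roi_means <- function(movie, center, radius) {
  d <- dim(movie$data)
  out <- numeric(d[3])
  for (k in seq_len(d[3])) {
    vals <- c()
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if ((i - center[1])^2 + (j - center[2])^2 <= radius^2 &&
          movie$mask[i, j, k]) {
        vals <- c(vals, movie$data[i, j, k])
      }
    }
    out[k] <- if (length(vals)) mean(vals) else NA_real_
  }
  out
}

# textbook pooled two-sample t (one-tailed, mean_a > mean_b)
bf_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = pt(t, na + nb - 2, lower.tail = FALSE))
}

# all ordered pairs of event times by explicit double loop
bf_all_pairs <- function(times) {
  out <- NULL
  n <- length(times)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out <- rbind(out, data.frame(t_i = times[i], t_j = times[j],
                                 interval_min = times[j] - times[i],
                                 lag = j - i))
  }
  out
}

# analytic mean of a normal truncated below at a
truncnorm_mean <- function(mean, sd, a) {
  alpha <- (a - mean) / sd
  mean + sd * dnorm(alpha) / (1 - pnorm(alpha))
}

# staircase border trajectory built directly from step times (frame grid)
staircase_traj <- function(step_times, duration_min, frame_dt = 5,
                           start_um = 60, speed = 1.65, noise_sd = 0) {
  t_min <- seq(0, duration_min, by = frame_dt)
  idx <- findInterval(t_min, step_times)
  pos <- c(start_um, start_um + speed * step_times)[idx + 1]
  if (noise_sd > 0) pos <- pos + rnorm(length(pos), 0, noise_sd)
  traj <- tibble::tibble(frame = seq_along(t_min), t_min = t_min,
                         position_um = pos,
                         velocity_um_min = c(diff(pos), NA) / frame_dt)
  structure(traj, frame_dt = frame_dt, level = NA_real_,
            velocity_variance = stats::var(diff(pos) / frame_dt),
            candidates = tibble::tibble(),
            class = c("border_trajectory", class(traj)))
}
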