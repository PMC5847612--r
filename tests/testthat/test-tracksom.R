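spot_frame <- function(xy_um, dims = c(32, 48), px = 1, sigma = 2,
                       amp = 100) {
  x <- (seq_len(dims[2]) - 1) * px
  y <- (seq_len(dims[1]) - 1) * px
  acc <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nrow(xy_um))) {
    acc <- acc + amp * outer(exp(-(y - xy_um[i, 2])^2 / (2 * sigma^2)),
                             exp(-(x - xy_um[i, 1])^2 / (2 * sigma^2)))
  }
  acc
}

test_that("spot detection finds Gaussian peaks to sub-pixel accuracy", {
  fr <- spot_frame(cbind(20.3, 11.7))
  det <- detect_spots(fr, 1, sigma_um = 2, min_intensity = 5)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_um - 20.3), 0.5)
  expect_lt(abs(det$y_um - 11.7), 0.5)

  expect_equal(nrow(detect_spots(matrix(0, 20, 20), 1)), 0L)

  two <- spot_frame(rbind(c(10, 10), c(30, 20)))  # >= 4 sigma apart
  det2 <- detect_spots(two, 1, sigma_um = 2, min_intensity = 5)
  expect_equal(nrow(det2), 2L)
})

test_that("retrograde tracking follows static and jittering cells", {
  # well-separated cells on a grid, with and without Brownian jitter
  cfg <- small_cfg(n_cells = 0, field_height_px = 48, duration_min = 50)
  grid <- tidyr::expand_grid(gx = c(15, 40, 65, 85), gy = c(14, 34))
  n_fr <- 11L
  mk_tracks <- function(jitter_sd, seed) {
    set.seed(seed)
    purrr::map_dfr(seq_len(nrow(grid)), function(i) {
      dx <- c(0, cumsum(rnorm(n_fr - 1, 0, jitter_sd)))
      dy <- c(0, cumsum(rnorm(n_fr - 1, 0, jitter_sd)))
      tibble::tibble(cell_id = i, frame = seq_len(n_fr),
                     t_min = (seq_len(n_fr) - 1) * 5,
                     x_um = grid$gx[i] + dx, y_um = grid$gy[i] + dy)
    })
  }
  for (jitter in c(0, 0.7)) {
    tr <- build_truth(cfg, 14)
    tr$cell_tracks <- mk_tracks(jitter, 100 + jitter)
    nuc <- render_channels(tr, cfg)$nuclei
    det <- detect_spots_movie(nuc, sigma_um = 2, min_intensity = 50)
    final <- tr$cell_tracks[tr$cell_tracks$frame == n_fr, ]
    tracks <- retrograde_track(det, final[, c("x_um", "y_um")],
                               max_disp_um = 6)
    merged <- dplyr::inner_join(tracks, tr$cell_tracks,
                                by = c("cell_id", "frame"),
                                suffix = c("", "_true"))
    expect_equal(nrow(merged), nrow(tr$cell_tracks))
    expect_lt(max(abs(merged$x_um - merged$x_um_true)), 1)
    expect_lt(max(abs(merged$y_um - merged$y_um_true)), 1)
  }
})

test_that("link gating terminates tracks and validates seeds", {
  det <- dplyr::bind_rows(
    tibble::tibble(frame = 1, t_min = 0, x_um = 50, y_um = 10),
    tibble::tibble(frame = 2, t_min = 5, x_um = 10, y_um = 10),
    tibble::tibble(frame = 3, t_min = 10, x_um = 10.5, y_um = 10))
  tracks <- retrograde_track(det, tibble::tibble(x_um = 10.5, y_um = 10),
                             max_disp_um = 5)
  # the frame-2 -> frame-1 jump (40 um) exceeds the gate: track stops
  expect_equal(sort(tracks$frame), c(2, 3))

  expect_error(retrograde_track(det, tibble::tibble(x_um = 90, y_um = 90),
                                max_disp_um = 5), "seed")
})

test_that("tracking is consistent under time reversal", {
  set.seed(44)
  n_fr <- 8
  pos <- cbind(10 + cumsum(rnorm(n_fr, 0, 1)), 12 + cumsum(rnorm(n_fr, 0, 1)))
  det <- purrr::map_dfr(seq_len(n_fr), function(k) tibble::tibble(
    frame = k, t_min = (k - 1) * 5, x_um = pos[k, 1], y_um = pos[k, 2]))
  fwd <- retrograde_track(det, tibble::tibble(x_um = pos[n_fr, 1],
                                              y_um = pos[n_fr, 2]),
                          max_disp_um = 8)
  rev_det <- dplyr::mutate(det, frame = n_fr + 1 - frame,
                           t_min = (frame - 1) * 5)
  bwd <- retrograde_track(rev_det, tibble::tibble(x_um = pos[1, 1],
                                                  y_um = pos[1, 2]),
                          max_disp_um = 8)
  expect_equal(fwd$x_um, rev(bwd$x_um))
  expect_equal(fwd$y_um, rev(bwd$y_um))
})

test_that("border overlap windows follow the run-length rule", {
  border <- staircase_traj(c(20, 40), duration_min = 45)
  mk_track <- function(x) tibble::tibble(
    cell_id = 1L, frame = seq_along(x), t_min = (seq_along(x) - 1) * 5,
    x_um = x, y_um = 0)
  b_pos <- border$position_um
  # coincident for exactly 2 consecutive frames -> 5 min
  x <- b_pos + 100
  x[3:4] <- b_pos[3:4]
  ov <- border_overlap(mk_track(x), border, tol_um = 5)
  expect_equal(ov$max_overlap_min, 5)
  # never within tolerance -> 0
  ov0 <- border_overlap(mk_track(b_pos + 100), border, tol_um = 5)
  expect_equal(ov0$max_overlap_min, 0)
  expect_equal(ov0$n_windows, 0L)
  # coincident over all 10 frames -> 45 min
  ov10 <- border_overlap(mk_track(b_pos), border, tol_um = 5)
  expect_equal(ov10$max_overlap_min, 45)
})

test_that("boundary-seeded cells overlap the border for at least one frame interval", {
  cfg <- sim_config(noise_sd = 0.03, n_cells = 6, cells_on_boundaries = TRUE)
  tr <- build_truth(cfg, 23)
  kym <- build_kymograph(median_filter_frames(render_ratio_movie(tr), 15L))
  border <- select_border(extract_isolines(kym))
  ov <- border_overlap(tr$cell_tracks, border, tol_um = 5)
  expect_true(all(ov$max_overlap_min >= 5))
})

test_that("somite sizes derive from border plateaus", {
  traj <- staircase_traj(c(30, 60, 90, 120), duration_min = 150, speed = 1.6)
  cps <- detect_change_points(traj)
  recs <- somite_sizes_from_border(traj, cps)
  expect_equal(nrow(recs), nrow(cps) - 1L)
  expect_true(all(abs(recs$size_um - 48) < 1e-9))
  expect_equal(recs$preceding_interval_min, rep(30, 3))
  # conservation: sizes sum to the plateau span
  expect_equal(sum(recs$size_um),
               recs$posterior_um[nrow(recs)] - recs$anterior_um[1])

  expect_error(somite_sizes_from_border(traj, cps[1, ]), "at least 2")
})

test_that("recovered somite sizes match the generator ground truth", {
  cfg <- sim_config(noise_sd = 0, interval_sd = 0, interval_mean = 30,
                    n_cells = 0)
  tr <- build_truth(cfg, 3)
  kym <- build_kymograph(median_filter_frames(render_ratio_movie(tr), 15L))
  border <- select_border(extract_isolines(kym))
  cps <- detect_change_points(border)
  # the final step lands on the last frame, so its plateau (and the last
  # somite record) is unobservable
  recs <- suppressWarnings(somite_sizes_from_border(border, cps))
  expect_equal(nrow(recs), length(tr$somite_sizes) - 1L)
  expect_lt(max(abs(recs$size_um - tr$somite_sizes[recs$somite_index])), 1)
})

test_that("interval-size fit recovers lines, degenerate cases and the printed pairs", {
  recs <- tibble::tibble(preceding_interval_min = c(10, 20, 30, 40),
                         size_um = 1.5 * c(10, 20, 30, 40) + 2)
  fit <- interval_size_correlation(recs)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit$slope, 1.5, tolerance = 1e-12)

  flat <- tibble::tibble(preceding_interval_min = c(10, 20, 30),
                         size_um = c(48, 48, 48))
  f2 <- interval_size_correlation(flat)
  expect_equal(f2$slope, 0)
  expect_equal(f2$pearson_r, 0)

  expect_error(interval_size_correlation(
    tibble::tibble(preceding_interval_min = c(30, 30), size_um = c(1, 2))),
    "identical")

  # the two clock-deficient worked examples: (20 min, 39 um), (45 min, 58 um)
  pairs <- tibble::tibble(preceding_interval_min = c(20, 45),
                          size_um = c(39, 58))
  f3 <- interval_size_correlation(pairs)
  expect_equal(f3$slope, (58 - 39) / (45 - 20), tolerance = 1e-12)
  expect_equal(predict(f3$lm, pairs), c(39, 58), ignore_attr = TRUE)
  expect_equal(f3$pearson_r, 1)

  gl <- glance(f3)
  expect_equal(gl$pearson_r, 1)
  # perfect colinear fits make summary.lm warn; only the shape matters here
  td <- suppressWarnings(tidy(fit))
  expect_equal(nrow(td), 2L)
})

test_that("size variability separates control from clock-deficient truths", {
  cv_sizes <- function(regime, seed) {
    tr <- build_truth(regime_preset(regime, duration_min = 800, n_cells = 0),
                      seed)
    interval_stats(tr$somite_sizes)$cv
  }
  seeds <- 1:20
  ctrl <- vapply(seeds, function(s) cv_sizes("control", s), numeric(1))
  clk <- vapply(seeds, function(s) cv_sizes("clockless", s + 1000), numeric(1))
  expect_true(all(clk > ctrl))
})
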