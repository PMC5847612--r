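test_that("renewal step times follow the configured gaps deterministically", {
  cfg <- sim_config(interval_mean = 30, interval_sd = 0, duration_min = 150,
                    n_cells = 0)
  expect_equal(draw_step_times(cfg, 1), c(30, 60, 90, 120, 150))

  cfg2 <- regime_preset("control")
  expect_identical(draw_step_times(cfg2, 42), draw_step_times(cfg2, 42))
  expect_false(identical(draw_step_times(cfg2, 42), draw_step_times(cfg2, 43)))

  short <- sim_config(interval_mean = 30, interval_sd = 0, duration_min = 20,
                      n_cells = 0)
  expect_warning(st <- draw_step_times(short, 1), "too short")
  expect_length(st, 0)
})

test_that("drawn gaps match the truncated-normal moments", {
  cfg <- sim_config(interval_mean = 29.4, interval_sd = 4.6,
                    duration_min = 40000, n_cells = 0)
  gaps <- diff(draw_step_times(cfg, 99))
  gaps <- gaps[seq_len(1000)]
  expect_equal(mean(gaps), truncnorm_mean(29.4, 4.6, 5), tolerance = 0.5 / 29.4)
  # pre-truncation CV recovered within Monte-Carlo error for SD/mean <= 0.2
  cfg_big <- sim_config(interval_mean = 30, interval_sd = 6,
                        duration_min = 400000, n_cells = 0)
  g <- diff(draw_step_times(cfg_big, 7))
  expect_gt(length(g), 1e4)
  expect_equal(sd(g) / mean(g), 0.2, tolerance = 0.03)
})

test_that("gamma interval distribution is supported and truncated", {
  cfg <- sim_config(interval_mean = 36.9, interval_sd = 12.5,
                    interval_dist = "gamma", duration_min = 20000,
                    n_cells = 0)
  gaps <- diff(draw_step_times(cfg, 3))
  expect_true(all(gaps >= cfg$frame_dt))
  expect_equal(mean(gaps), 36.9, tolerance = 0.05)
})

test_that("ground truth links somite sizes to intervals via the wavefront", {
  cfg <- sim_config(interval_mean = 30, interval_sd = 0,
                    wavefront_speed = 1.6, size_noise_sd = 0, n_cells = 0,
                    duration_min = 240)
  tr <- build_truth(cfg, 1)
  expect_equal(tr$somite_sizes, rep(48, length(tr$somite_sizes)))
  # consecutive plateau differences, exactly
  expect_identical(tr$somite_sizes, diff(tr$border_positions))
  # conservation: sizes sum to the total border displacement
  expect_equal(sum(tr$somite_sizes),
               tr$border_positions[length(tr$border_positions)] -
                 tr$border_positions[1])

  tr2 <- build_truth(regime_preset("control", n_cells = 0), 5)
  expect_equal(tr2$somite_sizes, 1.65 * tr2$intervals, tolerance = 1e-12)
  expect_equal(cor(tr2$intervals, tr2$somite_sizes), 1.0, tolerance = 1e-12)
  expect_true(all(diff(tr2$step_times) > 0))
  expect_length(tr2$somite_sizes, length(tr2$step_times) - 1)
})

test_that("clock-deficient truth yields the wavefront slope under size noise", {
  cfg <- regime_preset("clockless", duration_min = 1700, n_cells = 0)
  tr <- build_truth(cfg, 21)
  expect_gte(length(tr$somite_sizes), 40)
  fit <- lm(tr$somite_sizes ~ tr$intervals)
  expect_equal(unname(coef(fit)[2]), 1.65, tolerance = 0.15)
})

test_that("identical seeds give bit-identical truth and movies", {
  cfg <- small_cfg(noise_sd = 0.05, n_cells = 4)
  t1 <- build_truth(cfg, 11); t2 <- build_truth(cfg, 11)
  expect_identical(t1$step_times, t2$step_times)
  expect_identical(t1$cell_tracks, t2$cell_tracks)
  m1 <- render_ratio_movie(t1); m2 <- render_ratio_movie(t2)
  expect_identical(m1$data, m2$data)
})

test_that("rendered ratio field is the configured sigmoid", {
  cfg <- small_cfg()
  tr <- build_truth(cfg, 2)
  mov <- render_ratio_movie(tr)
  # far anterior of the border: sigmoid tail -> ratio_low
  expect_equal(mov$data[1, 1, 1], cfg$ratio_low, tolerance = 1e-4)
  # column exactly at the border: sigmoid midpoint (position 30 = col 31)
  expect_equal(mov$data[1, 31, 1], (cfg$ratio_low + cfg$ratio_high) / 2,
               tolerance = 1e-12)
  # the mid-level crossing column tracks b(t) within 1 px in every frame
  mid <- (cfg$ratio_low + cfg$ratio_high) / 2
  for (k in seq_len(dim(mov$data)[3])) {
    t_k <- (k - 1) * cfg$frame_dt
    prof <- mov$data[1, , k]
    cross <- which(prof >= mid)[1]
    expect_lt(abs((cross - 1) * cfg$pixel_size_um - true_border_at(tr, t_k)),
              1 + 1e-9)
  }
})

test_that("rendered channels invert to the analytic ratio and place spots", {
  cfg <- small_cfg(n_cells = 1)
  tr <- build_truth(cfg, 8)
  ch <- render_channels(tr, cfg)
  ratio <- compute_ratio(ch$ypet, ch$cfp)
  analytic <- render_ratio_movie(tr)
  expect_lt(max(abs(ratio$data - analytic$data)), 1e-6)

  # no cells -> identically zero nuclei channel
  ch0 <- render_channels(build_truth(small_cfg(n_cells = 0), 8))
  expect_true(all(ch0$nuclei$data == 0))

  # one static cell: per-frame argmax at its position
  tk <- tr$cell_tracks[tr$cell_tracks$frame == 1, ]
  for (k in c(1, 5, dim(ch$nuclei$data)[3])) {
    am <- arrayInd(which.max(ch$nuclei$data[, , k]), dim(ch$nuclei$data)[1:2])
    expect_equal((am[2] - 1) * cfg$pixel_size_um, tk$x_um, tolerance = 0.51)
    expect_equal((am[1] - 1) * cfg$pixel_size_um, tk$y_um, tolerance = 0.51)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(frame_dt = 0), "frame_dt")
  expect_error(sim_config(interval_mean = 3, frame_dt = 5))
  expect_error(sim_config(ratio_low = 2, ratio_high = 1))
})
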