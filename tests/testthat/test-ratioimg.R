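make_movie <- function(data, mask = NULL, frame_dt = 5, px = 1) {
  ratio_movie(data, frame_dt, px, mask = mask)
}

test_that("compute_ratio divides, guards zero donors, and checks shapes", {
  d <- c(4, 5, 3)
  ypet <- channel_movie(array(2, d), 5, 1, "YPet")
  cfp <- channel_movie(array(1, d), 5, 1, "CFP")
  r <- compute_ratio(ypet, cfp)
  expect_true(all(r$data == 2))
  expect_true(all(r$mask))

  cfp0 <- cfp
  cfp0$data[1, 1, 1] <- 0
  r2 <- compute_ratio(ypet, cfp0, min_cfp = 0.5)
  expect_false(r2$mask[1, 1, 1])
  expect_true(is.na(r2$data[1, 1, 1]))
  expect_true(all(is.finite(r2$data[r2$mask])))

  small <- channel_movie(array(1, c(4, 5, 2)), 5, 1)
  expect_error(compute_ratio(ypet, small), "shape")
  allmasked <- channel_movie(array(0, d), 5, 1)
  expect_warning(compute_ratio(ypet, allmasked, min_cfp = 1), "masked")
})

test_that("median filter is exact against the brute-force oracle", {
  set.seed(10)
  for (window in c(3L, 5L)) {
    x <- matrix(rnorm(21 * 21), 21, 21)
    mask <- matrix(runif(21 * 21) > 0.15, 21, 21)
    mov <- make_movie(array(x, c(21, 21, 1)), array(mask, c(21, 21, 1)))
    got <- median_filter_frames(mov, window)
    want <- bf_median_filter(x, mask, window)
    expect_equal(got$data[, , 1], want, tolerance = 1e-12)
    expect_identical(got$mask, mov$mask)
  }
})

test_that("median filter removes impulses and preserves flats", {
  const <- make_movie(array(3.3, c(9, 9, 2)))
  expect_equal(median_filter_frames(const, 5L)$data, const$data)

  imp <- array(1, c(31, 31, 1))
  imp[16, 16, 1] <- 100
  mov <- make_movie(imp)
  filt <- median_filter_frames(mov, 15L)
  expect_equal(filt$data[16, 16, 1], 1)

  expect_error(median_filter_frames(const, 4L), "odd")
})

test_that("median filter is idempotent on piecewise-constant regions", {
  x <- array(1, c(20, 20, 1))
  x[, 11:20, 1] <- 5
  mov <- make_movie(x)
  f1 <- median_filter_frames(mov, 3L)
  f2 <- median_filter_frames(f1, 3L)
  interior <- cbind(rep(5:15, 2), rep(c(4, 16), each = 11))
  expect_equal(f1$data[, , 1][interior], x[, , 1][interior])
  expect_equal(f2$data, f1$data)
})

test_that("ROI means equal the brute-force disc enumeration", {
  set.seed(20)
  data <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  mask <- array(runif(length(data)) > 0.1, dim(data))
  mov <- make_movie(data, mask)
  s <- roi_mean_series(mov, center = c(8, 9), radius = 4.2)
  expect_equal(s$mean, bf_roi_means(mov, c(8, 9), 4.2))
  expect_equal(s$t_min, (0:3) * 5)

  const <- make_movie(array(1.7, c(8, 8, 3)))
  expect_true(all(roi_mean_series(const, c(4, 4), 2)$mean == 1.7))

  single <- roi_mean_series(mov, c(5, 5), 0.5)
  expect_equal(single$mean, data[5, 5, ] * ifelse(mask[5, 5, ], 1, NA))
  expect_error(roi_mean_series(mov, c(200, 200), 3), "intersect")
})

test_that("one-tailed pooled t-test matches the textbook formula", {
  a <- c(10, 11, 12); b <- c(1, 2, 3)
  got <- ttest_one_tailed(a, b)
  want <- bf_pooled_t(a, b)
  expect_equal(got$t_stat, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df)
  expect_equal(got$p_one_tailed, want$p, tolerance = 1e-12)
  expect_true(got$significant)

  same <- ttest_one_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_one_tailed, 0.5)
  expect_false(same$significant)

  zerovar <- ttest_one_tailed(c(2, 2), c(2, 2))
  expect_equal(zerovar$p_one_tailed, 0.5)

  expect_error(ttest_one_tailed(1, c(1, 2)), "at least 2")
})

test_that("significance honors the P < 0.01 rule, not 0.05", {
  # a sample pair with 0.01 < p < 0.05 must not be called significant
  a <- c(3.1, 4.4, 3.8, 4.9)
  b <- c(2.6, 3.3, 2.9, 3.7)
  res <- ttest_one_tailed(a, b)
  expect_gt(res$p_one_tailed, 0.01)
  expect_lt(res$p_one_tailed, 0.05)
  expect_false(res$significant)
  expect_true(ttest_one_tailed(a, b, alpha = 0.05)$significant)
})

test_that("t-test is antisymmetric under sample swap", {
  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(5, 0.5)
    expect_equal(ttest_one_tailed(a, b)$p_one_tailed,
                 1 - ttest_one_tailed(b, a)$p_one_tailed, tolerance = 1e-12)
  }
})

test_that("tidy/glance methods expose the t-test result", {
  td <- tidy(ttest_one_tailed(c(10, 11, 12), c(1, 2, 3)))
  expect_named(td, c("estimate_a", "estimate_b", "statistic", "df",
                     "p.value", "significant"))
  gl <- glance(ttest_one_tailed(c(10, 11, 12), c(1, 2, 3)))
  expect_equal(gl$n_a, 3)
})

test_that("IMD rendering maps low to blue, mid to white, high to red", {
  data <- array(1, c(2, 3, 1))
  data[1, 2, 1] <- 1.5
  data[1, 3, 1] <- 2
  mask <- array(TRUE, dim(data))
  mask[2, 1, 1] <- FALSE
  mov <- make_movie(data, mask)
  bright <- matrix(1, 2, 3)
  img <- imd_render(mov, 1, "3color", range = c(1, 2), intensity = bright)
  expect_gt(img[1, 1, 3], img[1, 1, 1])              # low: blue > red
  expect_equal(img[1, 2, ], c(1, 1, 1))              # mid: exact white
  expect_gt(img[1, 3, 1], img[1, 3, 3])              # high: red > blue
  expect_equal(img[2, 1, ], c(0, 0, 0))              # masked: black

  img8 <- imd_render(mov, 1, "8color", range = c(1, 2), intensity = bright)
  expect_gt(img8[1, 1, 3], img8[1, 1, 1])
  expect_gt(img8[1, 3, 1], img8[1, 3, 3])
})
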