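test_that("a model-consistent noiseless series yields zero breaks and the true slope", {
  n <- 360
  t <- seq_len(n)
  y <- 4000 + 2.5 * t + 1200 * sin(2 * pi * t / 23)
  d <- decompose_series(y)
  expect_length(d$trend_breaks, 0)
  expect_length(d$seasonal_breaks, 0)
  expect_equal(d$trend_segments$slope[1], 2.5, tolerance = 1e-6)
  # exact reconstruction
  expect_lt(max(abs(y - (d$trend + d$seasonal + d$remainder))), 1e-6)
})

test_that("a planted level drop is recovered at the right position", {
  y <- make_shift_series(n = 360, shift_at = 180, magnitude = -3000,
                         noise_sd = 100, seed = 42)
  d <- decompose_series(y)
  expect_length(d$trend_breaks, 1)
  expect_true(abs(d$trend_breaks[1] - 180) <= 1)
})

test_that("detected break indices always lie in [min_segment, N - min_segment]", {
  cfg <- sim_config(noise_sd = 300, qa_dropout_prob = 0)
  for (i in 1:10) {
    cl <- management_classes()[(i %% 4) + 1]
    y <- simulate_series(cl, cfg, seed = i, n_obs = 360)$series$values
    d <- decompose_series(y)
    for (b in c(d$trend_breaks, d$seasonal_breaks))
      expect_true(b >= 46 && b <= 314)
  }
})

test_that("dynamic-programming RSS matches the exhaustive oracle", {
  n <- 120
  min_seg <- 20
  Xlin <- cbind(1, seq_len(n))
  Xhar <- harmonic_design(n, order = 2, period = 23)
  for (seed in 1:3) {
    y <- make_shift_series(n = n, shift_at = 55, magnitude = -2500,
                           noise_sd = 300, seed = seed)
    for (X in list(Xlin, Xhar)) {
      scan <- forestmgmt:::.seg_scan_batch(matrix(y), X, min_seg, 2)
      for (k in 0:2) {
        oracle <- brute_force_seg_rss(y, X, min_seg, k)
        expect_equal(scan$rss[1, k + 1], oracle, tolerance = 1e-9)
      }
      # a permitted extra break never increases the optimal RSS
      expect_true(scan$rss[1, 2] <= scan$rss[1, 1] + 1e-9)
      expect_true(scan$rss[1, 3] <= scan$rss[1, 2] + 1e-9)
    }
  }
})

test_that("segmentation ties and positions are 1-based segment ends", {
  # noiseless step: the optimal single break is exactly the last index of
  # the first level
  y <- c(rep(0, 60), rep(10, 60)) + 0.01 * sin(seq_len(120))
  scan <- forestmgmt:::.seg_scan_batch(matrix(y), cbind(1, 1:120), 20, 1)
  expect_equal(scan$breaks[[1]][1, 1], 60)
})

test_that("spectral entropy separates periodic from noisy series", {
  n <- 360
  pure <- sin(2 * pi * seq_len(n) * 15 / n)   # exact Fourier frequency
  expect_lt(spectral_entropy(pure), 0.3)
  set.seed(8)
  noise <- rnorm(n)
  expect_gt(spectral_entropy(noise), 0.8)
  expect_lt(spectral_entropy(pure), spectral_entropy(noise))
  expect_true(spectral_entropy(noise) <= 1)
  expect_error(spectral_entropy(rep(1, 100)), "constant")
})

test_that("decomposition propagates sentinels and validates input", {
  bad <- fill_gaps(evi_series(rep(NA_real_, 360)))
  d <- decompose_series(bad)
  expect_false(d$usable)
  expect_error(decompose_series(rnorm(50)), "too short")
  s <- evi_series(c(rnorm(359, 4000), NA))
  expect_error(decompose_series(s), "gap-filled")
})

test_that("cube decomposition matches per-series decomposition", {
  cfg <- sim_config(noise_sd = 150, qa_dropout_prob = 0)
  cube <- array(NA_real_, c(1, 3, 360))
  for (j in 1:3)
    cube[1, j, ] <- simulate_series("production", cfg, seed = j,
                                    n_obs = 360)$series$values
  usable <- matrix(c(TRUE, FALSE, TRUE), 1, 3)
  res <- decompose_cube(cube, usable)
  expect_null(res$decomps[[2]])
  one <- decompose_series(cube[1, 1, ])
  expect_equal(res$decomps[[1]]$trend_breaks, one$trend_breaks)
  expect_equal(res$decomps[[1]]$trend, one$trend)
})
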