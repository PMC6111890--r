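test_that("the feature vector has exactly the 29 canonical names", {
  y <- make_shift_series(noise_sd = 50, seed = 1)
  f <- extract_features(decompose_series(y))
  expect_length(f, 29)
  expect_identical(names(f), feature_names())
  expect_identical(sort(names(f)), names(f))  # canonical order is sorted
})

test_that("two-segment break features equal direct segment computations", {
  y <- make_shift_series(n = 360, shift_at = 180, magnitude = -3000,
                         noise_sd = 100, seed = 5)
  d <- decompose_series(y)
  expect_length(d$trend_breaks, 1)
  b <- d$trend_breaks[1]
  f <- extract_features(d)
  before <- 1:b
  after <- (b + 1):360
  expect_equal(unname(f["bd_b"]), b)
  expect_equal(unname(f["bd_b_mean_diff"]), mean(y[after]) - mean(y[before]),
               tolerance = 1e-9)
  expect_equal(unname(f["bd_b_diff"]), d$trend[b + 1] - d$trend[b],
               tolerance = 1e-9)
  expect_equal(unname(f["bd_b_inqtrng"]), IQR(y[before]), tolerance = 1e-9)
  expect_lt(f["bd_b_mean_diff"], 0)
  # with a single (negative) break it is extreme in every sense
  expect_equal(unname(f["bi_b"]), b)
  expect_equal(unname(f["lb_b"]), b)
  expect_equal(unname(f["lb_b_mean_diff"]), unname(f["bd_b_mean_diff"]))
})

test_that("a positive step mirrors the negative-step structure", {
  y <- make_shift_series(n = 360, shift_at = 150, magnitude = 2500,
                         noise_sd = 80, seed = 9)
  d <- decompose_series(y)
  f <- extract_features(d)
  expect_equal(unname(f["bi_b"]), d$trend_breaks[1])
  expect_gt(f["bi_b_mean_diff"], 0)
  expect_equal(unname(f["bd_b"]), unname(f["bi_b"]))  # single break
})

test_that("breakless decompositions produce sentinel features", {
  y <- 4500 + 1500 * sin(2 * pi * seq_len(360) / 23)
  f <- extract_features(decompose_series(y))
  expect_equal(unname(f["detected_breaks"]), 0)
  expect_equal(unname(f["detected_breaks_seasonal"]), 0)
  sentinel <- setdiff(feature_names(),
                      c("entropy", "entropy_seasonal",
                        "detected_breaks", "detected_breaks_seasonal"))
  expect_true(all(f[sentinel] == 0))
  expect_gt(f["entropy"], 0)
})

test_that("production-like series have negative biggest-decrease mean change", {
  cfg <- sim_config(noise_sd = 100, qa_dropout_prob = 0, rotation_years = 10)
  hits <- 0
  for (i in 1:5) {
    y <- simulate_series("production", cfg, seed = i, n_obs = 360)
    if (length(y$truth$break_times) == 0) next
    f <- extract_features(decompose_series(y$series$values))
    if (f["detected_breaks"] > 0) {
      expect_lt(f["bd_b_mean_diff"], 0)
      hits <- hits + 1
    }
  }
  expect_gt(hits, 0)
})

test_that("feature rasters assemble with nodata and round-trip band order", {
  feats <- as.data.frame(matrix(seq_len(4 * 29), 4, 29))
  names(feats) <- feature_names()
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  stack <- assemble_feature_rasters(feats, c(2, 2), mask = mask)
  expect_length(stack, 31)  # 29 features + 2 validity flags
  expect_identical(names(stack)[1:29], feature_names())
  expect_true(is.na(stack$bd_b$values[1, 2]))   # masked pixel (3rd, col-major)
  expect_false(is.na(stack$bd_b$values[1, 1]))
  dir <- file.path(tempdir(), "fstack")
  write_raster_stack(stack, dir)
  back <- read_raster_stack(dir)
  expect_identical(names(back), names(stack))
  expect_equal(back$entropy$values, stack$entropy$values)
  unlink(dir, recursive = TRUE)
  expect_error(assemble_feature_rasters(feats, c(3, 2)), "rows")
})
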