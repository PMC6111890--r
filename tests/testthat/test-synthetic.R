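test_that("noiseless preservation series is exactly baseline plus harmonic", {
  cfg <- sim_config(noise_sd = 0, qa_dropout_prob = 0)
  s <- simulate_series("preservation", cfg, seed = 3)
  n <- cfg$n_years * cfg$obs_per_year
  expected <- cfg$baseline +
    cfg$seasonal_amplitude * sin(2 * pi * (seq_len(n) - 1) / cfg$obs_per_year)
  expect_equal(s$series$values, expected)
  expect_length(s$truth$break_times, 0)
})

test_that("production clearcut count follows the rotation schedule", {
  # 20-year rotation in a 16-year window: one cut iff the uniform phase
  # offset falls inside the window, so 0 or 1 events, about 16/20 of the time
  cfg <- sim_config(rotation_years = 20, qa_dropout_prob = 0)
  counts <- vapply(1:100, function(i)
    length(simulate_series("production", cfg, seed = i)$truth$break_times), 0L)
  expect_true(all(counts %in% c(0L, 1L)))
  expect_gt(mean(counts == 1), 0.6)
  # short rotation: floor(16/5) = 3 events, plus/minus one by phase
  cfg5 <- sim_config(rotation_years = 5, qa_dropout_prob = 0)
  counts5 <- vapply(1:50, function(i)
    length(simulate_series("production", cfg5, seed = i)$truth$break_times), 0L)
  expect_true(all(abs(counts5 - 16 %/% 5) <= 1))
})

test_that("simulated series stay in the valid EVI range and are seeded", {
  cfg <- sim_config(noise_sd = 400, qa_dropout_prob = 0.3)
  for (cl in management_classes()) {
    a <- simulate_series(cl, cfg, seed = 11)
    b <- simulate_series(cl, cfg, seed = 11)
    expect_identical(a$series$values, b$series$values)
    expect_identical(a$truth, b$truth)
    expect_true(all(a$series$values >= -2000 & a$series$values <= 10000))
  }
  expect_error(simulate_series("plantation", cfg), "should be one of")
})

test_that("ecological cuts are a fixed fraction of production magnitude", {
  cfg <- sim_config(rotation_years = 8, qa_dropout_prob = 0)
  e <- simulate_series("ecological", cfg, seed = 5)
  p <- simulate_series("production", cfg, seed = 5)
  expect_identical(e$truth$break_times, p$truth$break_times)
  expect_equal(e$truth$magnitudes,
               cfg$ecological_cut_fraction * p$truth$magnitudes)
})

test_that("landscape class frequencies honour the mixture exactly by quota", {
  cfg <- sim_config()
  scene <- simulate_landscape(cfg, nrow = 50, ncol = 50, patch_size = 5,
                              seed = 2)
  freq <- table(factor(scene$truth, levels = management_classes())) / 2500
  expect_true(all(abs(as.numeric(freq) - cfg$class_mix) < 0.03))
  # contiguity: stands are uniform patches
  expect_true(all(scene$truth[1:5, 1:5] == scene$truth[1, 1]))
})

test_that("degenerate mixture yields a single-class landscape", {
  cfg <- sim_config(class_mix = c(ecological = 0, passive = 0,
                                  preservation = 1, production = 0))
  scene <- simulate_landscape(cfg, nrow = 20, ncol = 20, patch_size = 5,
                              seed = 1)
  expect_true(all(scene$truth == "preservation"))
  bad <- sim_config()
  bad$class_mix <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(simulate_landscape(bad, nrow = 20, ncol = 20), "sum")
  expect_error(simulate_landscape(cfg, nrow = 21, ncol = 20, patch_size = 5),
               "divisible")
})

test_that("landscape generation is reproducible under a fixed seed", {
  cfg <- sim_config()
  a <- simulate_landscape(cfg, nrow = 20, ncol = 20, patch_size = 4, seed = 9)
  b <- simulate_landscape(cfg, nrow = 20, ncol = 20, patch_size = 4, seed = 9)
  expect_identical(a$truth, b$truth)
  expect_identical(a$evi, b$evi)
  expect_identical(a$ownership, b$ownership)
  expect_identical(a$roads, b$roads)
})

test_that("annotators reproduce truth when error-free and disagree when noisy", {
  truth <- rep(management_classes(), 10)
  ann0 <- simulate_annotations(truth, annotators = 5, annotator_error = 0,
                               seed = 1)
  for (a in 1:5) expect_identical(ann0[[paste0("annotator_", a)]], truth)
  # error 0.5: the chance that >= 4 of 5 agree on any one label is small,
  # so an 80% consensus rule must fail for some points
  ann5 <- simulate_annotations(rep(truth, 5), annotators = 5,
                               annotator_error = 0.5, seed = 2)
  cons <- consensus_labels(ann5, threshold = 0.8)
  expect_gt(length(cons$unresolved), 0)
  expect_identical(
    simulate_annotations(truth, 5, 0.3, seed = 7),
    simulate_annotations(truth, 5, 0.3, seed = 7))
  expect_error(simulate_annotations(truth, annotators = 0), "annotators")
  expect_error(simulate_annotations(truth, annotator_error = 1), "error")
})
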