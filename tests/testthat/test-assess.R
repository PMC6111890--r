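test_that("accuracy arithmetic reproduces every published regional value", {
  round_half_up <- forestmgmt:::round_half_up
  rm2 <- function(x) round_half_up(x, 2)
  cm <- regional_confusion_matrices()

  seus_int <- accuracy_from_matrix(cm$seus$internal)
  expect_equal(rm2(seus_int$overall), 0.89)
  expect_equal(unname(rm2(seus_int$producers)), c(0.89, 0.82, 0.87, 0.94))
  expect_equal(unname(rm2(seus_int$users)), c(0.96, 0.87, 0.87, 0.91))
  expect_equal(seus_int$n, 800)

  seus_ext <- accuracy_from_matrix(cm$seus$external)
  expect_equal(unname(rm2(seus_ext$producers)), c(0.33, 0.49, 0.65, 0.81))
  expect_equal(unname(rm2(seus_ext$users)), c(0.50, 0.56, 0.59, 0.77))
  # the matrix-derived overall (124/178); the published 0.62/67% is
  # internally inconsistent with its own matrix
  expect_equal(seus_ext$overall, 124 / 178)

  pnw_int <- accuracy_from_matrix(cm$pnw$internal)
  expect_equal(rm2(pnw_int$overall), 0.91)
  expect_equal(unname(rm2(pnw_int$producers)), c(0.74, 0.94, 0.96, 0.82))
  expect_equal(unname(rm2(pnw_int$users)), c(0.92, 0.89, 0.97, 0.86))

  pnw_ext <- accuracy_from_matrix(cm$pnw$external)
  expect_equal(rm2(pnw_ext$overall), 0.70)
  expect_equal(unname(rm2(pnw_ext$producers)), c(0.06, 0.85, 0.90, 0.27))
  expect_equal(unname(rm2(pnw_ext$users)), c(0.17, 0.67, 0.91, 0.44))
  expect_equal(pnw_ext$n, 194)
})

test_that("confusion construction and orientation behave as documented", {
  ref <- c("production", "passive", "passive", "ecological", "preservation")
  pred <- c("production", "passive", "production", "ecological",
            "preservation")
  cf <- confusion_and_accuracies(ref, pred)
  expect_equal(cf$n, 5)
  expect_equal(cf$overall, 0.8)
  expect_equal(sum(cf$matrix), 5)
  perfect <- confusion_and_accuracies(ref, ref)
  expect_true(all(perfect$producers == 1) && all(perfect$users == 1) &&
                perfect$overall == 1)
  expect_error(confusion_and_accuracies(c("forest"), c("production")),
               "unknown")
  m <- matrix(c(8, 2, 1, 9), 2, 2)
  a <- accuracy_from_matrix(m)
  b <- accuracy_from_matrix(t(m), orientation = "rows_reference")
  expect_identical(a$matrix, b$matrix)
})

test_that("stratified folds are disjoint, covering and balanced", {
  dat <- make_separable_features(n_per_class = 25, seed = 4)
  cv <- kfold_cv(dat$features, dat$labels, k = 5, seed = 2,
                 config = rf_config(n_trees = 100, mtry = 2))
  expect_length(cv$folds, 100)
  expect_true(all(table(cv$folds) == 20))
  # per class, fold sizes differ from proportionality by at most 1
  for (cl in management_classes()) {
    tab <- table(cv$folds[dat$labels == cl])
    expect_lte(max(tab) - min(tab), 1)
  }
  cv2 <- kfold_cv(dat$features, dat$labels, k = 5, seed = 2,
                  config = rf_config(n_trees = 100, mtry = 2))
  expect_identical(cv$folds, cv2$folds)
  expect_lte(cv$mean_error, 0.05)
  # a class rarer than the fold count triggers the unstratified fallback
  labs <- c(rep("production", 40), rep("passive", 40), rep("preservation", 17),
            rep("ecological", 3))
  expect_warning(
    kfold_cv(dat$features, labs, k = 5, seed = 1,
             config = rf_config(n_trees = 50, mtry = 2)), "unstratified")
})

test_that("coarse-cell aggregation counts forest pixels only", {
  v <- matrix(4L, 4, 4)          # production everywhere
  v[1:2, 3:4] <- 1L              # one quadrant ecological
  attr(v, "levels") <- management_classes()
  cls <- fm_raster(v)
  forest <- matrix(TRUE, 4, 4)
  forest[3:4, 3:4] <- FALSE
  agg <- aggregate_proportions(cls, forest, factor = 2)
  # cells in column-major order: (1,1) (2,1) (1,2) (2,2)
  expect_equal(agg$p_obs[1, ], c(ecological = 0, passive = 0,
                                 preservation = 0, production = 1))
  expect_equal(unname(agg$p_obs[3, "ecological"]), 1)
  expect_true(all(is.na(agg$p_obs[4, ])))
  expect_equal(agg$n, c(4L, 4L, 4L, 0L))
  # half-and-half block
  h <- matrix(c(2L, 2L, 4L, 4L), 2, 2)
  agg2 <- aggregate_proportions(h, factor = 2)
  expect_equal(agg2$p_obs[1, c("passive", "production")],
               c(passive = 0.5, production = 0.5))
  # partial edge blocks use the available pixels
  agg3 <- aggregate_proportions(matrix(3L, 3, 3), factor = 2)
  expect_equal(agg3$n, c(4L, 2L, 2L, 1L))
  expect_true(all(agg3$p_obs[, "preservation"] == 1))
})

test_that("the aggregation posterior matches its oracles", {
  # identity channel, pure cell, large count: posterior concentrates on truth
  idcm <- diag(c(50, 50, 50, 50))
  agg <- list(p_obs = matrix(c(1, 0, 0, 0), 1, 4,
                             dimnames = list(NULL, management_classes())),
              n = 1000L, cell_row = 1L, cell_col = 1L, dims = c(1L, 1L))
  post <- posterior_uncertainty(agg, idcm, n_samples = 10000, seed = 1)
  expect_lt(abs(post$mean[1, 1] - 1), 0.02)
  expect_equal(sum(post$mean[1, ]), 1, tolerance = 1e-6)
  expect_true(all(post$sd[1, ] >= 0))

  # 2-class channel against 1-D grid integration
  M <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  counts <- c(200, 200)
  oracle <- grid_posterior_2class(M, counts)
  set.seed(2)
  mc <- forestmgmt:::.posterior_cell_mcmc(counts, M, 10000, 1000)
  expect_lt(abs(mc$mean[1] - oracle$mean[1]), 0.02)
  expect_lt(abs(mc$sd[1] - oracle$sd[1]), 0.02)

  # posterior sd shrinks monotonically with the cell pixel count
  sds <- vapply(c(100, 1000, 10000), function(n) {
    a <- agg
    a$n <- n
    posterior_uncertainty(a, idcm, n_samples = 5000, seed = 3)$sd[1, 1]
  }, 0)
  expect_true(all(diff(sds) < 0))

  # reproducibility under a fixed seed
  p1 <- posterior_uncertainty(agg, idcm, n_samples = 2000, seed = 7)
  p2 <- posterior_uncertainty(agg, idcm, n_samples = 2000, seed = 7)
  expect_identical(p1$mean, p2$mean)

  badcm <- idcm
  badcm[, 2] <- 0
  expect_error(posterior_uncertainty(agg, badcm, n_samples = 1000, seed = 1),
               "zero")
  expect_error(posterior_uncertainty(agg, idcm, n_samples = 10), "1000")
})
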