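test_that("line density is exact for simple geometries and linear", {
  grid <- list(nrow = 3, ncol = 3, xll = 0, yll = 0, cellsize = 100)
  empty <- data.frame(x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0))
  expect_true(all(line_density(empty, grid, 1000)$values == 0))
  # short segment through the center cell, fully inside every disc
  seg <- data.frame(x0 = 100, y0 = 150, x1 = 200, y1 = 150)
  r <- 1000
  d <- line_density(seg, grid, r)
  expect_equal(d$values[2, 2], 100 / (pi * r^2), tolerance = 1e-12)
  d2 <- line_density(rbind(seg, seg), grid, r)
  expect_equal(d2$values, 2 * d$values)
  # a segment outside the radius contributes nothing
  far <- data.frame(x0 = 5000, y0 = 5000, x1 = 5100, y1 = 5000)
  expect_equal(line_density(far, grid, 200)$values, matrix(0, 3, 3))
  expect_error(line_density(seg, grid, 0), "radius")
})

test_that("proportion upscaling counts nested fine cells exactly", {
  all_con <- matrix("conifer", 8, 8)
  expect_equal(upscale_proportion(all_con, 4, "conifer"),
               matrix(1, 2, 2))
  cb <- matrix(c("conifer", "hardwood"), 8, 8)  # checkerboard by rows
  expect_equal(upscale_proportion(cb, 4, "conifer"), matrix(0.5, 2, 2))
  expect_equal(upscale_proportion(cb, 4, character(0)), matrix(0, 2, 2))
  expect_error(upscale_proportion(matrix("a", 9, 8), 4, "a"), "nest")
})

test_that("the ownership crosswalk is total, exact and rejects unknowns", {
  cw <- ownership_crosswalk()
  # every listed pair maps to exactly one of the ten categories
  expect_false(any(duplicated(paste(cw$source, cw$label))))
  expect_true(all(cw$category %in% ownership_levels()))
  recs <- data.frame(row = c(1, 1, 2), col = c(1, 2, 1),
                     source = c("Federal Lands", "NCED", "USDA"),
                     label = c("NPS", "Private", "Corporate"))
  own <- crosswalk_ownership(recs, c(2, 2))
  expect_equal(own[1, 1], "federal protected")
  expect_equal(own[1, 2], "private")
  expect_equal(own[2, 1], "corporate")
  expect_true(is.na(own[2, 2]))
  bad <- data.frame(row = 1, col = 1, source = "NCED", label = "XYZ")
  expect_error(crosswalk_ownership(bad, c(1, 1)), "XYZ")
})

test_that("overlapping ownership records resolve by protection precedence", {
  recs <- data.frame(row = c(1, 1, 1), col = c(1, 1, 1),
                     source = c("USDA", "Federal Lands", "Federal Lands"),
                     label = c("Corporate", "DOD", "NPS"))
  own <- crosswalk_ownership(recs, c(1, 1))
  expect_equal(own[1, 1], "federal protected")
  recs2 <- data.frame(row = 1, col = 1,
                      source = c("USDA", "Federal Lands"),
                      label = c("Family", "DOD"))
  expect_equal(crosswalk_ownership(recs2, c(1, 1))[1, 1], "military")
})

test_that("the training mask applies both 50% rules inclusively", {
  ff <- matrix(c(0.5, 0.499, 0, 1), 2, 2)
  cf <- matrix(c(0.5, 0.9, 0.9, 0.49), 2, 2)
  m <- training_mask(ff, cf)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(training_mask(ff, matrix(1, 3, 2)), "dimensions")
})

test_that("forest reconciliation unions vintages and succession transitions", {
  f01 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  f06 <- matrix(FALSE, 2, 2)
  f11 <- matrix(FALSE, 2, 2)
  tr <- matrix(c("none", "forest_to_grass", "grass_to_shrub",
                 "urban_to_urban"), 2, 2)
  out <- reconcile_forest_mask(f01, f06, f11, tr)
  expect_identical(as.vector(out), c(TRUE, TRUE, TRUE, FALSE))
  tr_bad <- matrix("clearcut", 2, 2)
  expect_error(reconcile_forest_mask(f01, f06, f11, tr_bad), "transition")
})

test_that("consensus labelling applies the 80% rule and ignores annotator order", {
  ann <- rbind(c("production", "production", "production", "production", "production"),
               c("production", "production", "production", "production", "passive"),
               c("production", "production", "production", "passive", "passive"))
  cons <- consensus_labels(ann, threshold = 0.8)
  expect_identical(cons$labels, c("production", "production", NA))
  expect_identical(cons$unresolved, 3L)
  perm <- ann[, c(3, 1, 5, 2, 4)]
  expect_identical(consensus_labels(perm, 0.8)$labels, cons$labels)
  expect_error(consensus_labels(ann, threshold = 0.5), "threshold")
  expect_error(consensus_labels(ann[, 0, drop = FALSE]), "annotator")
})
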