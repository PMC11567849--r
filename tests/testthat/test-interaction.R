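test_that("mixed ANOVA matches hand and GLM oracles", {
  # identical per-subject differences in both groups: no interaction
  an <- mixed_anova_2x2(baseline = rep(0, 6), followup = rep(2, 6),
                        group = rep(c("A", "B"), each = 3))
  expect_equal(an$F_interaction, 0)
  # group A diffs (1,2,3), group B diffs (3,4,5): t^2 = 6 on df (1, 4)
  an <- mixed_anova_2x2(baseline = rep(0, 6), followup = c(1, 2, 3, 3, 4, 5),
                        group = rep(c("A", "B"), each = 3))
  expect_equal(an$F_interaction, 6)
  expect_equal(an$df, c(1L, 4L))
  # random instances against the subject-dummy GLM oracle
  set.seed(17)
  for (i in 1:5) {
    n <- 10
    grp <- rep(c("A", "B"), each = n)
    B <- rnorm(2 * n); P <- rnorm(2 * n)
    an <- mixed_anova_2x2(B, P, grp)
    expect_equal(an$F_interaction, glm_interaction_oracle(B, P, grp),
                 tolerance = 1e-10)
  }
  expect_error(mixed_anova_2x2(rnorm(3), rnorm(3), c("A", "A", "B")),
               "at least 2 subjects")
})

test_that("smoothness estimator recovers known FWHM", {
  g <- grid_geometry(c(20, 20, 20), 3)
  mask <- array(TRUE, g$dim)
  set.seed(5)
  # white noise: FWHM floored at the voxel size
  white <- lapply(1:4, function(i) array(rnorm(prod(g$dim)), g$dim))
  fw <- estimate_smoothness(white, mask, g)
  expect_true(all(abs(fw - 3) / 3 <= 0.15))
  # noise smoothed with a known 8 mm kernel recovered within 20%
  sm <- lapply(1:6, function(i)
    smooth_gaussian_3d(array(rnorm(prod(g$dim)), g$dim), fwhm_to_sigma(8) / 3))
  fw8 <- estimate_smoothness(sm, mask, g)
  expect_true(all(abs(fw8 - 8) / 8 <= 0.20))
  # units: same voxel data on a doubled voxel size doubles the mm FWHM
  g6 <- grid_geometry(c(20, 20, 20), 6)
  expect_equal(estimate_smoothness(sm, mask, g6), 2 * fw8, tolerance = 1e-10)
  # constant residuals error
  expect_error(estimate_smoothness(lapply(1:2, function(i) array(1, g$dim)),
                                   mask, g), "constant")
})

test_that("cluster labelling matches the flood-fill oracle", {
  dm <- c(8, 8, 8)
  # two voxels touching face-on: one cluster even at 6-connectivity
  b <- array(FALSE, dm); b[2, 2, 2] <- b[3, 2, 2] <- TRUE
  cl <- label_clusters(b * 1, 0.5, connectivity = 6)
  expect_equal(nrow(cl$table), 1L)
  # corner-on: two clusters under 6, one under 26
  b <- array(FALSE, dm); b[2, 2, 2] <- b[3, 3, 3] <- TRUE
  expect_equal(nrow(label_clusters(b * 1, 0.5, connectivity = 6)$table), 2L)
  expect_equal(nrow(label_clusters(b * 1, 0.5, connectivity = 26)$table), 1L)
  # random volumes against the breadth-first oracle at all connectivities
  set.seed(23)
  for (conn in c(6, 18, 26)) {
    b <- array(runif(prod(dm)) < 0.25, dm)
    cl <- label_clusters(b * 1, 0.5, connectivity = conn,
                         geometry = grid_geometry(dm, 3))
    expect_equal(sort(cl$table$n_voxels, decreasing = TRUE),
                 flood_fill_oracle(b, conn))
    expect_equal(cl$table$volume_mm3, cl$table$n_voxels * 27)
  }
})

test_that("Monte-Carlo extent threshold is reproducible and monotone", {
  g <- grid_geometry(c(10, 10, 10), 3)
  mask <- array(TRUE, g$dim)
  # degenerate alpha = 1: everything passes, threshold 1 voxel
  expect_equal(as.integer(monte_carlo_extent_threshold(
    mask, g, 3, alpha = 1, n_iter = 500, rng_seed = 2)), 1L)
  # determinism
  t1 <- monte_carlo_extent_threshold(mask, g, 6, n_iter = 500, rng_seed = 4)
  t2 <- monte_carlo_extent_threshold(mask, g, 6, n_iter = 500, rng_seed = 4)
  expect_identical(as.integer(t1), as.integer(t2))
  # monotone in smoothness: larger FWHM never lowers the threshold
  t3 <- monte_carlo_extent_threshold(mask, g, 3, n_iter = 500, rng_seed = 4)
  t9 <- monte_carlo_extent_threshold(mask, g, 9, n_iter = 500, rng_seed = 4)
  expect_gte(as.integer(t9), as.integer(t3))
  expect_error(monte_carlo_extent_threshold(mask, g, 6, n_iter = 100),
               "at least 500")
  expect_error(monte_carlo_extent_threshold(array(FALSE, g$dim), g, 6,
                                            n_iter = 500), "empty")
})

test_that("mask-mean extraction is an arithmetic mean on the region", {
  dm <- c(6, 6, 6)
  vol <- array(2.5, dm)
  mask <- array(FALSE, dm); mask[2:4, 2:4, 2:4] <- TRUE
  expect_equal(extract_mask_mean(vol, mask), 2.5)
  one <- array(FALSE, dm); one[3, 3, 3] <- TRUE
  vol[3, 3, 3] <- -1.25
  expect_equal(extract_mask_mean(vol, one), -1.25)
  # checkerboard +/-1 over an even-sized mask averages to zero
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  cb <- array(ifelse(rowSums(idx) %% 2 == 0, 1, -1), dm)
  expect_equal(extract_mask_mean(cb, array(TRUE, dm)), 0)
  expect_error(extract_mask_mean(vol, array(TRUE, c(4, 4, 4))), "mismatch")
})
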