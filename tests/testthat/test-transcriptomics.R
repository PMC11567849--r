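test_that("sample-to-mask assignment matches brute-force distances", {
  g <- grid_geometry(c(6, 6, 6), 3, origin = c(0, 0, 0))
  mask <- array(FALSE, g$dim); mask[2, 2, 2] <- mask[3, 2, 2] <- TRUE
  centers <- vox_to_mm(mask_voxels(mask), g)
  mni <- rbind(centers[1, ],                 # exactly at a mask-voxel centre
               centers[1, ] + c(1.9, 0, 0),  # within tolerance
               centers[2, ] + c(0, 10, 0),   # 10 mm away: dropped
               c(0, 0, 0),                   # off-mask voxel
               centers[2, ] + c(0, 0, 2.1))  # just outside 2 mm
  dset <- expression_dataset(matrix(rnorm(10 * 5), 10, 5), mni, rep("D1", 5))
  got <- assign_samples_to_mask(dset, mask, g, tolerance_mm = 2)
  # brute-force oracle: inside a mask voxel, or within 2 mm of a centre
  oracle <- which(sapply(seq_len(nrow(mni)), function(i) {
    v <- round(mm_to_vox(mni[i, ], g))
    inside <- all(v >= 1) && all(v <= g$dim) && mask[v[1], v[2], v[3]]
    inside || min(sqrt(rowSums(sweep(centers, 2, mni[i, ], `-`)^2))) <= 2
  }))
  expect_equal(got, oracle)
  expect_equal(got, c(1L, 2L))
  expect_error(assign_samples_to_mask(
    expression_dataset(matrix(rnorm(10), 10, 1), rbind(c(90, 90, 90)), "D1"),
    mask, g), "no expression sample")
})

test_that("regional values equal the sphere-enumeration oracle", {
  g <- grid_geometry(c(10, 10, 10), 3, origin = c(0, 0, 0))
  vol <- smooth_field(g, 6, seed = 13)
  mask <- array(TRUE, g$dim)
  # constant volume: constant values at any radius
  mni <- rbind(c(9, 9, 9), c(12, 15, 9), c(14, 8, 11))
  expect_equal(regional_value_per_sample(array(3.3, g$dim), g, mni, 6, mask),
               rep(3.3, 3))
  # radius 0: nearest-voxel lookup
  v0 <- regional_value_per_sample(vol, g, mni, 0, mask)
  near <- round(mm_to_vox(mni, g))
  expect_equal(v0, vol[near])
  # radius 6: brute-force average over enumerated in-sphere voxel centres
  v6 <- regional_value_per_sample(vol, g, mni, 6, mask)
  all_vox <- which(mask, arr.ind = TRUE)
  ctrs <- vox_to_mm(all_vox, g)
  oracle <- sapply(seq_len(nrow(mni)), function(i) {
    d2 <- rowSums(sweep(ctrs, 2, mni[i, ], `-`)^2)
    mean(vol[all_vox[d2 <= 36 + 1e-9, , drop = FALSE]])
  })
  expect_equal(v6, oracle, tolerance = 1e-12)
  # sphere entirely outside the mask: NA with a warning
  expect_warning(
    out <- regional_value_per_sample(vol, g, rbind(c(100, 100, 100)), 6, mask),
    "outside")
  expect_true(is.na(out))
})

test_that("gene-wise correlation handles exact, constant and rescaled genes", {
  set.seed(19)
  v <- rnorm(30)
  expr <- rbind(gene_same = v, gene_null = rnorm(30), gene_flat = rep(1, 30))
  tab <- genewise_correlation(expr, v)
  expect_equal(tab$r[tab$gene == "gene_same"], 1)
  expect_equal(attr(tab, "excluded"), "gene_flat")
  expect_false("gene_flat" %in% tab$gene)
  # p matches the t-distribution oracle via cor.test
  ct <- cor.test(as.numeric(expr["gene_null", ]), v)
  expect_equal(tab$p[tab$gene == "gene_null"], ct$p.value, tolerance = 1e-10)
  # per-gene affine rescaling leaves r and the significant set unchanged
  tab2 <- genewise_correlation(expr * 5 - 2, v)
  expect_equal(tab2$r, tab$r, tolerance = 1e-12)
  expect_error(genewise_correlation(expr[, 1:10], v), "disagree")
  expect_error(genewise_correlation(expr[, 1:9], v[1:9]), "fewer than 10")
})

test_that("FDR-BH follows the step-up rule", {
  # hand example: p(i) <= i * 0.001 / 5 holds for exactly the first two
  out <- fdr_bh(c(0.0001, 0.0004, 0.019, 0.095, 0.201), 0.001)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # all p = 1: nothing significant
  expect_false(any(fdr_bh(rep(1, 10), 0.001)$significant))
  # m = 1 identity
  one <- fdr_bh(0.0005, 0.001)
  expect_equal(one$q_values, 0.0005)
  expect_true(one$significant)
  # empty input, empty output
  empty <- fdr_bh(numeric(0))
  expect_length(empty$q_values, 0)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("spatial surrogates preserve marginals and variogram structure", {
  g <- grid_geometry(c(10, 10, 10), 3, origin = c(0, 0, 0))
  vol <- smooth_field(g, 9, seed = 29)
  set.seed(29)
  vox <- which(array(TRUE, g$dim), arr.ind = TRUE)
  pick <- vox[sample(nrow(vox), 150), ]
  coords <- vox_to_mm(pick, g)
  x <- vol[pick]
  s <- spatial_surrogates(x, coords, 40, rng_seed = 3)
  expect_equal(dim(s), c(150L, 40L))
  # marginal preserved exactly by rank-remapping
  for (j in c(1, 20, 40)) expect_equal(sort(s[, j]), sort(x))
  # variogram of surrogates within 20% integrated absolute deviation
  D <- as.matrix(dist(coords))
  breaks <- attr(s, "variogram_breaks")
  vg <- function(v) txnimage:::empirical_variogram(v, D, breaks)
  g0 <- vg(x)
  iad <- sapply(1:40, function(j) mean(abs(vg(s[, j]) - g0), na.rm = TRUE))
  expect_lt(mean(iad) / mean(g0, na.rm = TRUE), 0.20)
  # plain shuffles break the variogram far more than matched surrogates
  sh <- spatial_surrogates(x, coords, 40, rng_seed = 3, method = "shuffle")
  iad_sh <- sapply(1:40, function(j) mean(abs(vg(sh[, j]) - g0), na.rm = TRUE))
  expect_gt(mean(iad_sh), mean(iad))
  # n_surrogates = 0: empty set
  expect_equal(ncol(spatial_surrogates(x, coords, 0)), 0L)
  # coincident geometry falls back to unconstrained permutation
  expect_warning(spatial_surrogates(rnorm(25), matrix(0, 25, 3), 5),
                 "coincident")
})

test_that("unconstrained shuffles understate the null significant-gene count", {
  # dense sampling relative to the autocorrelation length: the regime the
  # spatially constrained null exists for
  g <- grid_geometry(c(10, 10, 10), 3, origin = c(0, 0, 0))
  mask <- array(TRUE, g$dim)
  vol <- smooth_field(g, 8, seed = 37)
  ed <- expression_design(n_genes = 600, n_samples = 250, n_planted_genes = 0,
                          spatial_corr_length_mm = 8, rng_seed = 37)
  dset <- generate_expression(ed, vol, mask, g)
  v <- regional_value_per_sample(vol, g, dset$sample_mni, 6, mask)
  expr <- dset$expr
  sh <- spatial_surrogates(v, dset$sample_mni, 60, rng_seed = 5, method = "shuffle")
  vg <- spatial_surrogates(v, dset$sample_mni, 60, rng_seed = 5, method = "variogram")
  c_sh <- txnimage:::surrogate_significant_counts(expr, sh)
  c_vg <- txnimage:::surrogate_significant_counts(expr, vg)
  expect_lt(mean(c_sh), mean(c_vg))
})

test_that("permutation count test uses the add-one estimator", {
  out <- permutation_count_test(50, rep(0, 5000))
  expect_equal(out$p_perm, 1 / 5001)
  expect_lt(out$p_perm, 0.001)
  out2 <- permutation_count_test(3, rep(10, 200))
  expect_equal(out2$p_perm, 1)
  expect_error(permutation_count_test(5, rep(0, 50)), "at least 100")
})
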