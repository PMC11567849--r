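#' Expression dataset container
#'
#' Bundles a genes x samples normalized expression matrix with per-sample
#' MNI coordinates and donor labels (the structure of Allen Human Brain
#' Atlas-style data after probe-level processing).
#'
#' @param expr numeric matrix, genes x samples, no missing values.
#' @param sample_mni numeric matrix, samples x 3, MNI mm coordinates.
#' @param donor character/factor of donor ids per sample.
#' @param gene_ids optional gene identifiers (default rownames of `expr`).
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(expr, sample_mni, donor, gene_ids = rownames(expr)) {
  expr <- as.matrix(expr)
  sample_mni <- as.matrix(sample_mni)
  if (anyNA(expr)) stop("expression matrix contains missing values")
  stopifnot(ncol(expr) == nrow(sample_mni), ncol(sample_mni) == 3L,
            all(is.finite(sample_mni)), length(donor) == ncol(expr))
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(nrow(expr)))
  rownames(expr) <- gene_ids
  structure(list(expr = expr, sample_mni = sample_mni,
                 donor = as.character(donor), gene_ids = gene_ids),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples, %d donor(s)\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$donor))))
  invisible(x)
}

#' Restrict expression samples to a region mask
#'
#' A sample is retained iff its MNI coordinate falls inside a mask voxel, or
#' lies within `tolerance_mm` of the centre of one. Deterministic.
#'
#' @param dataset an [expression_dataset()].
#' @param mask logical 3D array.
#' @param geometry a [grid_geometry()].
#' @param tolerance_mm distance slack in mm (default 2).
#' @return integer vector of retained sample indices, or an error if none.
#' @export
assign_samples_to_mask <- function(dataset, mask, geometry, tolerance_mm = 2) {
  mni <- dataset$sample_mni
  vox <- round(mm_to_vox(mni, geometry))
  dm <- geometry$dim
  inside <- vox[, 1] >= 1 & vox[, 1] <= dm[1] &
            vox[, 2] >= 1 & vox[, 2] <= dm[2] &
            vox[, 3] >= 1 & vox[, 3] <= dm[3]
  keep <- logical(nrow(mni))
  lin <- vox[inside, 1] + dm[1] * ((vox[inside, 2] - 1) + dm[2] * (vox[inside, 3] - 1))
  keep[inside] <- mask[lin]
  if (tolerance_mm > 0 && any(!keep)) {
    centers <- vox_to_mm(mask_voxels(mask), geometry)
    for (i in which(!keep)) {
      d2 <- rowSums(sweep(centers, 2L, mni[i, ], `-`)^2)
      keep[i] <- min(d2) <= tolerance_mm^2 + 1e-9
    }
  }
  if (!any(keep)) stop("no expression sample falls within the mask")
  which(keep)
}

#' Regional imaging value per expression sample
#'
#' Mean of a summary volume (e.g. the cohort-mean follow-up minus baseline
#' z within the interaction mask) over a sphere of radius `radius_mm`
#' centred at each sample's MNI coordinate, restricted to mask voxels.
#' `radius_mm = 0` returns the containing voxel's value. Samples whose
#' sphere misses the mask entirely get `NA` with a warning (callers drop
#' them).
#'
#' @param volume numeric 3D array.
#' @param geometry a [grid_geometry()].
#' @param sample_mni samples x 3 matrix of MNI mm coordinates.
#' @param radius_mm sphere radius (>= 0), default 6.
#' @param mask logical 3D array of defined voxels; default all.
#' @return numeric vector, one value (possibly `NA`) per sample.
#' @export
regional_value_per_sample <- function(volume, geometry, sample_mni,
                                      radius_mm = 6, mask = NULL) {
  stopifnot(radius_mm >= 0)
  if (is.null(mask)) mask <- array(TRUE, dim(volume))
  mni <- as.matrix(sample_mni)
  dm <- geometry$dim
  out <- rep(NA_real_, nrow(mni))
  for (i in seq_len(nrow(mni))) {
    if (radius_mm == 0) {
      v <- round(mm_to_vox(mni[i, ], geometry))
      if (any(v < 1) || any(v > dm)) next
      if (!mask[v[1], v[2], v[3]]) next
      out[i] <- volume[v[1], v[2], v[3]]
    } else {
      vox <- tryCatch(sphere_mask(list(center_mni = mni[i, ], radius_mm = radius_mm),
                                  geometry),
                      error = function(e) NULL)
      if (is.null(vox)) next
      ok <- mask[vox]
      if (!any(ok)) next
      out[i] <- mean(volume[vox[ok, , drop = FALSE]])
    }
  }
  if (anyNA(out)) warning(sprintf("%d sample(s) fall outside the defined volume; set to NA",
                                  sum(is.na(out))))
  out
}

#' Gene-wise cross-sample Pearson correlation with a regional imaging vector
#'
#' Correlates each gene's expression across retained samples with the
#' per-sample regional connectivity-change values; two-sided p from the t
#' distribution on n - 2 df. Zero-variance genes are excluded and flagged.
#'
#' @param expr genes x samples numeric matrix (already restricted to the
#'   retained samples).
#' @param regional_values numeric vector, one value per sample.
#' @return data.frame (gene, r, p) for testable genes; excluded gene ids in
#'   attribute `excluded`.
#' @export
genewise_correlation <- function(expr, regional_values) {
  expr <- as.matrix(expr)
  v <- as.numeric(regional_values)
  if (ncol(expr) != length(v)) stop("expression and regional values disagree on sample count")
  n <- length(v)
  if (n < 10L) stop("fewer than 10 samples; correlation not meaningful")
  if (stats::sd(v) == 0) stop("regional values are constant")
  genes <- rownames(expr)
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(nrow(expr)))
  ctr <- expr - rowMeans(expr)
  ss <- sqrt(rowSums(ctr^2))
  excluded <- genes[ss == 0]
  ok <- ss > 0
  v0 <- v - mean(v)
  r <- as.vector(ctr[ok, , drop = FALSE] %*% v0) / (ss[ok] * sqrt(sum(v0^2)))
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), n - 2)
  out <- data.frame(gene = genes[ok], r = r, p = p, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Benjamini-Hochberg FDR selection
#'
#' Standard BH step-up adjustment (with monotonicity enforcement, via
#' [stats::p.adjust()]); a gene is significant when its adjusted q-value is
#' at most `q_threshold`, which is exactly the step-up rule
#' `p_(i) <= i * q / m`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q_threshold FDR level (default 0.001).
#' @return list with `q_values` and logical `significant`.
#' @export
fdr_bh <- function(p_values, q_threshold = 0.001) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(list(q_values = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q_values = q, significant = q <= q_threshold)
}

# binned empirical semivariogram of values over coordinates
empirical_variogram <- function(values, D, breaks) {
  half_sq <- 0.5 * outer(values, values, `-`)^2
  lt <- lower.tri(D)
  bin <- cut(D[lt], breaks, include.lowest = TRUE)
  as.numeric(tapply(half_sq[lt], bin, mean))
}

#' Spatially constrained surrogate imaging vectors
#'
#' Generates null versions of a regional imaging vector that preserve both
#' its marginal distribution (exactly, by rank-remapping onto the original
#' values) and its spatial autocorrelation (approximately, by matching the
#' empirical variogram over the sample coordinates) — a volumetric analogue
#' of spin-test surrogate maps. Each surrogate permutes the values, smooths
#' the permutation with a distance-kernel chosen so the surrogate variogram
#' matches the original's, and rank-remaps back onto the observed values.
#' `method = "shuffle"` disables the spatial constraint (plain permutations)
#' for comparison.
#'
#' Kernel bandwidth and a white-noise mixing weight are selected once, by
#' minimising the mean absolute deviation between surrogate and original
#' binned variograms over a small grid, using `n_fit` pilot permutations.
#'
#' @param regional_values numeric vector (one value per sample).
#' @param sample_mni samples x 3 coordinate matrix.
#' @param n_surrogates number of surrogates (0 allowed).
#' @param rng_seed integer seed.
#' @param method `"variogram"` (default) or `"shuffle"`.
#' @param n_bins variogram distance bins (default 10).
#' @param n_fit pilot permutations per candidate parameter set (default 10).
#' @return matrix samples x n_surrogates; chosen bandwidth/mixture and the
#'   variogram bin edges as attributes.
#' @export
spatial_surrogates <- function(regional_values, sample_mni, n_surrogates,
                               rng_seed = 1L, method = c("variogram", "shuffle"),
                               n_bins = 10L, n_fit = 10L) {
  method <- match.arg(method)
  x <- as.numeric(regional_values)
  n <- length(x)
  coords <- as.matrix(sample_mni)
  stopifnot(nrow(coords) == n)
  if (n_surrogates == 0L) return(matrix(numeric(0), nrow = n, ncol = 0L))
  if (method == "variogram" && n < 20L) stop("at least 20 samples required for variogram fitting")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  xs <- sort(x)
  remap <- function(raw) xs[rank(raw, ties.method = "first")]

  if (method == "shuffle") {
    out <- vapply(seq_len(n_surrogates), function(i) sample(x), numeric(n))
    return(out)
  }

  D <- as.matrix(stats::dist(coords))
  dmax <- max(D)
  if (dmax == 0) {
    warning("all samples coincident; falling back to unconstrained permutation")
    return(vapply(seq_len(n_surrogates), function(i) sample(x), numeric(n)))
  }
  breaks <- seq(0, dmax / 2, length.out = n_bins + 1L)
  gamma0 <- empirical_variogram(x, D, breaks)

  bw_grid <- c(0, stats::quantile(D[lower.tri(D)], c(0.05, 0.10, 0.20, 0.30, 0.45),
                                  names = FALSE))
  mix_grid <- c(0, 0.25, 0.5, 0.75)
  kernels <- lapply(bw_grid, function(h) {
    if (h <= 0) return(NULL)
    W <- exp(-D^2 / (2 * h^2))
    W / rowSums(W)
  })
  pilot <- replicate(n_fit, sample(x))
  best <- NULL; best_dev <- Inf
  for (ih in seq_along(bw_grid)) {
    Sm <- if (is.null(kernels[[ih]])) pilot else kernels[[ih]] %*% pilot
    for (a in mix_grid) {
      if (is.null(kernels[[ih]]) && a > 0) next
      dev <- mean(vapply(seq_len(n_fit), function(j) {
        raw <- (1 - a) * scale_unit(Sm[, j]) + a * scale_unit(pilot[, j])
        g <- empirical_variogram(remap(raw), D, breaks)
        mean(abs(g - gamma0), na.rm = TRUE)
      }, numeric(1)))
      if (dev < best_dev) { best_dev <- dev; best <- c(ih, a) }
    }
  }
  W <- kernels[[best[1]]]; a <- best[2]
  out <- vapply(seq_len(n_surrogates), function(i) {
    perm <- sample(x)
    raw <- if (is.null(W)) perm else (1 - a) * scale_unit(W %*% perm) + a * scale_unit(perm)
    remap(raw)
  }, numeric(n))
  attr(out, "bandwidth_mm") <- bw_grid[best[1]]
  attr(out, "noise_mix") <- a
  attr(out, "variogram_breaks") <- breaks
  out
}

scale_unit <- function(v) {
  v <- as.numeric(v)
  s <- stats::sd(v)
  if (s == 0) return(v - mean(v))
  (v - mean(v)) / s
}

#' Permutation test on the significant-gene count
#'
#' Compares the observed number of significant genes with the counts
#' obtained from surrogate imaging vectors, using the add-one permutation
#' p-value `p_perm = (k + 1) / (n + 1)` with
#' `k = #(surrogate count >= real count)`.
#'
#' @param real_significant_count observed count.
#' @param surrogate_counts integer vector of surrogate counts (>= 100 for a
#'   reportable p).
#' @return object of class `permutation_null`: `n_surrogates`,
#'   `surrogate_counts`, `real_count`, `n_exceed`, `p_perm`.
#' @export
permutation_count_test <- function(real_significant_count, surrogate_counts) {
  if (length(surrogate_counts) < 100L)
    stop("at least 100 surrogates required for a reportable p-value")
  k <- sum(surrogate_counts >= real_significant_count)
  structure(list(n_surrogates = length(surrogate_counts),
                 surrogate_counts = as.integer(surrogate_counts),
                 real_count = as.integer(real_significant_count),
                 n_exceed = as.integer(k),
                 p_perm = (k + 1) / (length(surrogate_counts) + 1)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation null: real count %d; %d of %d surrogates >= real; p_perm = %.4g\n",
              x$real_count, x$n_exceed, x$n_surrogates, x$p_perm))
  invisible(x)
}

#' Transcription-neuroimaging association analysis
#'
#' Full transcriptomics stage: restrict expression samples to the
#' interaction mask, extract per-sample regional connectivity-change values
#' (sphere mean), correlate every gene with them, select genes by FDR-BH,
#' and test the significant-gene count against spatially constrained
#' surrogate vectors.
#'
#' @param dataset an [expression_dataset()].
#' @param summary_volume 3D array of the cohort-level connectivity-change
#'   summary (mean over subjects of follow-up minus baseline z).
#' @param mask logical 3D array (the corrected interaction mask).
#' @param geometry a [grid_geometry()].
#' @param radius_mm sphere radius for regional extraction (default 6).
#' @param tolerance_mm sample-to-mask assignment slack (default 2).
#' @param q_threshold FDR level (default 0.001).
#' @param n_surrogates surrogate count for the permutation null.
#' @param rng_seed integer seed.
#' @param surrogate `"variogram"` (default) or `"shuffle"`.
#' @return list with `association` (gene, r, p, q, significant),
#'   `retained_samples`, `regional_values`, and `permutation`
#'   (a `permutation_null`, or `NULL` when `n_surrogates == 0`).
#' @export
transcriptomic_association <- function(dataset, summary_volume, mask, geometry,
                                       radius_mm = 6, tolerance_mm = 2,
                                       q_threshold = 0.001, n_surrogates = 1000L,
                                       rng_seed = 1L,
                                       surrogate = c("variogram", "shuffle")) {
  surrogate <- match.arg(surrogate)
  idx <- assign_samples_to_mask(dataset, mask, geometry, tolerance_mm)
  vals <- regional_value_per_sample(summary_volume, geometry,
                                    dataset$sample_mni[idx, , drop = FALSE],
                                    radius_mm = radius_mm, mask = mask)
  ok <- !is.na(vals)
  idx <- idx[ok]; vals <- vals[ok]
  expr <- dataset$expr[, idx, drop = FALSE]
  assoc <- genewise_correlation(expr, vals)
  bh <- fdr_bh(assoc$p, q_threshold)
  assoc$q <- bh$q_values
  assoc$significant <- bh$significant
  real_count <- sum(assoc$significant)

  perm <- NULL
  if (n_surrogates > 0L) {
    surr <- spatial_surrogates(vals, dataset$sample_mni[idx, , drop = FALSE],
                               n_surrogates, rng_seed = rng_seed, method = surrogate)
    counts <- surrogate_significant_counts(expr, surr, q_threshold)
    perm <- permutation_count_test(real_count, counts)
  }
  list(association = assoc, retained_samples = idx, regional_values = vals,
       permutation = perm)
}

# significant-gene count for each surrogate imaging vector (vectorised:
# gene matrix standardised once, each surrogate is one matrix-vector product)
surrogate_significant_counts <- function(expr, surrogates, q_threshold = 0.001) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  ctr <- expr - rowMeans(expr)
  ss <- sqrt(rowSums(ctr^2))
  ok <- ss > 0
  ctr <- ctr[ok, , drop = FALSE] / ss[ok]
  vapply(seq_len(ncol(surrogates)), function(j) {
    v <- scale_unit(surrogates[, j])
    vn <- v / sqrt(sum(v^2))
    r <- as.vector(ctr %*% vn)
    r <- pmin(pmax(r, -1), 1)
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), n - 2)
    sum(fdr_bh(p, q_threshold)$significant)
  }, integer(1))
}
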