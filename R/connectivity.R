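#' Seed specification for seed-based functional connectivity
#'
#' The default is the left angular gyrus stimulation target used as the
#' connectivity seed: a 6 mm radius sphere centred at MNI (-45, -67, 38).
#'
#' @param center_mni 3-vector, seed centre in MNI mm.
#' @param radius_mm sphere radius in mm (> 0).
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(center_mni = c(-45, -67, 38), radius_mm = 6) {
  stopifnot(length(center_mni) == 3L, all(is.finite(center_mni)), radius_mm > 0)
  structure(list(center_mni = as.numeric(center_mni),
                 radius_mm = as.numeric(radius_mm)),
            class = "seed_spec")
}

#' Voxels of a sphere on a grid
#'
#' Returns every voxel whose centre lies within `radius_mm` of the seed
#' centre (Euclidean distance in mm). Deterministic; errors when the sphere
#' captures no voxel centre (seed outside the grid or radius too small for
#' the grid spacing).
#'
#' @param seed a [seed_spec()], or any list with `center_mni` and `radius_mm`.
#' @param geometry a [grid_geometry()].
#' @return integer matrix (n x 3) of 1-based voxel indices.
#' @export
sphere_mask <- function(seed, geometry) {
  ctr <- seed$center_mni
  r <- seed$radius_mm
  # candidate index box around the centre, then exact distance test
  lo <- floor(mm_to_vox(ctr - r, geometry))
  hi <- ceiling(mm_to_vox(ctr + r, geometry))
  lo <- pmax(as.integer(lo), 1L)
  hi <- pmin(as.integer(hi), geometry$dim)
  if (any(lo > hi)) stop("seed sphere lies entirely outside the grid")
  vox <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  mm <- vox_to_mm(vox, geometry)
  d2 <- rowSums(sweep(mm, 2L, ctr, `-`)^2)
  keep <- d2 <= r^2 + 1e-9
  if (!any(keep)) stop("seed sphere contains no voxel centre")
  vox <- vox[keep, , drop = FALSE]
  dimnames(vox) <- NULL
  storage.mode(vox) <- "integer"
  vox
}

#' Regress confounds out of time series
#'
#' Ordinary least-squares residualisation of every column of `series` on the
#' confound columns plus an always-included intercept. Rank-deficient
#' confound sets are handled by dropping collinear columns with a warning.
#'
#' @param series numeric matrix, time x voxels (or time x series).
#' @param confounds numeric matrix, time x k, or `NULL` for intercept only.
#' @return residual matrix with the same dimensions as `series`.
#' @export
nuisance_regress <- function(series, confounds = NULL) {
  series <- as.matrix(series)
  if (anyNA(series)) stop("series contains missing values")
  n <- nrow(series)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) stop("confounds and series disagree on the time dimension")
    if (anyNA(confounds)) stop("confounds contain missing values")
    X <- cbind(X, confounds)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[seq.int(qx$rank + 1L, ncol(X))]
    warning(sprintf("dropping %d collinear confound column(s): %s",
                    length(drop), paste(drop - 1L, collapse = ", ")))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  series - X %*% qr.coef(qx, series)
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, with `r` clipped to
#' `+/-(1 - clip)` beforehand so the transform stays finite.
#'
#' @param r correlations.
#' @param clip clipping margin before `atanh` (default `1e-7`).
#' @return z values.
#' @export
fisher_z <- function(r, clip = 1e-7) {
  atanh(pmin(pmax(r, -1 + clip), 1 - clip))
}

#' Seed-based functional-connectivity z-map for one scan
#'
#' Confound-regresses every voxel time series, averages the residual series
#' over the seed-sphere voxels, correlates that seed signal with every voxel's
#' residual series (Pearson), and Fisher z-transforms the result. Voxels with
#' zero residual variance (e.g. outside-brain padding) get `z = 0` and are
#' flagged rather than erroring, so all subjects keep a common grid.
#'
#' @param bold numeric 4D array (x, y, z, time).
#' @param geometry a [grid_geometry()] for the spatial dimensions.
#' @param seed a [seed_spec()].
#' @param confounds time x k confound matrix, or `NULL`.
#' @param mask logical 3D array restricting computation; default all voxels.
#' @param clip clipping margin passed to [fisher_z()].
#' @return An object of class `z_map`: list with `z` (3D array, 0 outside the
#'   mask), `flagged` (logical 3D array of zero-variance voxels), `seed`,
#'   `geometry`, and `n_time`.
#' @export
seed_fc_zmap <- function(bold, geometry, seed = seed_spec(), confounds = NULL,
                         mask = NULL, clip = 1e-7) {
  dm <- dim(bold)
  stopifnot(length(dm) == 4L, all(dm[1:3] == geometry$dim))
  n_time <- dm[4]
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  stopifnot(all(dim(mask) == dm[1:3]))
  k <- if (is.null(confounds)) 0L else ncol(as.matrix(confounds))
  if (n_time - k - 1L < 20L) stop("fewer than 20 effective time points after confound regression")

  vox <- mask_voxels(mask)
  lin <- vox[, 1] + geometry$dim[1] * ((vox[, 2] - 1) + geometry$dim[2] * (vox[, 3] - 1))
  Y <- matrix(aperm(bold, c(4, 1, 2, 3)), nrow = n_time)[, lin, drop = FALSE]
  R <- nuisance_regress(Y, confounds)

  seed_vox <- sphere_mask(seed, geometry)
  seed_lin <- seed_vox[, 1] + geometry$dim[1] *
    ((seed_vox[, 2] - 1) + geometry$dim[2] * (seed_vox[, 3] - 1))
  in_mask <- match(seed_lin, lin)
  if (anyNA(in_mask)) stop("seed sphere extends outside the brain mask")
  s <- rowMeans(R[, in_mask, drop = FALSE])
  if (stats::sd(s) == 0) stop("seed signal has zero variance")

  sds <- sqrt(colSums(R^2))
  # zero residual variance up to rounding of the confound projection
  flagged_cols <- sds <= 1e-8 * pmax(sqrt(colSums(Y^2)), 1)
  r <- rep(0, length(lin))
  ok <- !flagged_cols
  s0 <- s - mean(s)  # R already demeaned by intercept, s is a mean of demeaned
  r[ok] <- as.vector(crossprod(R[, ok, drop = FALSE], s0)) /
    (sds[ok] * sqrt(sum(s0^2)))
  z_vol <- array(0, geometry$dim)
  z_vol[lin] <- fisher_z(r, clip)
  z_vol[lin[flagged_cols]] <- 0
  flagged <- array(FALSE, geometry$dim)
  flagged[lin[flagged_cols]] <- TRUE

  structure(list(z = z_vol, flagged = flagged, seed = seed,
                 geometry = geometry, n_time = n_time),
            class = "z_map")
}
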