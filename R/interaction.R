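#' 2x2 mixed (group x timepoint) ANOVA via the difference-score identity
#'
#' For a balanced-or-not two-group design with two within-subject timepoints,
#' the interaction F equals the squared two-sample t statistic on per-subject
#' (follow-up - baseline) differences, on df (1, n1 + n2 - 2). The time main
#' effect is tested on the unweighted mean of the group difference means
#' against the same pooled difference variance, and the group main effect is
#' the two-sample F on per-subject means. This is exact for the 2x2 design
#' and is what a general linear model with subject dummy coding returns.
#'
#' All statistics are vectorised: `baseline` and `followup` may be subjects x
#' voxels matrices, in which case each F/p entry is a vector over voxels.
#' Voxels with zero pooled variance and zero effect get F = 0 (flagged via
#' `zero_variance`).
#'
#' @param baseline,followup numeric vectors (one value per subject) or
#'   subjects x voxels matrices of Fisher-z connectivity values.
#' @param group factor-like of length subjects with exactly 2 levels.
#' @return list with `F_interaction`, `F_group`, `F_time`, matching p-values,
#'   `df` (c(1, n1 + n2 - 2)), and `zero_variance` flags.
#' @export
mixed_anova_2x2 <- function(baseline, followup, group) {
  B <- if (is.matrix(baseline)) baseline else matrix(baseline, ncol = 1L)
  P <- if (is.matrix(followup)) followup else matrix(followup, ncol = 1L)
  stopifnot(all(dim(B) == dim(P)))
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (length(group) != nrow(B)) stop("group length must match the subject dimension")
  n1 <- sum(group == levels(group)[1]); n2 <- sum(group == levels(group)[2])
  if (n1 < 2L || n2 < 2L) stop("at least 2 subjects per group required")
  df2 <- n1 + n2 - 2L

  two_sample_f <- function(X) {
    x1 <- X[group == levels(group)[1], , drop = FALSE]
    x2 <- X[group == levels(group)[2], , drop = FALSE]
    m1 <- colMeans(x1); m2 <- colMeans(x2)
    ss <- colSums(sweep(x1, 2L, m1)^2) + colSums(sweep(x2, 2L, m2)^2)
    sp2 <- ss / df2
    se2 <- sp2 * (1 / n1 + 1 / n2)
    list(m1 = m1, m2 = m2, se2 = se2,
         F = ifelse(se2 == 0, ifelse((m1 - m2)^2 == 0, 0, Inf), (m1 - m2)^2 / se2))
  }

  D <- P - B
  d <- two_sample_f(D)
  g <- two_sample_f((B + P) / 2)
  tmean <- (d$m1 + d$m2) / 2
  F_time <- ifelse(d$se2 == 0, ifelse(tmean == 0, 0, Inf), tmean^2 / (d$se2 / 4))

  simplify <- function(x) if (ncol(B) == 1L) as.vector(x) else x
  pf2 <- function(f) stats::pf(f, 1, df2, lower.tail = FALSE)
  list(F_interaction = simplify(d$F), F_group = simplify(g$F), F_time = simplify(F_time),
       p_interaction = simplify(pf2(d$F)), p_group = simplify(pf2(g$F)),
       p_time = simplify(pf2(F_time)),
       df = c(1L, df2), zero_variance = simplify(d$se2 == 0))
}

#' Estimate noise smoothness (per-axis FWHM) from residual volumes
#'
#' Classical variance-of-differences estimator: along each axis the lag-1
#' neighbour correlation `rho = 1 - var(diff) / (2 var)` of the residual
#' field is converted to a Gaussian-autocorrelation FWHM,
#' `FWHM = dx * sqrt(-2 log 2 / log(rho))`. Estimates are pooled across
#' volumes; the result is floored at the voxel size (white noise maps to
#' exactly the voxel size).
#'
#' @param residuals list of 3D arrays, or a 4D array (x, y, z, volume).
#' @param mask logical 3D array.
#' @param geometry a [grid_geometry()].
#' @return numeric 3-vector of per-axis FWHM in mm.
#' @export
estimate_smoothness <- function(residuals, mask, geometry) {
  if (is.array(residuals) && length(dim(residuals)) == 4L) {
    residuals <- lapply(seq_len(dim(residuals)[4]), function(i) residuals[, , , i])
  }
  if (length(residuals) < 2L) stop("at least 2 residual volumes required")
  stopifnot(all(dim(residuals[[1]]) == dim(mask)))

  var_tot <- 0; vdif <- c(0, 0, 0); npair <- c(0, 0, 0); nvox <- 0
  for (r in residuals) {
    rv <- r[mask]
    r <- r - mean(rv)           # centre within mask
    r[!mask] <- NA
    var_tot <- var_tot + sum(r[mask]^2); nvox <- nvox + sum(mask)
    dm <- dim(r)
    shifts <- list(function(a) a[-1, , , drop = FALSE] - a[-dm[1], , , drop = FALSE],
                   function(a) a[, -1, , drop = FALSE] - a[, -dm[2], , drop = FALSE],
                   function(a) a[, , -1, drop = FALSE] - a[, , -dm[3], drop = FALSE])
    for (ax in 1:3) {
      d <- shifts[[ax]](r)
      ok <- !is.na(d)
      vdif[ax] <- vdif[ax] + sum(d[ok]^2)
      npair[ax] <- npair[ax] + sum(ok)
    }
  }
  if (var_tot == 0) stop("residuals are constant; smoothness undefined")
  v <- var_tot / nvox
  fwhm <- numeric(3)
  for (ax in 1:3) {
    if (npair[ax] == 0) { fwhm[ax] <- geometry$voxel_size[ax]; next }
    rho <- 1 - (vdif[ax] / npair[ax]) / (2 * v)
    fwhm[ax] <- if (rho <= 0 || rho >= 1) geometry$voxel_size[ax] else
      geometry$voxel_size[ax] * sqrt(-2 * log(2) / log(rho))
  }
  pmax(fwhm, geometry$voxel_size)
}

# neighbourhood offsets; half = one of each +/- pair (for edge building)
connectivity_offsets <- function(connectivity, half = FALSE) {
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dimnames(o) <- NULL
  s <- rowSums(abs(o))
  o <- switch(as.character(connectivity),
              "6" = o[s == 1, , drop = FALSE],
              "18" = o[s >= 1 & s <= 2, , drop = FALSE],
              "26" = o[s >= 1, , drop = FALSE])
  if (half) {
    first_nz <- apply(o, 1L, function(r) r[which(r != 0)[1]])
    o <- o[first_nz > 0, , drop = FALSE]
  }
  o
}

# connected components of a set of voxels given by linear indices.
# Returns an integer component id (1..n_comp) per input voxel.
cluster_components <- function(lin, dim3, connectivity = 18L) {
  m <- length(lin)
  if (m == 0L) return(integer(0))
  vox <- arrayInd(lin, dim3)
  offs <- connectivity_offsets(connectivity, half = TRUE)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2L, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
          nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
          nb[, 3] >= 1 & nb[, 3] <= dim3[3]
    if (!any(ok)) next
    nlin <- nb[ok, 1] + dim3[1] * ((nb[ok, 2] - 1) + dim3[2] * (nb[ok, 3] - 1))
    j <- match(nlin, lin)
    has <- !is.na(j)
    a <- which(ok)[has]; b <- j[has]
    for (e in seq_along(a)) {
      ra <- find(a[e]); rb <- find(b[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

#' Label supra-threshold clusters of a statistic volume
#'
#' Connected components (6-, 18- or 26-connectivity) of voxels with
#' `stat_volume > voxel_threshold`, with sizes in voxels and mm^3.
#'
#' @param stat_volume numeric 3D array (e.g. an F map, or |z| for two-sided
#'   thresholding of a signed map).
#' @param voxel_threshold cluster-forming threshold on the statistic scale.
#' @param connectivity 6, 18 (default) or 26.
#' @param geometry a [grid_geometry()]; needed for mm^3 sizes.
#' @param mask optional logical 3D array restricting the search.
#' @return list with `labels` (integer 3D array, 0 = background) and `table`
#'   (data.frame: label, n_voxels, volume_mm3, peak_i/j/k, peak_value, sorted
#'   by size descending).
#' @export
label_clusters <- function(stat_volume, voxel_threshold, connectivity = 18L,
                           geometry = NULL, mask = NULL) {
  dm <- dim(stat_volume)
  supra <- stat_volume > voxel_threshold
  if (!is.null(mask)) supra <- supra & mask
  lin <- which(supra)
  labels <- array(0L, dm)
  if (length(lin) == 0L) {
    tab <- data.frame(label = integer(0), n_voxels = integer(0),
                      volume_mm3 = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      peak_value = numeric(0))
    return(list(labels = labels, table = tab))
  }
  comp <- cluster_components(lin, dm, connectivity)
  vol_mm3 <- if (is.null(geometry)) NA_real_ else prod(geometry$voxel_size)
  sizes <- tabulate(comp)
  ord <- order(sizes, decreasing = TRUE)
  relab <- match(comp, ord)                     # 1 = largest
  labels[lin] <- relab
  vox <- arrayInd(lin, dm)
  tab <- do.call(rbind, lapply(seq_along(ord), function(l) {
    sel <- relab == l
    vals <- stat_volume[lin[sel]]
    pk <- which.max(vals)
    data.frame(label = l, n_voxels = sum(sel),
               volume_mm3 = sum(sel) * vol_mm3,
               peak_i = vox[sel, 1][pk], peak_j = vox[sel, 2][pk],
               peak_k = vox[sel, 3][pk], peak_value = vals[pk])
  }))
  list(labels = labels, table = tab)
}

#' Monte-Carlo cluster-extent threshold (AlphaSim-style)
#'
#' Simulates Gaussian noise on the mask grid, smooths it to the estimated
#' FWHM, applies the two-sided voxelwise threshold `voxel_p`, and records the
#' maximum supra-threshold cluster size per iteration. The extent threshold
#' is the ceiling of the (1 - alpha) quantile of that max-cluster-size null
#' distribution (floored at 1 voxel); clusters at least this large control
#' the family-wise error at approximately `alpha`.
#'
#' @param mask logical 3D array.
#' @param geometry a [grid_geometry()].
#' @param est_fwhm_mm per-axis noise FWHM in mm (scalar recycled).
#' @param voxel_p two-sided voxelwise cluster-forming p (default 0.05).
#' @param alpha family-wise error rate (default 0.05).
#' @param n_iter Monte-Carlo iterations (>= 500).
#' @param connectivity 6, 18 (default) or 26.
#' @param rng_seed integer seed; recorded in the result.
#' @return integer extent threshold in voxels, with attributes
#'   `max_cluster_sizes` (the simulated null) and `rng_seed`.
#' @export
monte_carlo_extent_threshold <- function(mask, geometry, est_fwhm_mm,
                                         voxel_p = 0.05, alpha = 0.05,
                                         n_iter = 1000L, connectivity = 18L,
                                         rng_seed = 1L) {
  if (!any(mask)) stop("mask is empty")
  if (n_iter < 500L) stop("n_iter must be at least 500")
  est_fwhm_mm <- rep_len(est_fwhm_mm, 3L)
  sigma_vox <- fwhm_to_sigma(est_fwhm_mm) / geometry$voxel_size
  zcrit <- stats::qnorm(1 - voxel_p / 2)
  dm <- geometry$dim
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  max_sizes <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    x <- array(stats::rnorm(prod(dm)), dm)
    if (any(sigma_vox > 0)) x <- smooth_gaussian_3d(x, sigma_vox, normalize = "l2")
    lin <- which(mask & abs(x) > zcrit)
    max_sizes[i] <- if (length(lin) == 0L) 0L else
      max(tabulate(cluster_components(lin, dm, connectivity)))
  }
  thr <- if (alpha >= 1) 1L else max(1L, as.integer(ceiling(
    stats::quantile(max_sizes, 1 - alpha, names = FALSE, type = 7))))
  attr(thr, "max_cluster_sizes") <- max_sizes
  attr(thr, "rng_seed") <- rng_seed
  thr
}

#' Mean connectivity within a region mask
#'
#' Arithmetic mean of a z-map (or any volume) over the voxels of a region
#' mask, e.g. the group-by-timepoint interaction mask.
#'
#' @param zmap a `z_map` object or a numeric 3D array.
#' @param region_mask logical 3D array on the same grid.
#' @return scalar mean.
#' @export
extract_mask_mean <- function(zmap, region_mask) {
  vol <- if (inherits(zmap, "z_map")) zmap$z else zmap
  if (!all(dim(vol) == dim(region_mask))) stop("grid mismatch between map and region mask")
  if (!any(region_mask)) stop("region mask is empty")
  mean(vol[region_mask])
}

#' Voxelwise group x timepoint interaction analysis with extent correction
#'
#' Runs the full interaction stage on a set of per-scan z-maps: voxelwise 2x2
#' mixed ANOVA, smoothness estimation from the interaction residuals
#' (difference maps minus their group means), Monte-Carlo extent threshold,
#' and labelling of surviving clusters.
#'
#' @param zmaps named list of `z_map` objects (or 3D arrays).
#' @param scan_info data.frame with one row per element of `zmaps`, columns
#'   `scan` (names into `zmaps`), `subject`, `group`, `timepoint`
#'   (`"baseline"` / `"followup"`). Subjects missing a timepoint are dropped
#'   with a warning.
#' @param mask logical 3D array; analysis restricted to these voxels.
#' @param geometry a [grid_geometry()].
#' @param voxel_p voxelwise cluster-forming p (default 0.05, F-map
#'   thresholded at its upper `voxel_p` quantile).
#' @param alpha cluster-level family-wise error rate (default 0.05).
#' @param n_iter Monte-Carlo iterations for the extent threshold.
#' @param connectivity cluster connectivity, default 18.
#' @param rng_seed seed for the Monte-Carlo simulation.
#' @return An object of class `interaction_result`: `F_volume`, `p_volume`,
#'   `est_fwhm_mm`, `extent_threshold_voxels`, `corrected_mask`,
#'   `cluster_table`, `df`, plus the settings used.
#' @export
interaction_analysis <- function(zmaps, scan_info, mask, geometry,
                                 voxel_p = 0.05, alpha = 0.05, n_iter = 1000L,
                                 connectivity = 18L, rng_seed = 1L) {
  stopifnot(all(scan_info$scan %in% names(zmaps)),
            all(scan_info$timepoint %in% c("baseline", "followup")))
  wide <- split(scan_info, scan_info$subject)
  complete <- vapply(wide, function(d) all(c("baseline", "followup") %in% d$timepoint),
                     logical(1))
  if (!all(complete)) {
    warning(sprintf("excluding %d subject(s) missing a timepoint: %s",
                    sum(!complete), paste(names(wide)[!complete], collapse = ", ")))
    wide <- wide[complete]
  }
  subjects <- names(wide)
  group <- vapply(wide, function(d) as.character(d$group[1]), character(1))
  lin <- which(mask)
  get_vals <- function(d, tp) {
    sc <- d$scan[d$timepoint == tp][1]
    vol <- zmaps[[sc]]
    if (inherits(vol, "z_map")) vol <- vol$z
    vol[lin]
  }
  B <- t(vapply(wide, get_vals, numeric(length(lin)), tp = "baseline"))
  P <- t(vapply(wide, get_vals, numeric(length(lin)), tp = "followup"))

  an <- mixed_anova_2x2(B, P, group)
  dm <- geometry$dim
  F_vol <- array(0, dm); F_vol[lin] <- an$F_interaction
  p_vol <- array(1, dm); p_vol[lin] <- an$p_interaction

  # interaction residuals: difference maps minus their group means
  D <- P - B
  for (g in unique(group)) {
    sel <- group == g
    D[sel, ] <- sweep(D[sel, , drop = FALSE], 2L, colMeans(D[sel, , drop = FALSE]))
  }
  res_vols <- lapply(seq_len(nrow(D)), function(i) {
    v <- array(0, dm); v[lin] <- D[i, ]; v
  })
  fwhm <- estimate_smoothness(res_vols, mask, geometry)

  ext <- monte_carlo_extent_threshold(mask, geometry, fwhm, voxel_p = voxel_p,
                                      alpha = alpha, n_iter = n_iter,
                                      connectivity = connectivity,
                                      rng_seed = rng_seed)
  Fcrit <- stats::qf(1 - voxel_p, 1, an$df[2])
  cl <- label_clusters(F_vol, Fcrit, connectivity, geometry, mask = mask)
  keep <- cl$table$label[cl$table$n_voxels >= as.integer(ext)]
  corrected <- array(FALSE, dm)
  corrected[cl$labels %in% keep & cl$labels > 0L] <- TRUE
  tab <- cl$table[cl$table$label %in% keep, , drop = FALSE]
  names(tab)[names(tab) == "peak_value"] <- "peak_F"

  structure(list(F_volume = F_vol, p_volume = p_vol, est_fwhm_mm = fwhm,
                 extent_threshold_voxels = as.integer(ext),
                 corrected_mask = corrected, cluster_table = tab,
                 df = an$df, subjects = subjects, group = group,
                 voxel_p = voxel_p, alpha = alpha,
                 connectivity = connectivity, rng_seed = rng_seed,
                 geometry = geometry),
            class = "interaction_result")
}

# save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
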