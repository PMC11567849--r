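#' Design of a synthetic rTMS cohort
#'
#' Describes the generative model for a two-group (low / high sleep quality),
#' two-timepoint (baseline / follow-up) resting-state cohort with a planted
#' group x timepoint interaction in seed-coupled connectivity. Defaults
#' mirror the study conditions the pipeline targets: 23 subjects per group,
#' 3 mm isotropic voxels, a 6 mm left-angular-gyrus seed at MNI
#' (-45, -67, 38), and 170 retained BOLD volumes per scan.
#'
#' Each scan is a shared seed time course projected onto the brain with a
#' voxelwise coupling weight, plus spatially and temporally smoothed
#' Gaussian noise. The interaction is implemented by shifting each planted
#' cluster's coupling at follow-up so the subject-level Fisher-z change is
#' `+d * sigma` in the low-sleep-quality group and `-d * sigma` in the
#' high-sleep-quality group (a pure interaction), where `sigma` is the
#' across-subject standard deviation of the null z-change (measurement
#' noise plus equal-variance subject heterogeneity).
#'
#' @param grid_shape voxel counts per axis (all >= 8).
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param n_per_group subjects per group.
#' @param n_timepoints_series BOLD samples per scan.
#' @param seed_center_mni seed centre, MNI mm.
#' @param planted_clusters list of clusters, each a list with
#'   `center_vox` (3 ints), `radius_mm`, `d` (interaction effect size),
#'   `sign` (+1 / -1). `NULL` for a null (d = 0) design.
#' @param noise_fwhm_mm spatial FWHM of the noise fields (0 = white).
#' @param temporal_sigma temporal smoothing SD of seed and noise, in TRs.
#' @param base_coupling seed-coupling weight of background voxels.
#' @param seed_coupling coupling weight inside the seed sphere.
#' @param memory_assoc_r target correlation between the latent memory-change
#'   score and the planted connectivity change.
#' @param rng_seed integer seed; recorded in all outputs.
#' @return object of class `synthetic_design`.
#' @export
synthetic_design <- function(grid_shape = c(16, 16, 16), voxel_size_mm = 3,
                             n_per_group = 23, n_timepoints_series = 170,
                             seed_center_mni = c(-45, -67, 38),
                             planted_clusters = list(list(
                               center_vox = c(12, 8, 8), radius_mm = 7.5,
                               d = 1.2, sign = 1)),
                             noise_fwhm_mm = 6, temporal_sigma = 1.5,
                             base_coupling = 0.3, seed_coupling = 2,
                             memory_assoc_r = 0.55, rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 8L)) stop("grid_shape must be at least 8 per axis")
  stopifnot(voxel_size_mm > 0, n_per_group >= 2, n_timepoints_series >= 30,
            length(seed_center_mni) == 3L, noise_fwhm_mm >= 0,
            temporal_sigma >= 0, abs(memory_assoc_r) < 1)
  if (!is.null(planted_clusters))
    for (cl in planted_clusters)
      stopifnot(length(cl$center_vox) == 3L, cl$radius_mm > 0,
                is.finite(cl$d), cl$sign %in% c(-1, 1))
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_per_group = as.integer(n_per_group),
                 n_timepoints_series = as.integer(n_timepoints_series),
                 seed_center_mni = as.numeric(seed_center_mni),
                 planted_clusters = planted_clusters,
                 noise_fwhm_mm = noise_fwhm_mm,
                 temporal_sigma = temporal_sigma,
                 base_coupling = base_coupling, seed_coupling = seed_coupling,
                 memory_assoc_r = memory_assoc_r,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_design")
}

# geometry placing the seed centre on the central voxel
design_geometry <- function(design) {
  vc <- floor((design$grid_shape + 1) / 2)
  grid_geometry(design$grid_shape, design$voxel_size_mm,
                origin = design$seed_center_mni - (vc - 1) * design$voxel_size_mm)
}

# variance inflation of a correlation estimate from shared temporal
# autocorrelation exp(-k^2 / (4 s^2)): gamma = sum_k rho(k)^2
temporal_variance_factor <- function(sigma_t) {
  if (sigma_t <= 0) return(1)
  K <- ceiling(6 * sigma_t)
  sum(exp(-(-K:K)^2 / (2 * sigma_t^2)))
}

r_to_coupling <- function(r) r / sqrt(1 - r^2)
coupling_to_r <- function(w) w / sqrt(w^2 + 1)

# smooth a (x, y, z, t) array spatially (axes 1-3) and temporally (axis 4),
# L2-normalised so white noise keeps unit variance
smooth_noise_4d <- function(a, sigma_vox, sigma_t) {
  dm <- dim(a)
  sigma <- c(rep_len(sigma_vox, 3L), sigma_t)
  for (ax in 1:4) {
    if (sigma[ax] <= 0) next
    K <- gaussian_band_matrix(dm[ax], sigma[ax], normalize = "l2")
    perm <- c(ax, setdiff(1:4, ax))
    m <- K %*% matrix(aperm(a, perm), nrow = dm[ax])
    a <- aperm(array(m, dm[perm]), order(perm))
  }
  a
}

#' Generate a synthetic rTMS cohort
#'
#' Produces 2 groups x 2 timepoints x `n_per_group` scans with the planted
#' interaction structure of the design, a phenotype table (group, age, sex,
#' education, five group-shifted sleep-scale totals, four episodic-memory
#' tests whose post-minus-pre change correlates with the planted
#' connectivity change), and per-scan confound series (6 motion + white
#' matter + cerebrospinal fluid) that leak into the voxel signals so
#' nuisance regression is consequential. Pure function of (design, seed):
#' identical seeds give identical outputs.
#'
#' @param design a [synthetic_design()].
#' @param include_bold generate the 4D BOLD arrays (set `FALSE` for
#'   phenotype-level studies; ground-truth connectivity changes are
#'   generated either way).
#' @return object of class `synthetic_cohort`: `geometry`, `mask`, `scans`
#'   (named list with `bold`, `confounds`, `subject`, `group`, `timepoint`),
#'   `scan_info`, `phenotype`, `truth` (cluster mask, per-subject true
#'   z-change, noise scales), `design`.
#' @export
generate_cohort <- function(design, include_bold = TRUE) {
  geometry <- design_geometry(design)
  dm <- geometry$dim
  mask <- array(TRUE, dm)

  # planted-cluster voxels; error if a cluster leaves the mask
  cluster_vox <- list()
  if (!is.null(design$planted_clusters)) {
    for (ci in seq_along(design$planted_clusters)) {
      cl <- design$planted_clusters[[ci]]
      ctr_mm <- vox_to_mm(cl$center_vox, geometry)[1, ]
      vox <- tryCatch(
        sphere_mask(list(center_mni = ctr_mm, radius_mm = cl$radius_mm), geometry),
        error = function(e) stop(sprintf("planted cluster %d lies outside the brain mask", ci)))
      n_expect <- nrow(sphere_offsets_oracle(cl$radius_mm, geometry$voxel_size,
                                             frac_center = cl$center_vox * 0))
      if (nrow(vox) < n_expect)
        stop(sprintf("planted cluster %d lies outside the brain mask", ci))
      cluster_vox[[ci]] <- vox
    }
  }
  truth_mask <- array(FALSE, dm)
  for (vox in cluster_vox) truth_mask[vox] <- TRUE

  n <- design$n_per_group
  N <- 2L * n
  T_ <- design$n_timepoints_series
  subjects <- sprintf("S%02d", seq_len(N))
  group <- rep(c("CI+LSQ", "CI+HSQ"), each = n)
  gsign <- rep(c(1, -1), each = n)

  gamma <- temporal_variance_factor(design$temporal_sigma)
  sigma_z <- sqrt(gamma / (T_ - 3))       # per-scan z-estimate SD (null)
  sigma_subj <- sqrt(2) * sigma_z         # subject heterogeneity of z-change
  sigma_tot <- 2 * sigma_z                # total SD of observed z-change
  z0 <- fisher_z(coupling_to_r(design$base_coupling))

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(design$rng_seed)

  # --- ground-truth connectivity change per subject x cluster ------------
  n_cl <- length(cluster_vox)
  delta_z_cl <- matrix(0, N, max(n_cl, 1L))
  if (n_cl > 0) {
    for (ci in seq_len(n_cl)) {
      cl <- design$planted_clusters[[ci]]
      delta_z_cl[, ci] <- gsign * cl$sign * cl$d * sigma_tot +
        stats::rnorm(N, 0, sigma_subj)
    }
  }
  delta_z <- if (n_cl > 0) rowMeans(delta_z_cl) else rep(0, N)

  # --- phenotype ---------------------------------------------------------
  age <- round(stats::rnorm(N, 68, 7))
  sex <- stats::rbinom(N, 1, 0.4)
  education <- pmax(6, round(stats::rnorm(N, 11.7, 2.9)))

  sleep_mean <- rbind(`CI+LSQ` = c(ISI = 10.2, AIS = 9.5, PSQI = 10.4,
                                   SRSS = 26.8, ESS = 9.7),
                      `CI+HSQ` = c(ISI = 2.6, AIS = 2.8, PSQI = 4.1,
                                   SRSS = 16.4, ESS = 5.7))
  sleep_sd <- rbind(`CI+LSQ` = c(4.0, 3.6, 3.5, 5.7, 5.0),
                    `CI+HSQ` = c(1.6, 1.6, 1.9, 2.0, 3.7))
  u <- stats::rnorm(N)                    # shared sleep-severity latent
  sleep <- sapply(1:5, function(j) {
    gi <- ifelse(group == "CI+LSQ", 1L, 2L)
    round(sleep_mean[gi, j] + sleep_sd[gi, j] *
            (0.35 * u + sqrt(1 - 0.35^2) * stats::rnorm(N)))
  })
  colnames(sleep) <- colnames(sleep_mean)

  # memory change tracks the within-group connectivity variation (both
  # groups share the mean improvement; the cross-subject association is
  # what the behavioral stage tests)
  a <- design$memory_assoc_r
  dz_ctr <- delta_z - stats::ave(delta_z, group)
  dz_std <- if (stats::sd(dz_ctr) > 0) scale_unit(dz_ctr) else rep(0, N)
  mem_latent <- a * dz_std + sqrt(1 - a^2) * stats::rnorm(N)
  mem_tests <- c("AVLT_IR", "AVLT_SR", "AVLT_LR", "VR_DR")
  pre_mean <- c(13.6, 3.5, 3.1, 5.4); pre_sd <- c(5.2, 2.9, 2.7, 3.9)
  chg_mean <- c(3.7, 2.0, 1.6, 1.9); chg_sd <- c(2.2, 2.0, 1.9, 2.1)
  pre <- sapply(1:4, function(j) round(pmax(0, stats::rnorm(N, pre_mean[j], pre_sd[j]))))
  chg <- sapply(1:4, function(j) round(chg_mean[j] + chg_sd[j] *
                                         (0.75 * mem_latent + sqrt(1 - 0.75^2) * stats::rnorm(N))))
  post <- pmax(pre + chg, 0)
  colnames(pre) <- paste0(mem_tests, "_pre")
  colnames(post) <- paste0(mem_tests, "_post")

  phenotype <- data.frame(subject = subjects, group = group, age = age,
                          sex = sex, education = education,
                          sleep, pre, post,
                          stringsAsFactors = FALSE)

  # --- confound series (always generated, fixed draw order) -------------
  scan_info <- expand.grid(subject = subjects,
                           timepoint = c("baseline", "followup"),
                           stringsAsFactors = FALSE)
  scan_info <- scan_info[order(scan_info$subject, scan_info$timepoint), ]
  scan_info$group <- group[match(scan_info$subject, subjects)]
  scan_info$scan <- paste(scan_info$subject, scan_info$timepoint, sep = "_")
  rownames(scan_info) <- NULL
  scan_info <- scan_info[, c("scan", "subject", "group", "timepoint")]

  Kt <- gaussian_band_matrix(T_, 3, normalize = "sum")
  confounds <- lapply(seq_len(nrow(scan_info)), function(i) {
    motion <- sapply(1:6, function(j) cumsum(stats::rnorm(T_, 0, 0.02)))
    tissue <- sapply(1:2, function(j) as.vector(Kt %*% stats::rnorm(T_)))
    cf <- cbind(motion, tissue)
    colnames(cf) <- c(paste0("motion", 1:6), "wm", "csf")
    cf
  })
  names(confounds) <- scan_info$scan

  # --- BOLD scans --------------------------------------------------------
  sigma_vox <- fwhm_to_sigma(design$noise_fwhm_mm) / geometry$voxel_size
  seed_vox <- sphere_mask(seed_spec(design$seed_center_mni, 6), geometry)
  w_base <- array(design$base_coupling, dm)
  w_base[seed_vox] <- design$seed_coupling

  scans <- vector("list", nrow(scan_info))
  names(scans) <- scan_info$scan
  for (i in seq_len(nrow(scan_info))) {
    si <- match(scan_info$subject[i], subjects)
    w <- w_base
    if (n_cl > 0 && scan_info$timepoint[i] == "followup") {
      for (ci in seq_len(n_cl)) {
        z1 <- z0 + delta_z_cl[si, ci]
        w[cluster_vox[[ci]]] <- r_to_coupling(tanh(z1))
      }
    }
    scan <- list(subject = scan_info$subject[i], group = scan_info$group[i],
                 timepoint = scan_info$timepoint[i],
                 confounds = confounds[[i]])
    if (include_bold) {
      s <- as.numeric(scale(smooth_noise_1d(stats::rnorm(T_), design$temporal_sigma)))
      noise <- smooth_noise_4d(array(stats::rnorm(prod(dm) * T_), c(dm, T_)),
                               sigma_vox, design$temporal_sigma)
      bold <- array(as.vector(w) %o% s + matrix(noise, prod(dm), T_), c(dm, T_))
      B <- matrix(stats::rnorm(prod(dm) * 8, 0, 0.15), prod(dm), 8)
      bold <- bold + array(B %*% t(confounds[[i]]), c(dm, T_))
      scan$bold <- bold
    }
    scans[[i]] <- scan
  }

  structure(list(geometry = geometry, mask = mask, scans = scans,
                 scan_info = scan_info, phenotype = phenotype,
                 truth = list(cluster_mask = truth_mask,
                              cluster_vox = cluster_vox,
                              delta_z = stats::setNames(delta_z, subjects),
                              sigma_z = sigma_z, sigma_tot = sigma_tot,
                              z0 = z0, gamma = gamma),
                 design = design),
            class = "synthetic_cohort")
}

smooth_noise_1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  as.vector(gaussian_band_matrix(length(x), sigma, normalize = "l2") %*% x)
}

# brute-force sphere voxel-offset enumeration used for cluster validation
sphere_offsets_oracle <- function(radius_mm, voxel_size, frac_center = c(0, 0, 0)) {
  r_vox <- ceiling(radius_mm / min(voxel_size))
  g <- as.matrix(expand.grid(-r_vox:r_vox, -r_vox:r_vox, -r_vox:r_vox))
  mm <- sweep(sweep(g, 2L, frac_center, `-`), 2L, voxel_size, `*`)
  g[rowSums(mm^2) <= radius_mm^2 + 1e-9, , drop = FALSE]
}

#' Compute z-maps for every scan of a synthetic cohort
#'
#' Convenience driver: runs [seed_fc_zmap()] (with each scan's confounds) on
#' all scans.
#'
#' @param cohort a `synthetic_cohort` with BOLD data.
#' @param seed a [seed_spec()]; defaults to the design's seed at 6 mm.
#' @return named list of `z_map` objects parallel to `cohort$scan_info`.
#' @export
cohort_zmaps <- function(cohort, seed = NULL) {
  if (is.null(seed)) seed <- seed_spec(cohort$design$seed_center_mni, 6)
  lapply(cohort$scans, function(sc) {
    if (is.null(sc$bold)) stop("cohort was generated without BOLD data")
    seed_fc_zmap(sc$bold, cohort$geometry, seed, confounds = sc$confounds,
                 mask = cohort$mask)
  })
}

#' Cohort-mean connectivity-change volume
#'
#' Mean over subjects of the (follow-up minus baseline) z volume — the
#' imaging summary correlated with gene expression.
#'
#' @param zmaps named list of `z_map` objects.
#' @param scan_info data.frame with `scan`, `subject`, `timepoint`.
#' @return numeric 3D array.
#' @export
connectivity_change_summary <- function(zmaps, scan_info) {
  subs <- unique(scan_info$subject)
  acc <- NULL
  for (s in subs) {
    b <- scan_info$scan[scan_info$subject == s & scan_info$timepoint == "baseline"]
    f <- scan_info$scan[scan_info$subject == s & scan_info$timepoint == "followup"]
    d <- zmaps[[f]]$z - zmaps[[b]]$z
    acc <- if (is.null(acc)) d else acc + d
  }
  acc / length(subs)
}

#' Design of a synthetic expression dataset
#'
#' Emulates Allen Human Brain Atlas-style data at reduced scale: spatially
#' autocorrelated per-gene noise over sample locations, per-donor intercept
#' offsets, and a planted subset of genes correlated with a supplied
#' imaging map.
#'
#' @param n_genes,n_samples,n_donors counts.
#' @param n_planted_genes number of genes carrying signal
#'   (`0 < n_planted_genes < n_genes`; 0 allowed for a null design).
#' @param planted_r target cross-sample correlation of planted genes with
#'   the imaging map (`|planted_r| < 1`).
#' @param spatial_corr_length_mm Gaussian autocorrelation scale of the
#'   per-gene noise fields.
#' @param donor_sd SD of per-gene, per-donor intercept offsets.
#' @param rng_seed integer seed.
#' @return object of class `expression_design`.
#' @export
expression_design <- function(n_genes = 2000, n_samples = 300, n_donors = 6,
                              n_planted_genes = 50, planted_r = 0.8,
                              spatial_corr_length_mm = 5, donor_sd = 0.3,
                              rng_seed = 1L) {
  stopifnot(n_genes >= 2, n_samples >= 10, n_donors >= 1,
            n_planted_genes >= 0, n_planted_genes < n_genes,
            abs(planted_r) < 1, spatial_corr_length_mm >= 0, donor_sd >= 0)
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 n_donors = as.integer(n_donors),
                 n_planted_genes = as.integer(n_planted_genes),
                 planted_r = planted_r,
                 spatial_corr_length_mm = spatial_corr_length_mm,
                 donor_sd = donor_sd, rng_seed = as.integer(rng_seed)),
            class = "expression_design")
}

#' Generate a synthetic expression dataset over a mask
#'
#' Sample locations are drawn uniformly inside mask voxels. Planted genes
#' are `planted_r * target + sqrt(1 - planted_r^2) * noise`; all genes carry
#' spatially autocorrelated noise (Gaussian-kernel mixing of sample-level
#' white noise by inter-sample distance) plus per-donor intercepts. The
#' empirical correlation of planted genes with the target is `planted_r`
#' within sampling error; non-planted genes have expected correlation 0.
#'
#' @param design an [expression_design()].
#' @param target_map numeric 3D array defined on `mask` (the imaging map the
#'   planted genes track).
#' @param mask logical 3D array.
#' @param geometry a [grid_geometry()].
#' @return an [expression_dataset()]; planted gene ids in attribute
#'   `planted_genes`, the design in attribute `design`.
#' @export
generate_expression <- function(design, target_map, mask, geometry) {
  if (design$n_samples < 10L) stop("n_samples must be at least 10")
  stopifnot(all(dim(target_map) == geometry$dim), all(dim(mask) == geometry$dim))
  vox_all <- mask_voxels(mask)
  if (nrow(vox_all) == 0L) stop("mask is empty")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(design$rng_seed)
  n <- design$n_samples
  pick <- vox_all[sample.int(nrow(vox_all), n, replace = TRUE), , drop = FALSE]
  jitter <- matrix(stats::runif(3 * n, -0.5, 0.5), n, 3)
  coords <- vox_to_mm(pick, geometry) +
    sweep(jitter, 2L, geometry$voxel_size, `*`)
  tvals <- target_map[pick]
  if (stats::sd(tvals) == 0) stop("target map is constant over the sampled voxels")
  t_std <- scale_unit(tvals)

  donor <- sprintf("D%02d", sample.int(design$n_donors, n, replace = TRUE))

  # spatially autocorrelated unit-variance noise per gene
  G <- design$n_genes
  E <- matrix(stats::rnorm(n * G), n, G)
  if (design$spatial_corr_length_mm > 0) {
    D <- as.matrix(stats::dist(coords))
    W <- exp(-D^2 / (2 * design$spatial_corr_length_mm^2))
    W <- W / sqrt(rowSums(W^2))
    E <- W %*% E
  }
  dv <- design$donor_sd^2
  if (dv > 0) {
    offsets <- matrix(stats::rnorm(design$n_donors * G, 0, design$donor_sd),
                      design$n_donors, G)
    du <- match(donor, sort(unique(donor)))
    E <- sqrt(1 / (1 + dv)) * (E + offsets[du, , drop = FALSE])
  }
  expr <- t(E)                               # genes x samples
  gene_ids <- sprintf("G%05d", seq_len(G))
  planted <- sort(sample.int(G, design$n_planted_genes))
  if (length(planted)) {
    r <- design$planted_r
    expr[planted, ] <- r * matrix(t_std, length(planted), n, byrow = TRUE) +
      sqrt(1 - r^2) * expr[planted, , drop = FALSE]
  }
  rownames(expr) <- gene_ids
  out <- expression_dataset(expr, coords, donor, gene_ids)
  attr(out, "planted_genes") <- gene_ids[planted]
  attr(out, "design") <- design
  out
}

#' Generate a random background PPI edge table
#'
#' Erdos-Renyi background graph with an optional denser planted module,
#' written in the STRING integer dialect (combined scores uniform on
#' 400-999, i.e. 0.4-1.0 after normalization).
#'
#' @param n_nodes number of nodes (named `G0001` ...).
#' @param edge_prob background edge probability.
#' @param planted_module `NULL`, or a list with `nodes` (character subset or
#'   integer indices) and `within_prob` (edge probability inside the
#'   module).
#' @param rng_seed integer seed.
#' @return data.frame (`node1`, `node2`, `combined_score`); module node
#'   names in attribute `module_nodes`.
#' @export
generate_ppi_background <- function(n_nodes, edge_prob, planted_module = NULL,
                                    rng_seed = 1L) {
  stopifnot(n_nodes >= 2, edge_prob >= 0, edge_prob <= 1)
  nodes <- sprintf("G%04d", seq_len(n_nodes))
  module <- character(0)
  within_prob <- NULL
  if (!is.null(planted_module)) {
    within_prob <- planted_module$within_prob
    stopifnot(within_prob >= 0, within_prob <= 1)
    module <- if (is.numeric(planted_module$nodes)) nodes[planted_module$nodes]
              else as.character(planted_module$nodes)
    stopifnot(all(module %in% nodes))
  }
  pairs <- utils::combn(n_nodes, 2)
  prob <- rep(edge_prob, ncol(pairs))
  if (length(module)) {
    in_mod <- nodes[pairs[1, ]] %in% module & nodes[pairs[2, ]] %in% module
    prob[in_mod] <- within_prob
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  present <- stats::runif(ncol(pairs)) < prob
  score <- sample.int(600, sum(present), replace = TRUE) + 399L
  out <- data.frame(node1 = nodes[pairs[1, present]],
                    node2 = nodes[pairs[2, present]],
                    combined_score = score, stringsAsFactors = FALSE)
  attr(out, "module_nodes") <- module
  out
}
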