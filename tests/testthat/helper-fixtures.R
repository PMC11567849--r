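# shared fixtures, all generated in code

# isotropic grid with its origin placed so `center_mni` sits on a voxel centre
centered_geometry <- function(dim = c(12, 12, 12), voxel = 3,
                              center_mni = c(0, 0, 0)) {
  vc <- floor((dim + 1) / 2)
  grid_geometry(dim, voxel, origin = center_mni - (vc - 1) * voxel)
}

# smooth Gaussian random field on a grid (the stand-in for a cohort-level
# connectivity-change summary map)
smooth_field <- function(geometry, fwhm_mm = 6, seed = 1) {
  set.seed(seed)
  smooth_gaussian_3d(array(rnorm(prod(geometry$dim)), geometry$dim),
                     fwhm_to_sigma(fwhm_mm) / geometry$voxel_size)
}

# independent sphere oracle: integer voxel offsets with centre distance <= r
sphere_count_oracle <- function(radius_mm, voxel_mm, frac_offset = c(0, 0, 0)) {
  k <- ceiling(radius_mm / voxel_mm) + 1
  g <- as.matrix(expand.grid(-k:k, -k:k, -k:k))
  mm <- sweep(g, 2, frac_offset, `+`) * voxel_mm
  sum(rowSums(mm^2) <= radius_mm^2 + 1e-9)
}

# flood-fill connected-components oracle (breadth-first, queue-based; an
# independent algorithm from the package's union-find)
flood_fill_oracle <- function(binary, connectivity) {
  dm <- dim(binary)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  s <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6"  = offs[s == 1, , drop = FALSE],
                 "18" = offs[s >= 1 & s <= 2, , drop = FALSE],
                 "26" = offs[s >= 1, , drop = FALSE])
  seen <- array(FALSE, dm)
  sizes <- integer(0)
  idx <- which(binary, arr.ind = TRUE)
  for (start in seq_len(nrow(idx))) {
    v0 <- idx[start, ]
    if (seen[v0[1], v0[2], v0[3]]) next
    queue <- matrix(v0, ncol = 3)
    seen[v0[1], v0[2], v0[3]] <- TRUE
    size <- 0L
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (o in seq_len(nrow(offs))) {
        nb <- v + offs[o, ]
        if (any(nb < 1) || any(nb > dm)) next
        if (binary[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue <- rbind(queue, nb)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# long-format general-linear-model oracle for the 2x2 mixed ANOVA
# interaction F (subject dummies + time + time:group)
glm_interaction_oracle <- function(baseline, followup, group) {
  n <- length(baseline)
  d <- data.frame(z = c(baseline, followup),
                  subject = factor(rep(seq_len(n), 2)),
                  time = factor(rep(c("pre", "post"), each = n),
                                levels = c("pre", "post")),
                  group = factor(rep(group, 2)))
  fit <- stats::lm(z ~ subject + time + time:group, data = d)
  a <- stats::anova(fit)
  a["time:group", "F value"]
}

# small deterministic toy PPI graph: 6 nodes, 7 edges, all scores 0.95
toy_ppi_graph <- function() {
  edges <- data.frame(
    node1 = c("A", "A", "B", "B", "C", "D", "E"),
    node2 = c("B", "C", "C", "D", "D", "E", "F"),
    combined_score = 0.95)
  ppi_graph(edges, min_score = 0.7)
}
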