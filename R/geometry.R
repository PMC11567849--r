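#' Regular voxel-grid geometry
#'
#' Minimal description of an axis-aligned MNI-space voxel grid: array
#' dimensions, isotropic-or-not voxel size, and the world (mm) coordinate of
#' the centre of voxel `(1, 1, 1)`. All volumes in the pipeline live on such
#' a grid.
#'
#' @param dim integer 3-vector of voxel counts per axis.
#' @param voxel_size voxel edge length(s) in mm; scalar is recycled to 3.
#' @param origin mm coordinate of the centre of the first voxel.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dim, voxel_size = 3, origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  stopifnot(all(voxel_size > 0), length(origin) == 3L, all(is.finite(origin)))
  structure(list(dim = dim, voxel_size = voxel_size, origin = as.numeric(origin)),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %s voxels, %s mm, origin (%s) mm\n",
              paste(x$dim, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Convert voxel indices to world (mm) coordinates
#'
#' @param vox integer matrix (n x 3) or 3-vector of 1-based voxel indices.
#' @param geometry a [grid_geometry()].
#' @return numeric matrix (n x 3) of mm coordinates of voxel centres.
#' @export
vox_to_mm <- function(vox, geometry) {
  v <- if (is.matrix(vox)) vox else matrix(vox, ncol = 3L)
  sweep(sweep(v - 1, 2L, geometry$voxel_size, `*`), 2L, geometry$origin, `+`)
}

#' Convert world (mm) coordinates to fractional voxel indices
#'
#' @param mm numeric matrix (n x 3) or 3-vector of mm coordinates.
#' @param geometry a [grid_geometry()].
#' @return numeric matrix (n x 3) of 1-based (fractional) voxel indices.
#' @export
mm_to_vox <- function(mm, geometry) {
  m <- if (is.matrix(mm)) mm else matrix(mm, ncol = 3L)
  sweep(sweep(m, 2L, geometry$origin, `-`), 2L, geometry$voxel_size, `/`) + 1
}

#' Voxel coordinates of all TRUE voxels of a mask
#' @param mask logical 3D array.
#' @return integer matrix (n x 3).
#' @keywords internal
mask_voxels <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# 1D Gaussian convolution matrix for an axis of length n. Rows normalised to
# unit sum ("sum": preserves means, for signal fields) or unit L2 norm
# ("l2": preserves the variance of white noise, for noise fields).
gaussian_band_matrix <- function(n, sigma, normalize = c("sum", "l2")) {
  normalize <- match.arg(normalize)
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), `-`)
  K <- exp(-d^2 / (2 * sigma^2))
  K[abs(d) > ceiling(4 * sigma)] <- 0
  nrm <- if (normalize == "sum") rowSums(K) else sqrt(rowSums(K^2))
  K / nrm
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param a numeric 3D array.
#' @param sigma_vox kernel standard deviation in voxels per axis (scalar
#'   recycled); `0` skips an axis.
#' @param normalize `"sum"` preserves local means; `"l2"` preserves the
#'   pointwise variance of white-noise input (used when simulating smooth
#'   null fields that are then thresholded at Gaussian quantiles).
#' @return smoothed array of the same dimensions.
#' @export
smooth_gaussian_3d <- function(a, sigma_vox, normalize = c("sum", "l2")) {
  normalize <- match.arg(normalize)
  dm <- dim(a)
  stopifnot(length(dm) == 3L)
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    K <- gaussian_band_matrix(dm[ax], sigma_vox[ax], normalize)
    perm <- c(ax, setdiff(1:3, ax))
    m <- K %*% matrix(aperm(a, perm), nrow = dm[ax])
    a <- aperm(array(m, dm[perm]), order(perm))
  }
  a
}

#' Convert a Gaussian FWHM to the kernel standard deviation
#' @param fwhm full width at half maximum (any length unit).
#' @return standard deviation in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))
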