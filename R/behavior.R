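#' Composite episodic-memory z-score
#'
#' Converts each memory test's raw scores to z-scores using the mean and SD
#' of the reference population (all rows supplied — pool both sessions into
#' one table to score them on a common scale), then sums the per-test
#' z-scores into one unweighted composite per row.
#'
#' @param test_scores numeric matrix or data.frame, subjects (x sessions) in
#'   rows, memory tests in columns (e.g. AVLT-IR, AVLT-SR, AVLT-LR, VR-DR).
#' @return numeric vector of composite z-sums, one per row; per-test means
#'   and SDs attached as attributes `center` / `scale`.
#' @export
composite_memory_z <- function(test_scores) {
  X <- as.matrix(test_scores)
  if (nrow(X) < 3L) stop("at least 3 subjects required")
  if (anyNA(X)) stop("test scores contain missing values")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  if (any(sdv == 0)) {
    bad <- colnames(X)[sdv == 0]
    if (is.null(bad)) bad <- which(sdv == 0)
    stop(sprintf("zero-variance test(s): %s", paste(bad, collapse = ", ")))
  }
  z <- sweep(sweep(X, 2L, mu), 2L, sdv, `/`)
  out <- rowSums(z)
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

#' Sleep-quality index (PCA) and median-split grouping
#'
#' Standardises the sleep-scale totals (higher raw totals mean worse sleep on
#' all five scales), takes the first principal component as a single
#' sleep-quality index, orients it so that the loading on the insomnia
#' severity scale (`ISI` column if present, else the first scale) is
#' negative — higher index = better sleep — and median-splits the cohort:
#' strictly below the median is the low-sleep-quality group (`CI+LSQ`), at
#' or above is the high-sleep-quality group (`CI+HSQ`). With an even number
#' of subjects and distinct scores this yields two equal halves.
#'
#' Constant scales are dropped with a warning; fewer than 2 usable scales is
#' an error.
#'
#' @param scale_totals numeric matrix or data.frame, subjects x sleep scales
#'   (e.g. ISI, AIS, PSQI, SRSS, ESS).
#' @return data.frame with `pc1_score`, `group` (factor `CI+LSQ` / `CI+HSQ`),
#'   rownames preserved; PC1 loadings and explained-variance proportion as
#'   attributes `loadings` / `var_explained`.
#' @export
sleep_pca_split <- function(scale_totals) {
  X <- as.matrix(scale_totals)
  if (nrow(X) < 4L) stop("at least 4 subjects required")
  if (anyNA(X)) stop("scale totals contain missing values")
  sdv <- apply(X, 2L, stats::sd)
  if (any(sdv == 0)) {
    warning(sprintf("dropping constant scale(s): %s",
                    paste(colnames(X)[sdv == 0], collapse = ", ")))
    X <- X[, sdv > 0, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("fewer than 2 non-constant scales remain")
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1L]
  load1 <- pc$rotation[, 1L]
  anchor <- if ("ISI" %in% colnames(X)) which(colnames(X) == "ISI") else 1L
  if (load1[anchor] > 0) { scores <- -scores; load1 <- -load1 }
  grp <- factor(ifelse(scores < stats::median(scores), "CI+LSQ", "CI+HSQ"),
                levels = c("CI+LSQ", "CI+HSQ"))
  out <- data.frame(pc1_score = scores, group = grp)
  rownames(out) <- rownames(scale_totals)
  attr(out, "loadings") <- load1
  attr(out, "var_explained") <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  out
}

#' Covariate-adjusted (partial) Pearson correlation
#'
#' Residualises `x` and `y` on the covariates plus an intercept and returns
#' the Pearson correlation of the residuals, with a t-test p-value on
#' `df = n - k - 2`. With no covariates this is the plain Pearson correlation
#' on `df = n - 2`.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix / data.frame (subjects x k) or `NULL`.
#' @return list with `r`, `p`, `df`.
#' @export
adjusted_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  k <- 0L
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (is.data.frame(covariates)) C <- data.matrix(covariates)
    stopifnot(nrow(C) == n)
    k <- ncol(C)
  }
  if (n <= k + 3L) stop("too few observations for the number of covariates")
  X <- cbind(rep(1, n), if (k > 0L) C)
  qx <- qr(X)
  rx <- x - X %*% qr.coef(qx, x)
  ry <- y - X %*% qr.coef(qx, y)
  if (sqrt(sum(rx^2)) <= 1e-12 * sqrt(sum((x - mean(x))^2)) ||
      sqrt(sum(ry^2)) <= 1e-12 * sqrt(sum((y - mean(y))^2)))
    stop("a covariate is collinear with x or y")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - k - 2L
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df)
}
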