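#' Fit a PCA transform with variance-retention selection
#'
#' Centres the features by their column means (optionally also scaling to
#' unit variance) and keeps the smallest number of principal components whose
#' cumulative explained-variance ratio reaches `variance_threshold`. The
#' default threshold 0.90 mirrors the common convention for reducing
#' high-dimensional convolutional features before metric learning.
#'
#' Component signs are fixed so that each component's largest-magnitude
#' loading is positive, making the transform reproducible across runs and
#' LAPACK builds up to that convention.
#'
#' @param features numeric matrix, cases in rows (>= 2 rows).
#' @param variance_threshold retained cumulative explained-variance ratio,
#'   in (0, 1]; default 0.90.
#' @param standardise if `TRUE`, scale features to unit variance before PCA
#'   (default `FALSE`: covariance PCA, the convention for CNN activations).
#' @return Object of class `fin_pca`: `mean` (and `scale` if standardised),
#'   `rotation` (`n_features x k`, orthonormal columns), `explained`
#'   (the k explained-variance ratios, non-increasing), `cum_explained`,
#'   `all_ratios`, `k`, `variance_threshold`.
#' @seealso [apply_pca()], [invert_pca()]
#' @examples
#' x <- matrix(rnorm(200), 40, 5)
#' p <- fit_pca(x, 0.9)
#' p$k; sum(p$explained)
#' @export
fit_pca <- function(features, variance_threshold = 0.9, standardise = FALSE) {
  features <- check_matrix(features, "features")
  if (nrow(features) < 2L) stop("need at least 2 cases", call. = FALSE)
  if (!is.numeric(variance_threshold) || length(variance_threshold) != 1L ||
      variance_threshold <= 0 || variance_threshold > 1)
    stop("`variance_threshold` must be in (0, 1]", call. = FALSE)

  mu <- colMeans(features)
  x <- sweep(features, 2L, mu)
  scl <- NULL
  if (standardise) {
    scl <- apply(x, 2L, stats::sd)
    if (any(scl == 0)) stop("constant feature column: cannot standardise",
                            call. = FALSE)
    x <- sweep(x, 2L, scl, "/")
  }

  sv <- svd(x)
  ev <- sv$d^2 / (nrow(x) - 1L)          # eigenvalues of the covariance
  total <- sum(ev)
  if (total <= 0) stop("feature matrix has zero total variance", call. = FALSE)
  ratios <- ev / total
  csum <- cumsum(ratios)
  k <- which(csum >= variance_threshold - 1e-12)[1L]
  if (is.na(k)) k <- length(ratios)

  rotation <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive in every component
  for (j in seq_len(k)) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) rotation[, j] <- -rotation[, j]
  }
  rownames(rotation) <- colnames(features)
  colnames(rotation) <- sprintf("PC%d", seq_len(k))

  structure(list(mean = mu,
                 scale = scl,
                 rotation = rotation,
                 explained = ratios[seq_len(k)],
                 cum_explained = csum[k],
                 all_ratios = ratios,
                 k = k,
                 variance_threshold = variance_threshold),
            class = "fin_pca")
}

#' @export
print.fin_pca <- function(x, ...) {
  cat(sprintf("<fin_pca> %d -> %d components (%.1f%% variance, threshold %g)\n",
              nrow(x$rotation), x$k, 100 * x$cum_explained,
              x$variance_threshold))
  invisible(x)
}

#' Apply / invert a fitted PCA transform
#'
#' `apply_pca()` projects new cases with the *training* mean (and scale) and
#' components — the transform is never refit, matching the requirement that
#' test data undergo exactly the transformations fitted on the training set.
#' `invert_pca()` maps component scores back to the original feature space.
#'
#' @param transform a `fin_pca` object from [fit_pca()].
#' @param features matrix with the same number of columns the transform was
#'   fitted on.
#' @param scores matrix of component scores with `transform$k` columns.
#' @return `apply_pca()`: cases x k score matrix. `invert_pca()`: cases x
#'   n_features reconstruction.
#' @export
apply_pca <- function(transform, features) {
  stopifnot(inherits(transform, "fin_pca"))
  features <- check_matrix(features, "features")
  if (ncol(features) != nrow(transform$rotation))
    stop(sprintf("feature count mismatch: transform expects %d, got %d",
                 nrow(transform$rotation), ncol(features)), call. = FALSE)
  x <- sweep(features, 2L, transform$mean)
  if (!is.null(transform$scale)) x <- sweep(x, 2L, transform$scale, "/")
  scores <- x %*% transform$rotation
  rownames(scores) <- rownames(features)
  scores
}

#' @rdname apply_pca
#' @export
invert_pca <- function(transform, scores) {
  stopifnot(inherits(transform, "fin_pca"))
  scores <- check_matrix(scores, "scores")
  if (ncol(scores) != transform$k)
    stop("score column count does not match transform$k", call. = FALSE)
  x <- scores %*% t(transform$rotation)
  if (!is.null(transform$scale)) x <- sweep(x, 2L, transform$scale, "*")
  sweep(x, 2L, transform$mean, "+")
}
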