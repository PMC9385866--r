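#' Gaussian kernel width from same-label geodesic distances
#'
#' \eqn{\sigma_G} is the natural length scale of the network: the average
#' pairwise geodesic distance between points sharing the same *predicted*
#' label, pooled over all unordered same-label pairs across labels.
#' Predicted (not true) labels are used because the network characterises
#' the classifier's geometry, not the annotation.
#'
#' @param distances n x n geodesic distance matrix.
#' @param predicted_labels one label per case; at least one label must have
#'   two or more members.
#' @return positive scalar \eqn{\sigma_G}.
#' @export
compute_sigma_g <- function(distances, predicted_labels) {
  D <- check_matrix(distances, "distances")
  n <- nrow(D)
  if (length(predicted_labels) != n)
    stop("`predicted_labels` length must match `distances`", call. = FALSE)
  total <- 0; count <- 0
  for (lab in unique(predicted_labels)) {
    idx <- which(predicted_labels == lab)
    if (length(idx) < 2L) next
    sub <- D[idx, idx, drop = FALSE]
    total <- total + sum(sub[upper.tri(sub)])
    count <- count + choose(length(idx), 2L)
  }
  if (count == 0)
    stop("no label has two or more members: sigma_G undefined", call. = FALSE)
  total / count
}

#' Gaussian radial kernel adjacency
#'
#' Converts geodesic distances into the network's connection weights,
#' \deqn{A_{ij} = \exp(-D_{ij}^2 / \sigma_G^2),}
#' a symmetric matrix with unit diagonal and entries in (0, 1]. The
#' adjacency is not consumed by the embedding (MDS works on distances); it
#' carries the similarity weights used in neighbour reports.
#'
#' @param distances n x n geodesic distance matrix.
#' @param sigma_g positive kernel width, typically [compute_sigma_g()].
#' @return Object of class `fin_adjacency`: `matrix` (n x n) and `sigma_g`.
#' @export
kernel_adjacency <- function(distances, sigma_g) {
  D <- check_matrix(distances, "distances")
  sigma_g <- check_positive(sigma_g, "sigma_g")
  A <- exp(-(D^2) / sigma_g^2)
  structure(list(matrix = A, sigma_g = sigma_g), class = "fin_adjacency")
}

#' @export
print.fin_adjacency <- function(x, ...) {
  cat(sprintf("<fin_adjacency> %d x %d, sigma_G = %.4g\n",
              nrow(x$matrix), ncol(x$matrix), x$sigma_g))
  invisible(x)
}

# orientation convention shared by embedding and out-of-sample projection:
# flip each axis so its largest-magnitude coordinate is positive
fix_signs <- function(points, vectors) {
  for (j in seq_len(ncol(points))) {
    i <- which.max(abs(points[, j]))
    if (points[i, j] < 0) {
      points[, j] <- -points[, j]
      vectors[, j] <- -vectors[, j]
    }
  }
  list(points = points, vectors = vectors)
}

embedding_stress <- function(points, D) {
  d_emb <- as.matrix(dist(points))
  lo <- lower.tri(D)
  denom <- sum(D[lo]^2)
  if (denom == 0) return(0)
  sqrt(sum((d_emb[lo] - D[lo])^2) / denom)
}

#' Classical multidimensional scaling of geodesic distances
#'
#' Torgerson's classical MDS: double-centre the squared distances,
#' eigendecompose, and take the top `m` axes scaled by the root
#' eigenvalues. Geodesic matrices are generally not exactly Euclidean;
#' negative eigenvalues are clamped to zero (standard Isomap practice) and
#' the clamped share of total eigenvalue mass is reported as a diagnostic.
#' Optionally the configuration is refined by SMACOF stress majorisation,
#' initialised from the classical solution (deterministic). Axis
#' orientation is fixed by flipping each axis so its largest-magnitude
#' coordinate is positive.
#'
#' @param distances n x n symmetric distance matrix.
#' @param m embedding dimension (default 2, `m < n`).
#' @param refine if `TRUE`, run stress-majorisation refinement.
#' @param max_iter,tol SMACOF iteration controls (used when `refine`).
#' @param seed accepted for interface symmetry; the solver is deterministic.
#' @return Object of class `fin_embedding`: `points` (n x m, case-id
#'   rownames), `eigenvalues` (all n, non-increasing), `lambda` (the m
#'   clamped eigenvalues used), `vectors` (n x m eigenvectors, sign-fixed
#'   with the points), `stress` (normalised residual), `clamped_mass`,
#'   `m`, `refined`.
#' @examples
#' xy <- matrix(rnorm(40), 20, 2)
#' emb <- mds_embed(as.matrix(dist(xy)), m = 2)
#' emb$stress  # ~ 0: planar distances are exactly recoverable
#' @export
mds_embed <- function(distances, m = 2L, refine = FALSE,
                      max_iter = 200L, tol = 1e-10, seed = NULL) {
  D <- check_matrix(distances, "distances")
  n <- nrow(D)
  m <- check_count(m, "m")
  if (ncol(D) != n) stop("`distances` must be square", call. = FALSE)
  if (m >= n) stop("`m` must be smaller than the number of cases", call. = FALSE)

  D2 <- D^2
  # B = -1/2 J D^2 J via explicit row/column centring
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  ev <- eig$values
  pos <- pmax(ev, 0)
  clamped_mass <- if (sum(abs(ev)) > 0) sum(pmax(-ev, 0)) / sum(abs(ev)) else 0
  lambda <- pos[seq_len(m)]
  vectors <- eig$vectors[, seq_len(m), drop = FALSE]
  points <- vectors %*% diag(sqrt(lambda), m)

  refined <- FALSE
  if (refine) {
    points <- smacof_refine(points, D, max_iter = max_iter, tol = tol)
    refined <- TRUE
  }
  fx <- fix_signs(points, vectors)
  points <- fx$points; vectors <- fx$vectors
  rownames(points) <- rownames(D)
  colnames(points) <- sprintf("dim%d", seq_len(m))

  structure(list(points = points,
                 eigenvalues = ev,
                 lambda = lambda,
                 vectors = vectors,
                 stress = embedding_stress(points, D),
                 clamped_mass = clamped_mass,
                 m = m,
                 refined = refined),
            class = "fin_embedding")
}

# Guttman-transform stress majorisation from a fixed starting configuration
smacof_refine <- function(points, D, max_iter = 200L, tol = 1e-10) {
  n <- nrow(points)
  lo <- lower.tri(D)
  prev <- sum((as.matrix(dist(points))[lo] - D[lo])^2)
  for (it in seq_len(max_iter)) {
    d_emb <- as.matrix(dist(points))
    ratio <- ifelse(d_emb > 0, D / d_emb, 0)
    Bz <- -ratio
    diag(Bz) <- 0
    diag(Bz) <- -rowSums(Bz)
    points <- Bz %*% points / n
    cur <- sum((as.matrix(dist(points))[lo] - D[lo])^2)
    if (prev - cur < tol * max(prev, 1e-300)) break
    prev <- cur
  }
  points
}

#' @export
print.fin_embedding <- function(x, ...) {
  cat(sprintf(
    "<fin_embedding> %d cases in %d dims; stress %.3g; clamped mass %.3g%s\n",
    nrow(x$points), x$m, x$stress, x$clamped_mass,
    if (x$refined) " (refined)" else ""))
  invisible(x)
}
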