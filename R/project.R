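#' Fisher distances from an unseen case to all training cases
#'
#' The test case is first linked to its `k` Euclidean-nearest training
#' anchors by local Fisher segment distances; its geodesic distance to
#' every training case `j` is then the cheapest route through an anchor,
#' \deqn{d(test, j) = \min_i \big( seg(test, i) + D_{train}(i, j) \big),}
#' leaving all training structures untouched (the embedding is never
#' refitted for unseen cases). The test features must already be in the
#' training feature space — i.e. transformed by the *same* fitted PCA.
#'
#' @param model posterior model used for the training graph.
#' @param train_features training case x feature matrix (post-PCA space).
#' @param graph the training `fin_graph` (supplies defaults for `k`,
#'   `n_steps`, `ridge`).
#' @param train_geodesics training all-pairs geodesic matrix.
#' @param test_case single feature vector in the training feature space.
#' @param k number of anchor neighbours (default: the graph's `k`).
#' @param n_steps,ridge segment quadrature controls (default: the graph's).
#' @return numeric vector of length n_train with attributes `anchors`
#'   (indices of the anchor cases) and `segments` (their segment
#'   distances).
#' @export
test_to_train_distances <- function(model, train_features, graph,
                                    train_geodesics, test_case,
                                    k = graph$k, n_steps = graph$n_steps,
                                    ridge = graph$ridge) {
  train_features <- check_matrix(train_features, "train_features")
  test_case <- as.numeric(test_case)
  if (length(test_case) != ncol(train_features))
    stop("test case length does not match training feature count",
         call. = FALSE)
  n <- nrow(train_features)
  k <- check_count(k, "k")
  if (k > n) stop("`k` exceeds the number of training cases", call. = FALSE)
  D <- check_matrix(train_geodesics, "train_geodesics")

  eu <- row_dist_to(train_features, test_case)
  anchors <- order(eu)[seq_len(k)]          # ties broken by case index
  segs <- vapply(anchors, function(i) {
    segment_distance(model, test_case, train_features[i, ],
                     n_steps = n_steps, ridge = ridge)
  }, numeric(1))
  # min over anchors of segment + training geodesic
  routed <- sweep(D[anchors, , drop = FALSE], 1L, segs, "+")
  out <- apply(routed, 2L, min)
  names(out) <- rownames(train_features)
  attr(out, "anchors") <- anchors
  attr(out, "segments") <- segs
  out
}

# Gower out-of-sample coordinates against a classical MDS basis
gower_coords <- function(embedding, train_geodesics, test_distances) {
  dbar <- colMeans(train_geodesics^2)
  diff <- dbar - as.numeric(test_distances)^2
  y <- 0.5 * as.vector(crossprod(embedding$vectors, diff))
  lam <- embedding$lambda
  ifelse(lam > 0, y / sqrt(lam), 0)
}

#' Place an unseen case into a fixed latent embedding
#'
#' Solves for latent coordinates whose Euclidean distances to the training
#' coordinates best match the supplied geodesic distances. Against a
#' classical-MDS embedding the Gower out-of-sample formula
#' \deqn{y = \tfrac{1}{2}\, \Lambda^{-1/2} V^T (\bar{\delta} - \delta)}
#' (with \eqn{\delta} the squared test distances and \eqn{\bar\delta} the
#' column means of the squared training distances) is used; it is exact on
#' Euclidean configurations. If the embedding was stress-refined, the
#' coordinates are polished by direct least squares on the distance
#' residuals from the Gower start.
#'
#' @param embedding a `fin_embedding` from [mds_embed()].
#' @param train_geodesics the training geodesic matrix the embedding was
#'   built from.
#' @param test_distances length-n vector of geodesic distances from the new
#'   case to every training case ([test_to_train_distances()]).
#' @param id optional case identifier carried into the result.
#' @return Object of class `fin_projection`: `id`, `coords` (length m),
#'   `distances`, `anchors` (if present on `test_distances`), `residual`
#'   (RMS mismatch between embedded and supplied distances).
#' @export
place_in_embedding <- function(embedding, train_geodesics, test_distances,
                               id = NULL) {
  stopifnot(inherits(embedding, "fin_embedding"))
  D <- check_matrix(train_geodesics, "train_geodesics")
  n <- nrow(embedding$points)
  if (length(test_distances) != n)
    stop("`test_distances` must have one entry per training case",
         call. = FALSE)
  if (all(as.matrix(dist(embedding$points)) == 0) && n > 1L)
    stop("degenerate training embedding: all coordinates coincide",
         call. = FALSE)

  y <- gower_coords(embedding, D, test_distances)
  if (embedding$refined) {
    X <- embedding$points
    d <- as.numeric(test_distances)
    obj <- function(z) sum((row_dist_to(X, z) - d)^2)
    y <- stats::optim(y, obj, method = "BFGS")$par
  }
  resid <- sqrt(mean((row_dist_to(embedding$points, y) -
                        as.numeric(test_distances))^2))
  structure(list(id = id,
                 coords = as.numeric(y),
                 distances = as.numeric(test_distances),
                 anchors = attr(test_distances, "anchors"),
                 residual = resid),
            class = "fin_projection")
}

#' @export
print.fin_projection <- function(x, ...) {
  cat(sprintf("<fin_projection> %s at (%s); residual %.4g\n",
              if (is.null(x$id)) "case" else x$id,
              paste(sprintf("%.3f", x$coords), collapse = ", "),
              x$residual))
  invisible(x)
}
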