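#' Fit a Fisher information network end to end
#'
#' Runs the full training pipeline: PCA with variance-retention selection,
#' MLP posterior training, Fisher-weighted k-NN graph construction,
#' all-pairs geodesics, the \eqn{\sigma_G} kernel adjacency (using the
#' MLP's *predicted* labels) and the classical MDS latent embedding.
#'
#' @param features raw training case x feature matrix.
#' @param labels integer class labels in `0:(C-1)`.
#' @param variance_threshold PCA retained-variance threshold (default 0.90).
#' @param standardise standardise features before PCA (default `FALSE`).
#' @param config an [mlp_config()]; if its seed is `NULL`, `seed` is used.
#' @param k graph neighbours per node (default 10).
#' @param n_steps segment quadrature resolution (default 10).
#' @param ridge metric ridge for graph edges (default 1e-8).
#' @param m latent dimension (default 2).
#' @param refine stress-majorisation refinement of the embedding.
#' @param seed master seed for all stochastic stages.
#' @return Object of class `fin_model` bundling every artifact: `pca`,
#'   `scores`, `mlp`, `predicted`, `labels`, `graph`, `geodesics`,
#'   `sigma_g`, `adjacency`, `embedding` and the call parameters.
#' @seealso [fin_project()], [fin_neighbours()]
#' @export
fin_fit <- function(features, labels, variance_threshold = 0.9,
                    standardise = FALSE, config = mlp_config(),
                    k = 10L, n_steps = 10L, ridge = 1e-8,
                    m = 2L, refine = FALSE, seed = NULL) {
  features <- check_matrix(features, "features")
  if (is.null(config$seed)) config$seed <- seed

  pca <- fit_pca(features, variance_threshold, standardise = standardise)
  scores <- apply_pca(pca, features)
  mlp <- train_mlp(scores, labels, config)
  predicted <- predict_labels(mlp, scores)
  graph <- build_graph(scores, mlp, k = k, n_steps = n_steps, ridge = ridge)
  geodesics <- all_pairs_geodesic(graph)
  sigma_g <- compute_sigma_g(geodesics, predicted)
  adjacency <- kernel_adjacency(geodesics, sigma_g)
  embedding <- mds_embed(geodesics, m = m, refine = refine, seed = seed)

  structure(list(pca = pca, scores = scores, mlp = mlp,
                 predicted = predicted, labels = as.integer(labels),
                 graph = graph, geodesics = geodesics,
                 sigma_g = sigma_g, adjacency = adjacency,
                 embedding = embedding,
                 params = list(variance_threshold = variance_threshold,
                               standardise = standardise, k = k,
                               n_steps = n_steps, ridge = ridge, m = m,
                               refine = refine, seed = seed)),
            class = "fin_model")
}

#' @export
print.fin_model <- function(x, ...) {
  cat(sprintf(
    "<fin_model> %d training cases; %d -> %d PCA dims; sigma_G = %.4g\n",
    nrow(x$scores), nrow(x$pca$rotation), x$pca$k, x$sigma_g))
  cat(sprintf("  training accuracy %.1f%%; embedding stress %.3g\n",
              100 * mean(x$predicted == x$labels), x$embedding$stress))
  invisible(x)
}

#' Project unseen cases into a fitted network
#'
#' Applies the training PCA to the new cases (never refitting), computes
#' their Fisher geodesic distances to all training cases through the anchor
#' mechanism of [test_to_train_distances()], and places each one in the
#' fixed latent embedding with [place_in_embedding()]. Cases are projected
#' independently — no test-test edges — so the training structure is
#' untouched.
#'
#' @param fit a `fin_model` from [fin_fit()].
#' @param features raw new-case x feature matrix (original feature space).
#' @return Object of class `fin_projection_set`: `projections` (list of
#'   `fin_projection`), `coords` (matrix), `distances` (cases x n_train),
#'   `predicted` labels for the new cases.
#' @export
fin_project <- function(fit, features) {
  stopifnot(inherits(fit, "fin_model"))
  features <- check_matrix(features, "features")
  scores <- apply_pca(fit$pca, features)
  ids <- rownames(features)
  if (is.null(ids)) ids <- sprintf("test_%04d", seq_len(nrow(features)))
  projections <- lapply(seq_len(nrow(scores)), function(i) {
    d <- test_to_train_distances(fit$mlp, fit$scores, fit$graph,
                                 fit$geodesics, scores[i, ])
    place_in_embedding(fit$embedding, fit$geodesics, d, id = ids[i])
  })
  coords <- do.call(rbind, lapply(projections, function(p) p$coords))
  rownames(coords) <- ids
  colnames(coords) <- colnames(fit$embedding$points)
  distances <- do.call(rbind, lapply(projections, function(p) p$distances))
  dimnames(distances) <- list(ids, rownames(fit$embedding$points))
  structure(list(projections = projections, coords = coords,
                 distances = distances,
                 predicted = predict_labels(fit$mlp, scores)),
            class = "fin_projection_set")
}

#' @export
print.fin_projection_set <- function(x, ...) {
  cat(sprintf("<fin_projection_set> %d cases projected; mean residual %.4g\n",
              nrow(x$coords),
              mean(vapply(x$projections, `[[`, numeric(1), "residual"))))
  invisible(x)
}

#' Neighbour report for a training or projected case
#'
#' Convenience wrapper around [nearest_neighbours()]: for a training case id
#' the query's row of the geodesic matrix is used (the query excluded from
#' its own list); for a `fin_projection` its projected geodesic distances
#' are used. Retrieval always happens on the distance structure, not on the
#' 2-D plot coordinates.
#'
#' @param fit a `fin_model`.
#' @param query a training case id (character) or a `fin_projection`.
#' @param k neighbours to return (default 10).
#' @param metadata optional data.frame with `case_id` for pass-through.
#' @return a `fin_neighbours` report.
#' @export
fin_neighbours <- function(fit, query, k = 10L, metadata = NULL) {
  stopifnot(inherits(fit, "fin_model"))
  ids <- rownames(fit$geodesics)
  if (inherits(query, "fin_projection")) {
    d <- query$distances
    names(d) <- ids
    qid <- query$id
    exclude <- NULL
  } else {
    qid <- as.character(query)
    if (!qid %in% ids) stop("unknown training case id: ", qid, call. = FALSE)
    d <- fit$geodesics[qid, ]
    exclude <- qid
  }
  nearest_neighbours(d, k, sigma_g = fit$sigma_g,
                     predicted_labels = fit$predicted,
                     true_labels = fit$labels,
                     metadata = metadata, query_id = qid, exclude = exclude)
}

#' Export the latent embedding as delimited text
#'
#' One row per training case: case id, latent coordinates, predicted label,
#' true label.
#'
#' @param fit a `fin_model`.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
write_embedding <- function(fit, file) {
  stopifnot(inherits(fit, "fin_model"))
  df <- data.frame(case_id = rownames(fit$embedding$points),
                   fit$embedding$points,
                   predicted_label = fit$predicted,
                   true_label = fit$labels)
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export a distance matrix as delimited text
#'
#' @param distances square matrix (e.g. from [all_pairs_geodesic()]).
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
write_distance_matrix <- function(distances, file) {
  D <- as.matrix(distances)
  write.csv(data.frame(case_id = rownames(D), D, check.names = FALSE),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
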