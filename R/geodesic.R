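# k-nearest-neighbour candidate lists in Euclidean space, ties by index
knn_pairs <- function(features, k) {
  n <- nrow(features)
  D <- as.matrix(dist(features))
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])            # stable: ties broken by case index
    nb <- seq_len(n)[-i][ord][seq_len(k)]
    pairs[[i]] <- cbind(pmin(i, nb), pmax(i, nb))
  }
  unique(do.call(rbind, pairs))
}

graph_components <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges[, 1:2, drop = FALSE]))
  igraph::components(g)$membership
}

#' Build the Fisher-weighted nearest-neighbour graph
#'
#' Connects each case to its `k` nearest neighbours (neighbourhoods selected
#' by Euclidean distance in the input feature space, the standard
#' Isomap-style pre-screen, which keeps Fisher evaluations O(nk)), weights
#' every edge by the local Fisher segment distance
#' ([segment_distance()]), and symmetrises the union. If the k-NN graph is
#' disconnected, components are bridged by the cheapest inter-component
#' Fisher edge (candidates ranked by Euclidean distance); every added edge
#' is recorded in `$augmented`.
#'
#' @param features training case x feature matrix.
#' @param model posterior model inducing the metric.
#' @param k neighbours per node (`0 < k < n`); default 10.
#' @param n_steps quadrature resolution for segment distances (default 10).
#' @param ridge metric ridge (default 1e-8) so that duplicate-free graphs
#'   get strictly positive weights even where posteriors are flat.
#' @param bridge_candidates maximum number of Euclidean-closest cross pairs
#'   scored with the Fisher metric when bridging two components.
#' @return Object of class `fin_graph`: `n`, `edges` (data.frame `i, j,
#'   weight` with `i < j`), `k`, `n_steps`, `ridge`, `symmetrised`,
#'   `augmented` (data.frame of bridging edges, 0 rows if none) and the
#'   case `ids`.
#' @seealso [all_pairs_geodesic()]
#' @export
build_graph <- function(features, model, k = 10L, n_steps = 10L,
                        ridge = 1e-8, bridge_candidates = 200L) {
  features <- check_matrix(features, "features")
  n <- nrow(features)
  k <- check_count(k, "k")
  if (n < 2L) stop("need at least 2 cases", call. = FALSE)
  if (k >= n) stop("`k` must be smaller than the number of cases", call. = FALSE)

  pairs <- knn_pairs(features, k)
  w <- vapply(seq_len(nrow(pairs)), function(e) {
    segment_distance(model, features[pairs[e, 1L], ], features[pairs[e, 2L], ],
                     n_steps = n_steps, ridge = ridge)
  }, numeric(1))
  edges <- data.frame(i = pairs[, 1L], j = pairs[, 2L], weight = w)

  augmented <- edges[0, ]
  memb <- graph_components(n, pairs)
  while (max(memb) > 1L) {
    # cheapest Fisher edge between component 1's block and the rest,
    # scored over the Euclidean-closest candidate cross pairs
    in1 <- which(memb == memb[1L])
    out1 <- which(memb != memb[1L])
    cross <- expand.grid(i = in1, j = out1)
    eu <- sqrt(rowSums((features[cross$i, , drop = FALSE] -
                          features[cross$j, , drop = FALSE])^2))
    keep <- order(eu)[seq_len(min(nrow(cross), bridge_candidates))]
    cand <- cross[keep, , drop = FALSE]
    cw <- vapply(seq_len(nrow(cand)), function(e) {
      segment_distance(model, features[cand$i[e], ], features[cand$j[e], ],
                       n_steps = n_steps, ridge = ridge)
    }, numeric(1))
    best <- which.min(cw)
    add <- data.frame(i = min(cand$i[best], cand$j[best]),
                      j = max(cand$i[best], cand$j[best]),
                      weight = cw[best])
    edges <- rbind(edges, add)
    augmented <- rbind(augmented, add)
    memb <- graph_components(n, as.matrix(edges[, 1:2]))
  }

  structure(list(n = n, edges = edges, k = k, n_steps = n_steps,
                 ridge = ridge, symmetrised = TRUE, augmented = augmented,
                 ids = rownames(features)),
            class = "fin_graph")
}

#' @export
print.fin_graph <- function(x, ...) {
  cat(sprintf("<fin_graph> %d nodes, %d edges (k = %d, %d bridging)\n",
              x$n, nrow(x$edges), x$k, nrow(x$augmented)))
  invisible(x)
}

graph_weight_matrix <- function(graph) {
  W <- matrix(Inf, graph$n, graph$n)
  diag(W) <- 0
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    w <- min(W[e$i[r], e$j[r]], e$weight[r])   # keep cheapest parallel edge
    W[e$i[r], e$j[r]] <- w
    W[e$j[r], e$i[r]] <- w
  }
  W
}

#' All-pairs geodesic distances over the neighbour graph
#'
#' Shortest-path distances between every pair of nodes, approximating
#' geodesic distances under the Fisher metric by chaining local segment
#' lengths. The reference algorithm is Floyd-Warshall (vectorised over the
#' intermediate node); `method = "dijkstra"` runs repeated single-source
#' Dijkstra through igraph instead, which is faster for large n and returns
#' identical distances.
#'
#' @param graph a connected `fin_graph`.
#' @param method `"floyd"` (default) or `"dijkstra"`.
#' @return `n x n` symmetric matrix of class `fin_geodesic` (zero diagonal,
#'   non-negative, metric), with case ids as dimnames.
#' @export
all_pairs_geodesic <- function(graph, method = c("floyd", "dijkstra")) {
  stopifnot(inherits(graph, "fin_graph"))
  method <- match.arg(method)
  memb <- graph_components(graph$n, as.matrix(graph$edges[, 1:2]))
  if (max(memb) > 1L)
    stop("graph is disconnected; build_graph() performs augmentation",
         call. = FALSE)
  if (method == "floyd") {
    D <- graph_weight_matrix(graph)
    n <- graph$n
    for (k in seq_len(n)) {
      D <- pmin(D, outer(D[, k], D[k, ], "+"))
    }
  } else {
    g <- igraph::graph_from_data_frame(
      graph$edges[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = seq_len(graph$n)))
    D <- igraph::distances(g, weights = graph$edges$weight,
                           algorithm = "dijkstra")
    ord <- order(as.integer(rownames(D)))
    D <- D[ord, ord]
  }
  dimnames(D) <- list(graph$ids, graph$ids)
  class(D) <- c("fin_geodesic", class(D))
  D
}
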