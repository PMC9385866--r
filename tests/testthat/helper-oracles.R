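# Independent oracles and fixtures shared across the suite.

# Rigid (rotation/reflection + translation) alignment of X onto Y by
# orthogonal Procrustes; used to compare embeddings up to isometry.
align_rigid <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  s <- svd(crossprod(Xc, Yc))
  sweep(Xc %*% (s$u %*% t(s$v)), 2L, cy, "+")
}

align_rmse <- function(X, Y) sqrt(mean((align_rigid(X, Y) - Y)^2))

# Brute-force all-pairs shortest paths by exhaustive simple-path DFS
# (independent of Floyd-Warshall); W has Inf where there is no edge.
bf_all_pairs <- function(W) {
  n <- nrow(W)
  D <- matrix(0, n, n)
  for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
    best <- Inf
    dfs <- function(v, visited, len) {
      if (len >= best) return(invisible())
      if (v == t) { best <<- len; return(invisible()) }
      for (u in which(is.finite(W[v, ]))) if (!visited[u]) {
        visited[u] <- TRUE
        dfs(u, visited, len + W[v, u])
        visited[u] <- FALSE
      }
    }
    visited <- rep(FALSE, n); visited[s] <- TRUE
    dfs(s, visited, 0)
    D[s, t] <- D[t, s] <- best
  }
  D
}

# random connected undirected weighted graph as a weight matrix
random_connected_graph <- function(n, p = 0.35) {
  W <- matrix(Inf, n, n); diag(W) <- 0
  for (i in seq_len(n - 1L)) {               # random spanning tree
    j <- sample.int(i, 1L)
    W[i + 1L, j] <- W[j, i + 1L] <- runif(1, 0.1, 2)
  }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    if (!is.finite(W[i, j]) && runif(1) < p)
      W[i, j] <- W[j, i] <- runif(1, 0.1, 2)
  W
}

# wrap a weight matrix as the fin_graph structure all_pairs_geodesic expects
graph_from_weights <- function(W, k = 1L) {
  n <- nrow(W)
  idx <- which(upper.tri(W) & is.finite(W), arr.ind = TRUE)
  structure(list(n = n,
                 edges = data.frame(i = idx[, 1L], j = idx[, 2L],
                                    weight = W[idx]),
                 k = k, n_steps = 1L, ridge = 0, symmetrised = TRUE,
                 augmented = data.frame(i = integer(), j = integer(),
                                        weight = numeric()),
                 ids = sprintf("case_%04d", seq_len(n))),
            class = "fin_graph")
}

# oracle posterior model with identity Fisher metric: segment distances
# reduce to Euclidean lengths. Registers its quadform method on the
# package's generic.
euclid_oracle <- function(d) structure(list(d = d), class = "fin_euclid_oracle")
registerS3method("fi_quadform", "fin_euclid_oracle",
                 function(model, points, delta, ...) {
                   rep(sum(delta^2), nrow(as.matrix(points)))
                 },
                 envir = asNamespace("finet"))

# central finite differences of log posteriors: rows are grad log p(c|x)
fd_grad_log <- function(model, x, h = 1e-5) {
  d <- length(x)
  out <- sapply(seq_len(d), function(j) {
    e <- numeric(d); e[j] <- h
    (log(predict_posteriors(model, x + e)) -
       log(predict_posteriors(model, x - e))) / (2 * h)
  })
  matrix(out, ncol = d)
}

# finite-difference Hessian of f at x (central, O(h^2))
fd_hessian <- function(f, x, h = 1e-3) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq(i, d)) {
    ei <- numeric(d); ei[i] <- h
    ej <- numeric(d); ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
      (4 * h^2)
  }
  H
}

# negative posterior-weighted finite-difference Hessian of the log posteriors
fd_neg_expected_hessian <- function(model, x, h = 1e-3) {
  p <- as.vector(predict_posteriors(model, x))
  C <- length(p)
  H <- 0
  for (c in seq_len(C)) {
    f <- function(z) log(predict_posteriors(model, z)[1, c])
    H <- H - p[c] * fd_hessian(f, x, h)
  }
  H
}

# small trained MLP fixture reused by fisher/posterior tests
fixture_mlp <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cases(240, n_classes = 3, n_features = 4,
                            separation = 5, seed = 401)
      cache <<- list(
        sim = sim,
        model = train_mlp(sim$features, sim$labels,
                          mlp_config(max_epochs = 60, seed = 401)))
    }
    cache
  }
})
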