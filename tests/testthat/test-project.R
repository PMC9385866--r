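# planar fixture with exactly-Euclidean geodesics: identity metric,
# complete graph over random 2-D points
planar_fixture <- function(n = 20, seed = 331) {
  set.seed(seed)
  xy <- matrix(rnorm(2 * n), n, 2)
  rownames(xy) <- sprintf("case_%04d", seq_len(n))
  g <- build_graph(xy, euclid_oracle(2), k = n - 1, ridge = 0)
  D <- all_pairs_geodesic(g)
  list(xy = xy, graph = g, D = D, emb = mds_embed(D, m = 2))
}

test_that("a test case coincident with a training case inherits its row", {
  fx <- planar_fixture()
  t0 <- 7L
  d <- test_to_train_distances(euclid_oracle(2), fx$xy, fx$graph, fx$D,
                               fx$xy[t0, ], k = 5)
  expect_equal(as.numeric(d[t0]), 0, tolerance = 1e-12)
  expect_equal(as.numeric(d), unname(fx$D[t0, ]), tolerance = 1e-12)
})

test_that("identity metric distances reduce to Euclidean anchor routing", {
  fx <- planar_fixture()
  set.seed(332)
  test <- rnorm(2)
  k <- 6
  d <- test_to_train_distances(euclid_oracle(2), fx$xy, fx$graph, fx$D,
                               test, k = k)
  # direct oracle: min over the k Euclidean-nearest anchors of
  # |test - anchor| + D(anchor, j)
  eu <- sqrt(colSums((t(fx$xy) - test)^2))
  anchors <- order(eu)[1:k]
  oracle <- sapply(seq_len(nrow(fx$xy)), function(j)
    min(eu[anchors] + fx$D[anchors, j]))
  expect_equal(as.numeric(d), oracle, tolerance = 1e-12)
  # definition of the minimum: d(test, j) <= seg_i + D(i, j) for all anchors
  segs <- attr(d, "segments")
  for (a in seq_along(anchors))
    expect_true(all(d <= segs[a] + fx$D[anchors[a], ] + 1e-12))
})

test_that("training rows project onto their own coordinates", {
  fx <- planar_fixture()
  for (t0 in c(1L, 11L)) {
    pr <- place_in_embedding(fx$emb, fx$D, fx$D[t0, ])
    expect_equal(pr$coords, unname(fx$emb$points[t0, ]), tolerance = 1e-6)
    expect_gte(pr$residual, 0)
  }
})

test_that("a held-out planar point is recovered exactly", {
  set.seed(333)
  xy <- matrix(rnorm(40), 20, 2)
  hold <- 20L
  train <- xy[-hold, ]
  D <- as.matrix(dist(train))
  emb <- mds_embed(D, m = 2)
  d_test <- sqrt(colSums((t(train) - xy[hold, ])^2))
  pr <- place_in_embedding(emb, D, d_test)
  # align (training embedding + projection) back onto the source plane
  aligned <- align_rigid(rbind(emb$points, pr$coords), rbind(train, xy[hold, ]))
  expect_lt(sqrt(sum((aligned[20, ] - xy[hold, ])^2)), 1e-6)
  expect_lt(pr$residual, 1e-8)
})

test_that("equidistant query of a simplex projects to the centroid", {
  D <- matrix(1, 4, 4); diag(D) <- 0   # regular tetrahedron, unit edges
  emb <- mds_embed(D, m = 3)
  pr <- place_in_embedding(emb, D, rep(0.9, 4))
  expect_lt(max(abs(pr$coords - colMeans(emb$points))), 1e-10)
})

test_that("projection leaves every training artifact untouched", {
  fx <- planar_fixture()
  snap_D <- unclass(fx$D)
  snap_pts <- fx$emb$points
  d <- test_to_train_distances(euclid_oracle(2), fx$xy, fx$graph, fx$D,
                               c(0.3, -0.2), k = 4)
  invisible(place_in_embedding(fx$emb, fx$D, d))
  expect_identical(unclass(fx$D), snap_D)
  expect_identical(fx$emb$points, snap_pts)
})

test_that("routing all training cases through the test pathway reproduces
           the embedding on exact-Euclidean fixtures", {
  fx <- planar_fixture(n = 15)
  coords <- t(sapply(seq_len(15), function(i) {
    d <- test_to_train_distances(euclid_oracle(2), fx$xy, fx$graph, fx$D,
                                 fx$xy[i, ], k = 5)
    place_in_embedding(fx$emb, fx$D, d)$coords
  }))
  expect_lt(sqrt(mean((coords - fx$emb$points)^2)), 1e-6)
})

test_that("projected synthetic test cases land among their own class", {
  sim <- simulate_cases(360, n_classes = 5, n_features = 10,
                        separation = 6, seed = 334)
  tr <- 1:300; te <- 301:360
  fit <- fin_fit(sim$features[tr, ], sim$labels[tr], seed = 334)
  proj <- fin_project(fit, sim$features[te, , drop = FALSE])
  ok <- vapply(seq_along(te), function(i) {
    nb <- fin_neighbours(fit, proj$projections[[i]], k = 10)
    frac <- mean(nb$neighbours$true_label == sim$labels[te[i]])
    frac > 0.5
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("degenerate and mismatched inputs are rejected", {
  fx <- planar_fixture(n = 8)
  expect_error(test_to_train_distances(euclid_oracle(2), fx$xy, fx$graph,
                                       fx$D, c(1, 2, 3)), "length")
  degenerate <- fx$emb
  degenerate$points[] <- 0
  expect_error(place_in_embedding(degenerate, fx$D, rep(1, 8)), "degenerate")
  expect_error(place_in_embedding(fx$emb, fx$D, rep(1, 5)), "per training")
})
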