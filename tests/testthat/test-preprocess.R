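make_subspace_data <- function(n, seed = 101) {
  # points exactly on a 3-D linear subspace embedded in 10-D
  set.seed(seed)
  basis <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
  # balanced component variances so no 2-D cut reaches 90% of the variance
  scores <- matrix(rnorm(n * 3, sd = c(1.5, 1.2, 1)), n, 3, byrow = TRUE)
  list(x = scores %*% t(basis), basis = basis)
}

test_that("variance threshold selects the forced rank of subspace data", {
  x <- make_subspace_data(100)$x
  p <- fit_pca(x, 0.90)
  expect_identical(p$k, 3L)
  expect_gte(p$cum_explained, 0.999)  # subspace: 3 PCs carry everything
})

test_that("threshold 1.0 on full-rank n > d data keeps all d components", {
  set.seed(102)
  x <- matrix(rnorm(200), 40, 5)
  p <- fit_pca(x, 1.0)
  expect_identical(p$k, 5L)
})

test_that("known population eigenvalues land at the oracle component count", {
  # eigenvalues (10, 5, 1, 1, 1): cumulative ratios 10/18, 15/18 = 0.833...
  # so threshold 0.80 must select k = 2
  set.seed(103)
  x <- matrix(rnorm(10000 * 5), 10000, 5) %*% diag(sqrt(c(10, 5, 1, 1, 1)))
  p <- fit_pca(x, 0.80)
  expect_identical(p$k, 2L)
  expect_equal(sum(p$explained), 15 / 18, tolerance = 0.02)
})

test_that("component columns are orthonormal and ratios well-formed", {
  set.seed(104)
  x <- matrix(rnorm(600), 60, 10)
  p <- fit_pca(x, 0.9)
  gram <- crossprod(p$rotation)
  expect_lt(max(abs(gram - diag(p$k))), 1e-8)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_true(all(p$explained >= 0 & p$explained <= 1))
  csum <- cumsum(p$all_ratios)
  expect_gte(csum[p$k], 0.9 - 1e-12)
  expect_lt(csum[p$k - 1], 0.9)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(p$k))
    expect_gt(p$rotation[which.max(abs(p$rotation[, j])), j], 0)
})

test_that("apply/invert round trips: lossless at full rank, mean maps to 0", {
  set.seed(105)
  x <- matrix(rnorm(200), 40, 5)
  p <- fit_pca(x, 1.0)
  expect_lt(max(abs(invert_pca(p, apply_pca(p, x)) - x)), 1e-8)
  z <- apply_pca(p, matrix(p$mean, 1))
  expect_lt(max(abs(z)), 1e-10)
})

test_that("held-out rows from the fitted subspace reconstruct exactly", {
  d <- make_subspace_data(100)
  p <- fit_pca(d$x, 0.90)
  # membership oracle: rows built from the SAME basis as the training fit
  set.seed(107)
  new_scores <- matrix(rnorm(20 * 3), 20, 3)
  new_x <- new_scores %*% t(d$basis)
  rec <- invert_pca(p, apply_pca(p, new_x))
  expect_lt(max(abs(rec - new_x)), 1e-8)
})

test_that("projection then inverse-projection is idempotent on the subspace", {
  set.seed(108)
  x <- matrix(rnorm(300), 60, 5)
  p <- fit_pca(x, 0.8)
  once <- invert_pca(p, apply_pca(p, x))
  twice <- invert_pca(p, apply_pca(p, once))
  expect_lt(max(abs(once - twice)), 1e-10)
})

test_that("transform is immutable under application to test data", {
  set.seed(109)
  x <- matrix(rnorm(200), 40, 5)
  p <- fit_pca(x, 0.9)
  snapshot <- unclass(p)
  invisible(apply_pca(p, matrix(rnorm(25), 5, 5)))
  expect_identical(unclass(p), snapshot)
})

test_that("degenerate inputs and mismatches are rejected", {
  expect_error(fit_pca(matrix(1, 10, 3), 0.9), "variance")
  expect_error(fit_pca(matrix(rnorm(10), 1, 10), 0.9), "2 cases")
  expect_error(fit_pca(matrix(rnorm(40), 10, 4), 0), "threshold")
  p <- fit_pca(matrix(rnorm(40), 10, 4), 0.9)
  expect_error(apply_pca(p, matrix(rnorm(30), 10, 3)), "mismatch")
})

test_that("optional standardisation rescales before rotation", {
  set.seed(110)
  x <- cbind(rnorm(50, sd = 100), rnorm(50, sd = 1), rnorm(50, sd = 1))
  p_cov <- fit_pca(x, 0.9)
  p_std <- fit_pca(x, 0.99, standardise = TRUE)
  # covariance PCA is dominated by the high-variance column
  expect_gt(abs(p_cov$rotation[1, 1]), 0.99)
  expect_lt(p_cov$k, 3L)
  # standardised PCA treats columns comparably
  expect_identical(length(p_std$scale), 3L)
  expect_lt(max(abs(apply(apply_pca(p_std, x), 2, sd) - 1)), 0.5)
})

test_that("transform serialization round-trips", {
  set.seed(111)
  p <- fit_pca(matrix(rnorm(200), 40, 5), 0.9)
  f <- tempfile(fileext = ".json")
  fin_save(p, f)
  q <- fin_load(f)
  expect_s3_class(q, "fin_pca")
  expect_equal(q$rotation, p$rotation, tolerance = 1e-15)
  expect_equal(q$mean, unname(p$mean), tolerance = 1e-15)
  expect_identical(q$k, p$k)
})
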