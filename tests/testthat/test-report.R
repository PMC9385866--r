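test_that("a duplicate case ranks first at distance zero", {
  d <- c(case_0001 = 0.5, case_0002 = 0, case_0003 = 1.2)
  rep <- nearest_neighbours(d, k = 2)
  expect_identical(rep$neighbours$case_id[1], "case_0002")
  expect_identical(rep$neighbours$distance[1], 0)
})

test_that("k = n returns every case, fully sorted", {
  set.seed(341)
  d <- runif(8)
  names(d) <- sprintf("case_%04d", 1:8)
  rep <- nearest_neighbours(d, k = 8)
  expect_identical(nrow(rep$neighbours), 8L)
  expect_true(!is.unsorted(rep$neighbours$distance))
})

test_that("ordering equals a brute-force full sort, ties broken by id", {
  set.seed(342)
  for (r in 1:5) {
    d <- sample(round(runif(12), 1))   # coarse values force ties
    names(d) <- sprintf("case_%04d", sample(12))
    rep <- nearest_neighbours(d, k = 12)
    oracle <- names(d)[order(d, names(d))]
    expect_identical(rep$neighbours$case_id, oracle)
  }
})

test_that("query exclusion, similarity law and majority summary hold", {
  d <- c(a = 0, b = 1, c = 2, e = 3)
  rep <- nearest_neighbours(d, k = 3, sigma_g = 2,
                            true_labels = c("m", "m", "m", "x"),
                            query_id = "a", exclude = "a")
  expect_false("a" %in% rep$neighbours$case_id)
  expect_equal(rep$neighbours$similarity,
               exp(-rep$neighbours$distance^2 / 4), tolerance = 1e-15)
  expect_identical(rep$majority$label, "m")
  expect_equal(sum(rep$majority$fractions), 1)
  expect_error(nearest_neighbours(d, k = 9), "exceeds")
})

test_that("metadata is passed through verbatim and never reorders", {
  d <- c(x1 = 3, x2 = 1, x3 = 2)
  meta <- data.frame(case_id = c("x3", "x1", "x2"),
                     birads = c(4, 2, 5),
                     note = c("a", "b", "c"))
  base <- nearest_neighbours(d, k = 3)
  with_meta <- nearest_neighbours(d, k = 3, metadata = meta)
  expect_identical(with_meta$neighbours$case_id, base$neighbours$case_id)
  expect_identical(with_meta$neighbours$birads, c(5, 4, 2))
  expect_error(nearest_neighbours(d, k = 2, metadata = data.frame(z = 1)),
               "case_id")
})

test_that("misclassification table matches hand and brute-force tallies", {
  perfect <- misclassification_table(c(0, 1, 2), c(0, 1, 2))
  expect_equal(perfect$confusion, diag(3), ignore_attr = TRUE)
  expect_identical(perfect$accuracy, 1)

  m <- misclassification_table(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  expect_equal(m$confusion["a", ], c(a = 0.5, b = 0.5))
  expect_equal(m$confusion["b", ], c(a = 0, b = 1))
  expect_identical(m$accuracy, 0.75)

  set.seed(343)
  true <- sample(0:3, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, true, sample(0:3, 200, replace = TRUE))
  mt <- misclassification_table(true, pred)
  # brute-force counting oracle
  for (a in 0:3) for (p in 0:3) {
    expect_identical(mt$counts[as.character(a), as.character(p)],
                     as.numeric(sum(true == a & pred == p)))
  }
  expect_lt(max(abs(rowSums(mt$confusion) - 1)), 1e-12)
  expect_identical(mt$accuracy, mean(true == pred))

  expect_error(misclassification_table(c("a", "a"), c("b", "b")), "disjoint")
  expect_error(misclassification_table(1:3, 1:4), "length")
})

test_that("latent plots are written and validate highlight ids", {
  set.seed(344)
  xy <- matrix(rnorm(60), 30, 2)
  rownames(xy) <- sprintf("case_%04d", 1:30)
  emb <- mds_embed(as.matrix(dist(xy)), m = 2)
  labs <- sample(0:4, 30, replace = TRUE)
  f <- tempfile(fileext = ".png")
  render_latent_plot(emb, labs, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  # both colour modes draw; projections overlay; pdf flavour works
  f2 <- tempfile(fileext = ".pdf")
  render_latent_plot(emb, labs, projections = matrix(rnorm(6), 3, 2),
                     colour_by = "predicted", highlight = "case_0003",
                     file = f2)
  expect_true(file.exists(f2) && file.size(f2) > 0)
  expect_error(render_latent_plot(emb, labs, highlight = "nope", file = f),
               "nope")
  expect_error(render_latent_plot(emb, labs[1:4], file = f), "labels")
})

test_that("report generation is read-only over its inputs", {
  d <- c(a = 1, b = 2, c = 3)
  snap <- d
  invisible(nearest_neighbours(d, k = 2, sigma_g = 1))
  expect_identical(d, snap)
})

test_that("neighbour reports export as delimited text", {
  d <- c(a = 1, b = 2, c = 3)
  rep <- nearest_neighbours(d, k = 3, sigma_g = 1.5)
  f <- tempfile(fileext = ".csv")
  write_neighbours(rep, f)
  back <- read.csv(f)
  expect_identical(back$case_id, c("a", "b", "c"))
  expect_equal(back$similarity, rep$neighbours$similarity, tolerance = 1e-6)
})
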