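test_that("MLP separates well-separated blobs to near the centroid oracle", {
  sim <- simulate_cases(500, n_classes = 5, n_features = 10,
                        separation = 8, seed = 201)
  # nearest-centroid oracle bound on the same data
  pred_nc <- apply(sim$features, 1,
                   function(r) which.min(colSums((t(sim$means) - r)^2)) - 1L)
  expect_gte(mean(pred_nc == sim$labels), 0.99)

  m <- train_mlp(sim$features, sim$labels, mlp_config(seed = 201))
  expect_gte(mean(predict_labels(m, sim$features) == sim$labels), 0.95)

  # training loss trends down (up to mini-batch noise)
  expect_lt(mean(tail(m$loss, 10)), mean(head(m$loss, 10)))
})

test_that("posteriors are row-stochastic everywhere, including off-data", {
  fx <- fixture_mlp()
  pts <- rbind(fx$sim$features[1:10, ],
               matrix(rnorm(40, sd = 10), 10, 4))
  p <- predict_posteriors(fx$model, pts)
  expect_true(all(p >= 0))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-10)
})

test_that("duplicate inputs give identical posterior rows", {
  fx <- fixture_mlp()
  x <- fx$sim$features[3, ]
  p <- predict_posteriors(fx$model, rbind(x, x))
  expect_identical(p[1, ], p[2, ])
})

test_that("zero-epoch training still yields a valid posterior model", {
  sim <- simulate_cases(50, n_classes = 3, n_features = 4, seed = 202)
  m0 <- train_mlp(sim$features, sim$labels,
                  mlp_config(max_epochs = 0, seed = 202))
  p <- predict_posteriors(m0, sim$features)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-10)
  expect_identical(length(m0$loss), 0L)
})

test_that("linear softmax closed forms hold", {
  # all-zero weights: uniform posteriors
  m <- linear_softmax_model(matrix(0, 4, 3))
  expect_equal(as.vector(predict_posteriors(m, rnorm(3))), rep(0.25, 4))
  # 1-D logistic at the boundary
  m1 <- linear_softmax_model(matrix(c(0, 1), 2, 1))
  expect_equal(as.vector(predict_posteriors(m1, 0)), c(0.5, 0.5))
  # 2-class gradient: grad log p1 = (1 - p1)(w1 - w0), vs closed form and FD
  set.seed(203)
  W <- matrix(rnorm(6), 2, 3)
  m2 <- linear_softmax_model(W, bias = rnorm(2))
  for (i in 1:5) {
    x <- rnorm(3)
    p1 <- predict_posteriors(m2, x)[1, 2]
    G <- grad_log_posteriors(m2, x)
    expect_equal(G[2, ], (1 - p1) * (W[2, ] - W[1, ]), tolerance = 1e-10)
    expect_equal(G, fd_grad_log(m2, x), tolerance = 1e-6)
  }
})

test_that("MLP analytic input-gradients match central finite differences", {
  fx <- fixture_mlp()
  set.seed(204)
  for (i in 1:20) {
    x <- rnorm(4, sd = 2)
    G <- grad_log_posteriors(fx$model, x)
    Gfd <- fd_grad_log(fx$model, x)
    expect_lt(max(abs(G - Gfd)) / max(abs(Gfd)), 1e-4)
  }
})

test_that("tanh hidden activation gradients are also exact", {
  sim <- simulate_cases(120, n_classes = 3, n_features = 4, seed = 205)
  m <- train_mlp(sim$features, sim$labels,
                 mlp_config(max_epochs = 20, hidden_activation = "tanh",
                            seed = 205))
  x <- rnorm(4)
  expect_lt(max(abs(grad_log_posteriors(m, x) - fd_grad_log(m, x))), 1e-5)
})

test_that("weight decay strictly shrinks weight norms at equal epochs/seed", {
  sim <- simulate_cases(200, n_classes = 3, n_features = 5,
                        separation = 6, seed = 206)
  norms <- sapply(c(0, 0.2), function(wd) {
    m <- train_mlp(sim$features, sim$labels,
                   mlp_config(weight_decay = wd, max_epochs = 80, seed = 206))
    sum(m$W1^2) + sum(m$W2^2)
  })
  expect_lt(norms[2], norms[1])
  # "mean" decay mode applies the raw (much stronger) coefficient
  m_mean <- train_mlp(sim$features, sim$labels,
                      mlp_config(weight_decay = 0.2, decay_mode = "mean",
                                 max_epochs = 80, seed = 206))
  expect_lt(sum(m_mean$W1^2) + sum(m_mean$W2^2), norms[2])
})

test_that("training is reproducible for a fixed seed", {
  sim <- simulate_cases(100, n_classes = 3, n_features = 4, seed = 207)
  cfg <- mlp_config(max_epochs = 15, seed = 207)
  m1 <- train_mlp(sim$features, sim$labels, cfg)
  m2 <- train_mlp(sim$features, sim$labels, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$loss, m2$loss)
})

test_that("training rejects degenerate inputs", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(train_mlp(x, rep(0L, 10), mlp_config()), "2 classes")
  xx <- x; xx[1, 1] <- NaN
  expect_error(train_mlp(xx, rep(0:1, 5), mlp_config()), "finite")
  m <- train_mlp(x, rep(0:1, 5), mlp_config(max_epochs = 2, seed = 1))
  expect_error(predict_posteriors(m, matrix(rnorm(30), 10, 3)), "4")
})

test_that("model serialization preserves predictions exactly", {
  fx <- fixture_mlp()
  f <- tempfile(fileext = ".json")
  fin_save(fx$model, f)
  m2 <- fin_load(f)
  expect_identical(predict_posteriors(m2, fx$sim$features),
                   predict_posteriors(fx$model, fx$sim$features))
})
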