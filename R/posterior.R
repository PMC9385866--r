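#' The posterior-model contract
#'
#' The Fisher information machinery is agnostic to the classifier: anything
#' that can report class posteriors \eqn{p(c|x)} and the input-gradients of
#' their logs can induce the metric. A posterior model is an S3 object
#' implementing four generics:
#'
#' * `predict_posteriors(model, features)`: `n x C` row-stochastic matrix;
#' * `grad_log_posteriors(model, x)`: `C x d` matrix with rows
#'   \eqn{\nabla_x \log p(c|x)};
#' * `n_classes(model)`, `n_inputs(model)`.
#'
#' The bundled implementations are [train_mlp()] (a one-hidden-layer softmax
#' MLP with analytic backpropagated input gradients) and
#' [linear_softmax_model()] (closed-form multinomial-logistic model, useful
#' as an analytically tractable oracle).
#'
#' @param model a posterior model object.
#' @param features numeric matrix of cases (rows) to score; a single case may
#'   be given as a vector.
#' @param x a single feature vector.
#' @param ... passed to methods.
#' @return See the contract description above.
#' @name posterior-contract
NULL

#' @rdname posterior-contract
#' @export
predict_posteriors <- function(model, features, ...) UseMethod("predict_posteriors")

#' @rdname posterior-contract
#' @export
grad_log_posteriors <- function(model, x, ...) UseMethod("grad_log_posteriors")

#' @rdname posterior-contract
#' @export
n_classes <- function(model) UseMethod("n_classes")

#' @rdname posterior-contract
#' @export
n_inputs <- function(model) UseMethod("n_inputs")

#' Fisher quadratic form along a fixed direction (internal extension point)
#'
#' Evaluates \eqn{q(x) = \Delta^T FI(x) \Delta = \sum_c p(c|x)
#' (g_c(x) \cdot \Delta)^2} at each row of `points`. The default method loops
#' over [grad_log_posteriors()]; models with cheap batched Jacobian-vector
#' products (the bundled MLP, linear softmax) override it for speed. Ridge is
#' NOT included here; [segment_distance()] adds it.
#'
#' @param model posterior model.
#' @param points matrix of evaluation points (rows).
#' @param delta direction vector.
#' @param ... passed to methods.
#' @return numeric vector, one non-negative value per row of `points`.
#' @keywords internal
#' @export
fi_quadform <- function(model, points, delta, ...) UseMethod("fi_quadform")

#' @export
fi_quadform.default <- function(model, points, delta, ...) {
  points <- check_matrix(points, "points")
  p <- predict_posteriors(model, points)
  vapply(seq_len(nrow(points)), function(i) {
    g <- grad_log_posteriors(model, points[i, ])
    sum(p[i, ] * as.vector(g %*% delta)^2)
  }, numeric(1))
}

row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

as_row <- function(features, d) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- check_matrix(features, "features")
  if (ncol(features) != d)
    stop(sprintf("expected %d input features, got %d", d, ncol(features)),
         call. = FALSE)
  features
}

#' Closed-form linear softmax posterior model
#'
#' Multinomial-logistic model \eqn{p(c|x) = softmax(Wx + b)_c}. Its
#' log-posterior gradients have the closed form
#' \eqn{\nabla_x \log p(c|x) = w_c - \sum_k p(k|x) w_k}, which makes it the
#' standard analytic oracle for the Fisher information pipeline: for two
#' classes, \eqn{FI(x) = p(1-p)(w_1 - w_0)(w_1 - w_0)^T}.
#'
#' @param weights `C x d` weight matrix (rows = classes).
#' @param bias length-C bias vector (default zeros).
#' @return Posterior model of class `fin_linear_softmax`.
#' @examples
#' m <- linear_softmax_model(matrix(c(0, 1), 2, 1))  # 1-D logistic in class 1
#' predict_posteriors(m, 0)  # c(0.5, 0.5)
#' @export
linear_softmax_model <- function(weights, bias = NULL) {
  weights <- check_matrix(weights, "weights")
  if (is.null(bias)) bias <- rep(0, nrow(weights))
  stopifnot(length(bias) == nrow(weights), all(is.finite(bias)))
  structure(list(weights = weights, bias = as.numeric(bias)),
            class = "fin_linear_softmax")
}

#' @export
n_classes.fin_linear_softmax <- function(model) nrow(model$weights)

#' @export
n_inputs.fin_linear_softmax <- function(model) ncol(model$weights)

#' @export
predict_posteriors.fin_linear_softmax <- function(model, features, ...) {
  x <- as_row(features, ncol(model$weights))
  z <- x %*% t(model$weights)
  z <- sweep(z, 2L, model$bias, "+")
  row_softmax(z)
}

#' @export
grad_log_posteriors.fin_linear_softmax <- function(model, x, ...) {
  x <- as.numeric(x)
  p <- as.vector(predict_posteriors(model, x))
  # rows: w_c - sum_k p_k w_k
  sweep(model$weights, 2L, as.vector(p %*% model$weights))
}

#' @export
fi_quadform.fin_linear_softmax <- function(model, points, delta, ...) {
  points <- check_matrix(points, "points")
  p <- predict_posteriors(model, points)            # T x C
  a <- as.vector(model$weights %*% delta)           # C
  A <- matrix(a, nrow(points), length(a), byrow = TRUE)
  b <- rowSums(p * A)                               # p . (W delta)
  rowSums(p * (A - b)^2)
}

#' @export
print.fin_linear_softmax <- function(x, ...) {
  cat(sprintf("<fin_linear_softmax> %d classes, %d inputs\n",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}
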