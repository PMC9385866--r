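#' Data-space Fisher information matrix at a point
#'
#' Computes
#' \deqn{FI(x) = \sum_c p(c|x)\, g_c(x) g_c(x)^T + \lambda I, \qquad
#'       g_c(x) = \nabla_x \log p(c|x),}
#' the outer-product form of the Fisher information of the class posteriors
#' with respect to the data point \eqn{x} (equivalently the negative
#' posterior-weighted Hessian of the log-posteriors). It is symmetric
#' positive semi-definite and large in directions along which class
#' membership changes quickly; it is the Riemannian metric underlying the
#' whole network construction.
#'
#' @param model a posterior model (see [posterior-contract]).
#' @param x finite feature vector.
#' @param ridge non-negative \eqn{\lambda} added to the diagonal (default 0);
#'   a tiny ridge (1e-8) keeps distances positive in posterior-flat regions.
#' @return `d x d` symmetric PSD matrix.
#' @examples
#' m <- linear_softmax_model(matrix(c(0, 1), 2, 1))  # 1-D logistic
#' fisher_matrix(m, 0)  # p(1-p) = 0.25 at the decision boundary
#' @export
fisher_matrix <- function(model, x, ridge = 0) {
  x <- as.numeric(x)
  ridge <- check_nonneg(ridge, "ridge")
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  p <- as.vector(predict_posteriors(model, x))
  G <- grad_log_posteriors(model, x)
  if (any(!is.finite(G)))
    stop("non-finite log-posterior gradients at the queried point",
         call. = FALSE)
  FI <- crossprod(G * sqrt(p))           # sum_c p_c g_c g_c^T
  FI <- (FI + t(FI)) / 2
  if (ridge > 0) FI <- FI + diag(ridge, length(x))
  FI
}

#' Local Fisher distance between two points
#'
#' Approximates the Riemannian length of the straight segment from `x` to
#' `y` under the Fisher metric,
#' \deqn{d(x, y) \approx \int_0^1 \sqrt{\Delta^T FI(x + t\Delta)\, \Delta}\,
#'       dt, \qquad \Delta = y - x,}
#' by the composite midpoint rule on `n_steps` equispaced midpoints. The
#' midpoint rule is symmetric under path reversal, so
#' `segment_distance(x, y) == segment_distance(y, x)` exactly, and refining
#' `n_steps` converges at the usual second order for smooth posteriors.
#' These segment lengths are the edge weights of the neighbour graph from
#' which geodesics are chained ([build_graph()]).
#'
#' @inheritParams fisher_matrix
#' @param y finite feature vector, same length as `x`.
#' @param n_steps quadrature resolution (>= 1, default 10).
#' @param ridge non-negative diagonal ridge on the metric; with `ridge > 0`
#'   the distance is zero iff `x == y`.
#' @return non-negative scalar; 0 when `x == y`.
#' @examples
#' m <- linear_softmax_model(matrix(c(0, 1), 2, 1))
#' segment_distance(m, -6, 6, n_steps = 200)  # ~ integral of sqrt(p(1-p))
#' @export
segment_distance <- function(model, x, y, n_steps = 10L, ridge = 0) {
  x <- as.numeric(x); y <- as.numeric(y)
  n_steps <- check_count(n_steps, "n_steps")
  ridge <- check_nonneg(ridge, "ridge")
  if (length(x) != length(y)) stop("`x` and `y` differ in length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("`x` and `y` must be finite", call. = FALSE)
  delta <- y - x
  if (all(delta == 0)) return(0)
  tt <- (seq_len(n_steps) - 0.5) / n_steps
  pts <- matrix(x, n_steps, length(x), byrow = TRUE) + outer(tt, delta)
  q <- fi_quadform(model, pts, delta) + ridge * sum(delta^2)
  sum(sqrt(pmax(q, 0))) / n_steps
}
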