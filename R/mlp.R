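#' MLP training configuration
#'
#' Defaults follow the reference configuration for posterior estimation on
#' reduced convolutional features: one hidden layer of 30 units, learning
#' rate 0.01, classical momentum 0.9, weight decay 0.2 and a softmax output.
#' Weight decay is applied as an L2 penalty on the weight matrices (not the
#' biases). A stated decay "rate" is ambiguous in common usage; the classical
#' MLP convention (Bishop; the netlab toolbox) regularises the *summed*
#' cross-entropy, \eqn{E = \sum_i E_i + (\alpha/2)\|W\|^2}, making the
#' effective per-sample coefficient \eqn{\alpha/n}. That is the default here
#' (`decay_mode = "sum"`); `decay_mode = "mean"` instead applies the raw
#' coefficient to the mean loss, which at 0.2 is a very strong penalty.
#'
#' @param hidden_units hidden layer width (default 30).
#' @param learning_rate SGD step size (default 0.01).
#' @param momentum classical momentum coefficient in `[0, 1)` (default 0.9).
#' @param weight_decay L2 penalty coefficient (default 0.2).
#' @param max_epochs training epochs (default 500); 0 returns the random
#'   initialisation (still a valid posterior model).
#' @param batch_size mini-batch size (default 32).
#' @param decay_mode `"sum"` (default; penalty relative to the summed data
#'   misfit, effective coefficient `weight_decay / n`) or `"mean"` (raw
#'   coefficient on the mean loss).
#' @param hidden_activation `"sigmoid"` (default) or `"tanh"`.
#' @param seed integer seed controlling initialisation and batch shuffling.
#' @return list of class `fin_mlp_config`.
#' @export
mlp_config <- function(hidden_units = 30L, learning_rate = 0.01,
                       momentum = 0.9, weight_decay = 0.2,
                       max_epochs = 500L, batch_size = 32L,
                       decay_mode = c("sum", "mean"),
                       hidden_activation = c("sigmoid", "tanh"),
                       seed = NULL) {
  hidden_activation <- match.arg(hidden_activation)
  decay_mode <- match.arg(decay_mode)
  cfg <- list(hidden_units = check_count(hidden_units, "hidden_units"),
              learning_rate = check_positive(learning_rate, "learning_rate"),
              momentum = check_nonneg(momentum, "momentum"),
              weight_decay = check_nonneg(weight_decay, "weight_decay"),
              max_epochs = check_count(max_epochs, "max_epochs", min = 0L),
              batch_size = check_count(batch_size, "batch_size"),
              decay_mode = decay_mode,
              hidden_activation = hidden_activation,
              seed = seed)
  if (cfg$momentum >= 1) stop("`momentum` must be < 1", call. = FALSE)
  structure(cfg, class = "fin_mlp_config")
}

act_fun <- function(kind) {
  switch(kind,
         sigmoid = list(f = function(a) 1 / (1 + exp(-a)),
                        dfh = function(h) h * (1 - h)),  # derivative via output
         tanh = list(f = tanh, dfh = function(h) 1 - h^2))
}

#' Train a one-hidden-layer softmax MLP
#'
#' Mini-batch gradient descent with classical momentum, categorical
#' cross-entropy loss, L2 weight decay and a softmax output layer. The model
#' fulfils the posterior-model contract (see [posterior-contract]); its
#' input gradients \eqn{\nabla_x \log p(c|x)} are computed analytically by
#' backpropagation to the inputs, which is what the Fisher information
#' metric consumes.
#'
#' @param features numeric case x feature matrix (finite).
#' @param labels integer labels in `0:(C-1)`; at least two classes present.
#' @param config a [mlp_config()] object.
#' @return Posterior model of class `fin_mlp` with weight matrices `W1`
#'   (hidden x input), `W2` (classes x hidden), biases, the config and the
#'   per-epoch training `loss` history (cross-entropy + penalty).
#' @examples
#' sim <- simulate_cases(200, n_classes = 3, n_features = 5, seed = 1)
#' m <- train_mlp(sim$features, sim$labels,
#'                mlp_config(max_epochs = 50, seed = 1))
#' mean(predict_labels(m, sim$features) == sim$labels)
#' @export
train_mlp <- function(features, labels, config = mlp_config()) {
  features <- check_matrix(features, "features")
  stopifnot(inherits(config, "fin_mlp_config"))
  labels <- as.integer(labels)
  n <- nrow(features)
  if (length(labels) != n) stop("labels/features length mismatch", call. = FALSE)
  if (any(is.na(labels)) || any(labels < 0))
    stop("labels must be non-negative integers", call. = FALSE)
  C <- max(labels) + 1L
  if (length(unique(labels)) < 2L)
    stop("need at least 2 classes present in `labels`", call. = FALSE)
  d <- ncol(features)
  H <- config$hidden_units
  act <- act_fun(config$hidden_activation)
  lr <- config$learning_rate
  mu <- config$momentum
  # effective L2 coefficient on the mean-loss scale used by the updates
  lam <- if (config$decay_mode == "sum") config$weight_decay / n
         else config$weight_decay
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), labels + 1L)] <- 1

  model <- with_seed(config$seed, {
    W1 <- matrix(runif(H * d, -1, 1) / sqrt(d), H, d)
    b1 <- numeric(H)
    W2 <- matrix(runif(C * H, -1, 1) / sqrt(H), C, H)
    b2 <- numeric(C)
    vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- b2
    loss <- numeric(config$max_epochs)

    full_loss <- function() {
      Hh <- act$f(sweep(features %*% t(W1), 2L, b1, "+"))
      P <- row_softmax(sweep(Hh %*% t(W2), 2L, b2, "+"))
      -mean(log(pmax(P[Y == 1], 1e-300))) +
        lam / 2 * (sum(W1^2) + sum(W2^2))
    }

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- features[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        nb <- length(idx)
        Hh <- act$f(sweep(Xb %*% t(W1), 2L, b1, "+"))
        P <- row_softmax(sweep(Hh %*% t(W2), 2L, b2, "+"))
        dZ <- (P - Yb) / nb
        gW2 <- crossprod(dZ, Hh) + lam * W2
        gb2 <- colSums(dZ)
        dH <- (dZ %*% W2) * act$dfh(Hh)
        gW1 <- crossprod(dH, Xb) + lam * W1
        gb1 <- colSums(dH)
        vW2 <- mu * vW2 - lr * gW2; W2 <- W2 + vW2
        vb2 <- mu * vb2 - lr * gb2; b2 <- b2 + vb2
        vW1 <- mu * vW1 - lr * gW1; W1 <- W1 + vW1
        vb1 <- mu * vb1 - lr * gb1; b1 <- b1 + vb1
      }
      loss[epoch] <- full_loss()
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, loss = loss)
  })

  structure(c(model,
              list(n_inputs = d, n_classes = C, config = config)),
            class = "fin_mlp")
}

#' @export
n_classes.fin_mlp <- function(model) model$n_classes

#' @export
n_inputs.fin_mlp <- function(model) model$n_inputs

mlp_forward <- function(model, x) {
  act <- act_fun(model$config$hidden_activation)
  Hh <- act$f(sweep(x %*% t(model$W1), 2L, model$b1, "+"))
  P <- row_softmax(sweep(Hh %*% t(model$W2), 2L, model$b2, "+"))
  list(hidden = Hh, posteriors = P, dfh = act$dfh(Hh))
}

#' @export
predict_posteriors.fin_mlp <- function(model, features, ...) {
  x <- as_row(features, model$n_inputs)
  p <- mlp_forward(model, x)$posteriors
  rownames(p) <- rownames(x)
  p
}

#' @export
grad_log_posteriors.fin_mlp <- function(model, x, ...) {
  x <- as.numeric(x)
  if (length(x) != model$n_inputs || any(!is.finite(x)))
    stop("`x` must be a finite vector of length n_inputs", call. = FALSE)
  fw <- mlp_forward(model, matrix(x, 1L))
  # Jacobian of the logits wrt x: W2 diag(h') W1, then centre by posteriors
  J <- model$W2 %*% (as.vector(fw$dfh) * model$W1)       # C x d
  J - matrix(as.vector(fw$posteriors %*% J), nrow(J), ncol(J), byrow = TRUE)
}

#' @export
fi_quadform.fin_mlp <- function(model, points, delta, ...) {
  points <- as_row(points, model$n_inputs)
  fw <- mlp_forward(model, points)
  u <- as.vector(model$W1 %*% delta)                     # H
  A <- sweep(fw$dfh, 2L, u, "*") %*% t(model$W2)         # T x C logit JVPs
  b <- rowSums(fw$posteriors * A)
  rowSums(fw$posteriors * (A - b)^2)
}

#' Hard class predictions from a posterior model
#'
#' Argmax of [predict_posteriors()]; ties broken toward the lower class
#' index. Labels are 0-based, matching [simulate_cases()].
#'
#' @inheritParams posterior-contract
#' @return integer vector of predicted labels in `0:(C-1)`.
#' @export
predict_labels <- function(model, features) {
  p <- predict_posteriors(model, features)
  max.col(p, ties.method = "first") - 1L
}

#' @export
print.fin_mlp <- function(x, ...) {
  cat(sprintf(
    "<fin_mlp> %d inputs -> %d %s units -> %d classes (softmax)\n",
    x$n_inputs, x$config$hidden_units, x$config$hidden_activation,
    x$n_classes))
  if (length(x$loss))
    cat(sprintf("  final training loss: %.4f after %d epochs\n",
                x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}
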