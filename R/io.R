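# Versioned JSON container format for persisted artifacts.
# Layout: {"container": "<class>", "version": 1, "payload": {...}}.
# Matrices are stored column-major as {"data", "dim", "rownames", "colnames"}.

FIN_FORMAT_VERSION <- 1L

to_payload <- function(object) {
  cls <- class(object)[1L]
  switch(
    cls,
    fin_pca = list(mean = object$mean, scale = object$scale,
                   rotation = mat2list(object$rotation),
                   explained = object$explained,
                   cum_explained = object$cum_explained,
                   all_ratios = object$all_ratios, k = object$k,
                   variance_threshold = object$variance_threshold),
    fin_mlp = list(W1 = mat2list(object$W1), b1 = object$b1,
                   W2 = mat2list(object$W2), b2 = object$b2,
                   loss = object$loss, n_inputs = object$n_inputs,
                   n_classes = object$n_classes,
                   config = unclass(object$config)),
    fin_linear_softmax = list(weights = mat2list(object$weights),
                              bias = object$bias),
    fin_graph = list(n = object$n, edges = object$edges, k = object$k,
                     n_steps = object$n_steps, ridge = object$ridge,
                     symmetrised = object$symmetrised,
                     augmented = object$augmented, ids = object$ids),
    fin_embedding = list(points = mat2list(object$points),
                         eigenvalues = object$eigenvalues,
                         lambda = object$lambda,
                         vectors = mat2list(object$vectors),
                         stress = object$stress,
                         clamped_mass = object$clamped_mass,
                         m = object$m, refined = object$refined),
    stop("no serializer for class ", cls, call. = FALSE)
  )
}

from_payload <- function(cls, p) {
  obj <- switch(
    cls,
    fin_pca = list(mean = unlist(p$mean), scale = unlist(p$scale),
                   rotation = list2mat(p$rotation),
                   explained = unlist(p$explained),
                   cum_explained = p$cum_explained,
                   all_ratios = unlist(p$all_ratios), k = as.integer(p$k),
                   variance_threshold = p$variance_threshold),
    fin_mlp = {
      cfg <- p$config
      cfg$seed <- if (is.null(cfg$seed)) NULL else as.integer(cfg$seed)
      cfg <- structure(cfg, class = "fin_mlp_config")
      list(W1 = list2mat(p$W1), b1 = unlist(p$b1),
           W2 = list2mat(p$W2), b2 = unlist(p$b2),
           loss = unlist(p$loss), n_inputs = as.integer(p$n_inputs),
           n_classes = as.integer(p$n_classes), config = cfg)
    },
    fin_linear_softmax = list(weights = list2mat(p$weights),
                              bias = unlist(p$bias)),
    fin_graph = list(n = as.integer(p$n), edges = as.data.frame(p$edges),
                     k = as.integer(p$k), n_steps = as.integer(p$n_steps),
                     ridge = p$ridge, symmetrised = isTRUE(p$symmetrised),
                     augmented = as.data.frame(p$augmented), ids = p$ids),
    fin_embedding = list(points = list2mat(p$points),
                         eigenvalues = unlist(p$eigenvalues),
                         lambda = unlist(p$lambda),
                         vectors = list2mat(p$vectors),
                         stress = p$stress, clamped_mass = p$clamped_mass,
                         m = as.integer(p$m), refined = isTRUE(p$refined)),
    stop("no deserializer for class ", cls, call. = FALSE)
  )
  structure(obj, class = cls)
}

#' Save / load artifacts in the package's JSON container format
#'
#' Persists fitted artifacts (PCA transform, MLP model, neighbour graph,
#' latent embedding, linear softmax oracle, or a whole `fin_model`) as
#' plain-text JSON: `{"container": <class>, "version": 1, "payload": ...}`.
#' The round trip is exact to double precision (numbers are written with
#' full precision).
#'
#' @param object one of the supported fitted objects.
#' @param path output file (conventionally `.json`).
#' @return `fin_save()` returns `path` invisibly; `fin_load()` the restored
#'   object.
#' @examples
#' p <- fit_pca(matrix(rnorm(60), 20, 3), 0.9)
#' f <- tempfile(fileext = ".json")
#' fin_save(p, f)
#' identical(fin_load(f)$rotation, p$rotation)
#' @export
fin_save <- function(object, path) {
  cls <- class(object)[1L]
  if (cls == "fin_model") {
    payload <- list(
      pca = to_payload(object$pca),
      scores = mat2list(object$scores),
      mlp = to_payload(object$mlp),
      predicted = object$predicted,
      labels = object$labels,
      graph = to_payload(object$graph),
      geodesics = mat2list(unclass(object$geodesics)),
      sigma_g = object$sigma_g,
      embedding = to_payload(object$embedding),
      params = object$params)
  } else payload <- to_payload(object)
  jsonlite::write_json(list(container = cls, version = FIN_FORMAT_VERSION,
                            payload = payload),
                       path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname fin_save
#' @export
fin_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyMatrix = FALSE, simplifyDataFrame = TRUE)
  if (is.null(x$container) || is.null(x$version))
    stop("not a finet container file: ", path, call. = FALSE)
  cls <- x$container
  p <- x$payload
  if (cls != "fin_model") return(from_payload(cls, p))
  geodesics <- list2mat(p$geodesics)
  obj <- list(pca = from_payload("fin_pca", p$pca),
              scores = list2mat(p$scores),
              mlp = from_payload("fin_mlp", p$mlp),
              predicted = as.integer(p$predicted),
              labels = as.integer(p$labels),
              graph = from_payload("fin_graph", p$graph),
              geodesics = geodesics,
              sigma_g = p$sigma_g,
              adjacency = kernel_adjacency(geodesics, p$sigma_g),
              embedding = from_payload("fin_embedding", p$embedding),
              params = p$params)
  structure(obj, class = "fin_model")
}
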