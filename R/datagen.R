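#' Regular-simplex class means
#'
#' Places `n_classes` class centroids at the vertices of a regular simplex in
#' the first `n_classes - 1` feature dimensions (zeros elsewhere), scaled so
#' every pair of centroids is exactly `separation` apart. The basis is the
#' column-normalised Helmert contrast matrix, which makes the construction
#' closed-form and platform-independent.
#'
#' @param n_classes number of classes (>= 1).
#' @param n_features feature dimension; must be at least `n_classes - 1`.
#' @param separation pairwise Euclidean distance between class means.
#' @return `n_classes x n_features` matrix of class means.
#' @examples
#' m <- simplex_means(5, 10, 6)
#' round(dist(m), 10)  # all pairwise distances equal 6
#' @export
simplex_means <- function(n_classes, n_features, separation) {
  n_classes <- check_count(n_classes, "n_classes")
  n_features <- check_count(n_features, "n_features")
  separation <- check_nonneg(separation, "separation")
  if (n_features < n_classes - 1L)
    stop("`n_features` must be at least `n_classes` - 1 for simplex means",
         call. = FALSE)
  mu <- matrix(0, n_classes, n_features)
  if (n_classes > 1L) {
    H <- stats::contr.helmert(n_classes)           # n_classes x (n_classes-1)
    H <- sweep(H, 2L, sqrt(colSums(H^2)), "/")     # orthonormal basis of 1^T
    # rows of H form a regular simplex with pairwise distance sqrt(2)
    mu[, seq_len(n_classes - 1L)] <- H * separation / sqrt(2)
  }
  mu
}

#' Simulate multi-class Gaussian-mixture feature data
#'
#' Generates synthetic cases emulating PCA-reduced convolutional features: a
#' Gaussian mixture with one component per class. Class means default to a
#' regular simplex (see [simplex_means()]) so all pairwise class separations
#' are equal and controlled by a single `separation` parameter, expressed in
#' the same units as `within_class_sd`. One class may be flagged as a
#' heterogeneous "background" class with inflated dispersion via
#' `background_scale` (off by default).
#'
#' Labels are integers in `0:(n_classes - 1)`; class 0 plays the background
#' role when `background_scale > 1`. Case identifiers `case_0001, ...` are
#' attached as rownames and used by all downstream joins.
#'
#' @param n_cases number of cases to generate.
#' @param n_classes number of classes (default 5: background plus the four
#'   lesion classes of a mammogram patch classifier).
#' @param n_features feature dimension.
#' @param separation pairwise distance between class means (ignored when
#'   `class_means` is supplied).
#' @param within_class_sd isotropic within-class standard deviation; either a
#'   scalar or one value per class.
#' @param class_proportions mixing proportions; must be non-negative and sum
#'   to 1 (within 1e-12).
#' @param class_means optional explicit `n_classes x n_features` mean matrix.
#' @param background_scale multiplier on class 0's standard deviation
#'   (default 1 = off).
#' @param seed integer seed; identical seeds give identical output.
#' @return Object of class `fin_simdata`: list with `features` (matrix with
#'   case-id rownames), `labels` (integer vector), `means`, `sds` and the
#'   generating parameters.
#' @examples
#' sim <- simulate_cases(100, n_classes = 5, n_features = 10, seed = 7)
#' dim(sim$features); table(sim$labels)
#' @export
simulate_cases <- function(n_cases,
                           n_classes = 5L,
                           n_features = 10L,
                           separation = 6,
                           within_class_sd = 1,
                           class_proportions = NULL,
                           class_means = NULL,
                           background_scale = 1,
                           seed = NULL) {
  n_cases <- check_count(n_cases, "n_cases")
  n_classes <- check_count(n_classes, "n_classes")
  n_features <- check_count(n_features, "n_features")
  background_scale <- check_positive(background_scale, "background_scale")

  if (is.null(class_proportions))
    class_proportions <- rep(1 / n_classes, n_classes)
  if (length(class_proportions) != n_classes ||
      any(!is.finite(class_proportions)) || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-12)
    stop("`class_proportions` must be non-negative and sum to 1", call. = FALSE)

  if (length(within_class_sd) == 1L)
    within_class_sd <- rep(within_class_sd, n_classes)
  if (length(within_class_sd) != n_classes || any(within_class_sd <= 0) ||
      any(!is.finite(within_class_sd)))
    stop("`within_class_sd` must be positive (scalar or one per class)",
         call. = FALSE)
  sds <- within_class_sd
  sds[1L] <- sds[1L] * background_scale

  if (is.null(class_means)) {
    class_means <- simplex_means(n_classes, n_features, separation)
  } else {
    class_means <- check_matrix(class_means, "class_means")
    if (!all(dim(class_means) == c(n_classes, n_features)))
      stop("`class_means` must be n_classes x n_features", call. = FALSE)
  }

  out <- with_seed(seed, {
    labels <- sample.int(n_classes, n_cases, replace = TRUE,
                         prob = class_proportions) - 1L
    noise <- matrix(rnorm(n_cases * n_features), n_cases, n_features)
    list(labels = labels, noise = noise)
  })
  features <- class_means[out$labels + 1L, , drop = FALSE] +
    out$noise * sds[out$labels + 1L]
  rownames(features) <- sprintf("case_%04d", seq_len(n_cases))
  colnames(features) <- sprintf("f%d", seq_len(n_features))
  names(out$labels) <- rownames(features)

  structure(list(features = features,
                 labels = out$labels,
                 means = class_means,
                 sds = sds,
                 n_classes = n_classes,
                 class_proportions = class_proportions,
                 separation = separation,
                 seed = seed),
            class = "fin_simdata")
}

#' @export
print.fin_simdata <- function(x, ...) {
  cat(sprintf("<fin_simdata> %d cases, %d features, %d classes\n",
              nrow(x$features), ncol(x$features), x$n_classes))
  print(table(label = x$labels))
  invisible(x)
}

#' Write / read cases as delimited text
#'
#' `write_cases()` writes `<prefix>_features.csv` (header row; first column
#' `case_id`, one case per row) and `<prefix>_labels.csv` (`case_id,label`).
#' `read_cases()` reads the same dialect back.
#'
#' @param sim a `fin_simdata` object, or any list with `features` and
#'   (optionally) `labels`.
#' @param prefix path prefix for the two CSV files.
#' @return `write_cases()` returns the two file paths invisibly;
#'   `read_cases()` a list with `features` (matrix, case-id rownames) and
#'   `labels` (integer vector or `NULL`).
#' @export
write_cases <- function(sim, prefix) {
  features <- check_matrix(sim$features, "features")
  paths <- c(features = paste0(prefix, "_features.csv"),
             labels = paste0(prefix, "_labels.csv"))
  df <- data.frame(case_id = rownames(features), features,
                   check.names = FALSE)
  write.csv(df, paths[["features"]], row.names = FALSE, quote = FALSE)
  if (!is.null(sim$labels)) {
    write.csv(data.frame(case_id = rownames(features),
                         label = as.integer(sim$labels)),
              paths[["labels"]], row.names = FALSE, quote = FALSE)
  } else paths <- paths[1L]
  invisible(paths)
}

#' @rdname write_cases
#' @export
read_cases <- function(prefix) {
  fpath <- paste0(prefix, "_features.csv")
  df <- read.csv(fpath, check.names = FALSE)
  features <- as.matrix(df[, -1L, drop = FALSE])
  rownames(features) <- df[[1L]]
  lpath <- paste0(prefix, "_labels.csv")
  labels <- NULL
  if (file.exists(lpath)) {
    ldf <- read.csv(lpath)
    labels <- as.integer(ldf$label)
    names(labels) <- ldf$case_id
    labels <- labels[rownames(features)]
  }
  list(features = features, labels = labels)
}
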