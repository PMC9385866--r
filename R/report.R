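#' Ranked nearest neighbours for a query case
#'
#' 'Patient-like-me' retrieval: ranks training cases by geodesic distance to
#' the query (ascending, ties broken by case id), attaches the Gaussian
#' kernel similarity \eqn{\exp(-d^2/\sigma_G^2)}, predicted/true labels and
#' any free-form metadata joined by case id. Retrieval uses the
#' geodesic/projected geodesic distances — the network's similarity
#' structure — not the 2-D plot coordinates. When the query is itself a
#' training case, pass its id as `exclude` so it does not appear in its own
#' list.
#'
#' @param distances named vector of distances from the query to the training
#'   cases (a row of the geodesic matrix, or [test_to_train_distances()]).
#' @param k number of neighbours to return (`1 <= k <=` available cases).
#' @param sigma_g kernel width for the similarity column (optional).
#' @param predicted_labels,true_labels optional per-training-case labels,
#'   aligned with `distances`.
#' @param metadata optional data.frame with a `case_id` column; matching
#'   rows are passed through verbatim.
#' @param query_id optional identifier recorded on the report.
#' @param exclude case ids to drop before ranking (typically the query).
#' @return Object of class `fin_neighbours`: `query_id`, `k`, `neighbours`
#'   (data.frame: case_id, distance, similarity, labels, metadata) and
#'   `majority` (vote fractions over the neighbours' labels, true labels
#'   when available).
#' @export
nearest_neighbours <- function(distances, k, sigma_g = NULL,
                               predicted_labels = NULL, true_labels = NULL,
                               metadata = NULL, query_id = NULL,
                               exclude = NULL) {
  d <- as.numeric(distances)
  ids <- names(distances)
  if (is.null(ids)) ids <- sprintf("case_%04d", seq_along(d))
  df <- data.frame(case_id = ids, distance = d, stringsAsFactors = FALSE)
  if (!is.null(predicted_labels)) df$predicted_label <- predicted_labels
  if (!is.null(true_labels)) df$true_label <- true_labels
  if (!is.null(exclude)) df <- df[!df$case_id %in% exclude, , drop = FALSE]
  k <- check_count(k, "k")
  if (k > nrow(df))
    stop("`k` exceeds the number of available training cases", call. = FALSE)
  df <- df[order(df$distance, df$case_id), , drop = FALSE][seq_len(k), ]
  if (!is.null(sigma_g))
    df$similarity <- exp(-df$distance^2 / sigma_g^2)
  if (!is.null(metadata)) {
    if (!"case_id" %in% names(metadata))
      stop("`metadata` must contain a `case_id` column", call. = FALSE)
    df <- merge(df, metadata, by = "case_id", all.x = TRUE, sort = FALSE)
    df <- df[order(df$distance, df$case_id), , drop = FALSE]
  }
  rownames(df) <- NULL

  vote_col <- if (!is.null(df$true_label)) df$true_label else df$predicted_label
  majority <- NULL
  if (!is.null(vote_col)) {
    tab <- sort(table(vote_col), decreasing = TRUE)
    majority <- list(label = names(tab)[1L],
                     fractions = as.numeric(tab) / k,
                     labels = names(tab))
  }
  structure(list(query_id = query_id, k = k, neighbours = df,
                 sigma_g = sigma_g, majority = majority),
            class = "fin_neighbours")
}

#' @export
print.fin_neighbours <- function(x, ...) {
  cat(sprintf("<fin_neighbours> query %s, k = %d\n",
              if (is.null(x$query_id)) "<unnamed>" else x$query_id, x$k))
  print(x$neighbours, digits = 4)
  if (!is.null(x$majority))
    cat(sprintf("majority label: %s (%.0f%% of votes)\n",
                x$majority$label, 100 * x$majority$fractions[1L]))
  invisible(x)
}

#' Write a neighbour report as delimited text
#'
#' @param report a `fin_neighbours` object.
#' @param file output CSV path.
#' @return the file path, invisibly.
#' @export
write_neighbours <- function(report, file) {
  stopifnot(inherits(report, "fin_neighbours"))
  write.csv(report$neighbours, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

fin_palette <- function(n) {
  base <- c("#4477AA", "#EE6677", "#228833", "#CCBB44", "#66CCEE",
            "#AA3377", "#BBBBBB")
  if (n <= length(base)) base[seq_len(n)] else hcl.colors(n, "Dark 3")
}

#' Scatter plot of the latent space
#'
#' Draws the training cloud (translucent, coloured by true or predicted
#' label, legend listing every class present), optionally overlays projected
#' test cases as black stars, and highlights selected case ids as solid red
#' circles. Writes PNG or PDF depending on the file extension; the output is
#' deterministic given identical inputs.
#'
#' @param embedding a `fin_embedding` (2-D or more; first two axes drawn).
#' @param labels per-training-case labels used for colouring.
#' @param projections optional list of `fin_projection` objects (or a matrix
#'   of coordinates) to overlay.
#' @param colour_by legend title: `"true"` or `"predicted"` label.
#' @param highlight character vector of training case ids to mark; unknown
#'   ids are an error naming the offender.
#' @param file output path ending in `.png` or `.pdf`.
#' @param width,height device size in pixels (png) or inches (pdf).
#' @return the file path, invisibly.
#' @export
render_latent_plot <- function(embedding, labels, projections = NULL,
                               colour_by = c("true", "predicted"),
                               highlight = NULL, file = "fin_latent.png",
                               width = NULL, height = NULL) {
  stopifnot(inherits(embedding, "fin_embedding"))
  colour_by <- match.arg(colour_by)
  pts <- embedding$points
  if (nrow(pts) < 1L) stop("embedding has no cases", call. = FALSE)
  if (length(labels) != nrow(pts))
    stop("`labels` must have one entry per embedded case", call. = FALSE)
  if (!is.null(highlight)) {
    missing_ids <- setdiff(highlight, rownames(pts))
    if (length(missing_ids))
      stop("unknown highlight id(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
  }
  proj_xy <- NULL
  if (!is.null(projections)) {
    proj_xy <- if (is.list(projections) && !is.data.frame(projections) &&
                   !is.matrix(projections))
      do.call(rbind, lapply(projections, function(p) p$coords[1:2]))
    else as.matrix(projections)[, 1:2, drop = FALSE]
  }

  ext <- tolower(tools::file_ext(file))
  if (ext == "pdf") pdf(file, width = width %||% 7, height = height %||% 6)
  else png(file, width = width %||% 900, height = height %||% 780)
  on.exit(dev.off())

  lv <- sort(unique(as.character(labels)))
  cols <- fin_palette(length(lv))
  names(cols) <- lv
  xr <- range(c(pts[, 1L], proj_xy[, 1L]))
  yr <- range(c(pts[, 2L], proj_xy[, 2L]))
  plot(NA, xlim = xr, ylim = yr, xlab = "latent dim 1", ylab = "latent dim 2",
       main = "Fisher information network latent space")
  points(pts[, 1L], pts[, 2L], pch = 16, cex = 0.8,
         col = adjustcolor(cols[as.character(labels)], alpha.f = 0.35))
  if (!is.null(proj_xy))
    points(proj_xy[, 1L], proj_xy[, 2L], pch = 8, cex = 1.1, col = "black")
  if (!is.null(highlight)) {
    hi <- pts[highlight, , drop = FALSE]
    points(hi[, 1L], hi[, 2L], pch = 19, cex = 1.2, col = "red")
  }
  legend("topright",
         legend = lv, col = cols, pch = 16, bty = "n",
         title = sprintf("%s label", colour_by))
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row-normalised confusion matrix and overall accuracy
#'
#' @param true,predicted equal-length label vectors; their label sets must
#'   overlap.
#' @return Object of class `fin_confusion`: `counts` (raw matrix, rows =
#'   actual), `confusion` (rows with at least one case normalised to sum to
#'   1), `accuracy` (trace of counts / n).
#' @examples
#' misclassification_table(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
#' @export
misclassification_table <- function(true, predicted) {
  if (length(true) != length(predicted))
    stop("label vectors differ in length", call. = FALSE)
  if (!length(intersect(unique(true), unique(predicted))))
    stop("true and predicted label sets are disjoint", call. = FALSE)
  levels <- sort(unique(c(as.character(true), as.character(predicted))))
  tf <- factor(as.character(true), levels = levels)
  pf <- factor(as.character(predicted), levels = levels)
  counts <- table(actual = tf, predicted = pf)
  counts <- matrix(as.numeric(counts), nrow = length(levels),
                   dimnames = list(actual = levels, predicted = levels))
  rs <- rowSums(counts)
  confusion <- counts
  nonzero <- rs > 0
  confusion[nonzero, ] <- counts[nonzero, , drop = FALSE] / rs[nonzero]
  structure(list(counts = counts, confusion = confusion,
                 accuracy = sum(diag(counts)) / length(true)),
            class = "fin_confusion")
}

#' @export
print.fin_confusion <- function(x, ...) {
  cat(sprintf("<fin_confusion> overall accuracy %.1f%%\n", 100 * x$accuracy))
  print(round(x$confusion, 3))
  invisible(x)
}

#' Mean k-nearest-neighbour label purity
#'
#' For each case, the fraction of its `k` nearest neighbours (Euclidean, in
#' the supplied coordinates, self excluded, ties by index) sharing its
#' label; averaged over cases. Used to compare class structure between
#' embeddings (e.g. the FIN latent space vs the first two principal
#' components).
#'
#' @param coords case x dim coordinate matrix.
#' @param labels one label per case.
#' @param k neighbourhood size (default 10).
#' @return scalar in `[0, 1]`.
#' @export
knn_purity <- function(coords, labels, k = 10L) {
  coords <- check_matrix(coords, "coords")
  n <- nrow(coords)
  k <- check_count(k, "k")
  if (k >= n) stop("`k` must be smaller than the number of cases", call. = FALSE)
  D <- as.matrix(dist(coords))
  mean(vapply(seq_len(n), function(i) {
    nb <- seq_len(n)[-i][order(D[i, -i])][seq_len(k)]
    mean(labels[nb] == labels[i])
  }, numeric(1)))
}
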