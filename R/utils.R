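#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so package functions never perturb the caller's
#' random stream. `seed = NULL` leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar validators; all stop() with the argument name in the message
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive number", name), call. = FALSE)
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("`%s` must be a non-negative number", name), call. = FALSE)
  as.numeric(x)
}

check_matrix <- function(x, name) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop(sprintf("`%s` must be a finite numeric matrix", name), call. = FALSE)
  x
}

# Euclidean distances from one point to the rows of a matrix
row_dist_to <- function(mat, x) {
  sqrt(rowSums(sweep(mat, 2L, x)^2))
}

# matrix <-> plain-list round trip for the JSON container format
mat2list <- function(m) list(data = as.vector(m), dim = dim(m),
                             rownames = rownames(m), colnames = colnames(m))

list2mat <- function(l) {
  m <- matrix(as.numeric(l$data), nrow = l$dim[[1]], ncol = l$dim[[2]])
  if (!is.null(l$rownames) && length(l$rownames)) rownames(m) <- l$rownames
  if (!is.null(l$colnames) && length(l$colnames)) colnames(m) <- l$colnames
  m
}
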