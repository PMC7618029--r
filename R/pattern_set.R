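#' Construct a pattern set
#'
#' A pattern set is the unit of training and querying throughout the package:
#' a \code{d x N} numeric matrix whose columns are patterns, optionally carrying
#' integer class labels (one per column).
#'
#' @param data numeric matrix with one pattern per column (\code{d x N}).
#'   A numeric vector is treated as a single column.
#' @param labels optional vector of per-pattern class labels, length \code{N}.
#' @return An object of class \code{"pattern_set"}: a list with elements
#'   \code{data} and \code{labels}.
#' @examples
#' ps <- pattern_set(matrix(rnorm(20), 4, 5))
#' dim(ps)
#' pattern_mean(ps)
#' @export
pattern_set <- function(data, labels = NULL) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, ncol = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix with one pattern per column")
  if (!is.null(labels)) {
    if (length(labels) != ncol(data))
      stop("'labels' must have one entry per pattern (column)")
    labels <- as.integer(labels)
  }
  structure(list(data = data, labels = labels), class = "pattern_set")
}

#' Coerce to a pattern matrix
#'
#' Accepts either a \code{pattern_set} or a plain numeric matrix/vector and
#' returns the underlying \code{d x N} matrix. Most functions in the package
#' accept both forms.
#'
#' @param x a \code{pattern_set}, numeric matrix, or numeric vector.
#' @param d required dimension, checked if given.
#' @return numeric matrix with patterns in columns.
#' @export
as_pattern_matrix <- function(x, d = NULL) {
  m <- if (inherits(x, "pattern_set")) x$data
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(x, ncol = 1L)
  else stop("cannot interpret 'x' as patterns: expected a pattern_set or numeric matrix")
  if (!is.null(d) && nrow(m) != d)
    stop(sprintf("pattern dimension mismatch: expected %d rows, got %d", d, nrow(m)))
  m
}

#' Pattern-set sample mean
#'
#' The column average of the pattern matrix, recomputed from the data.
#' Rejects an empty set, which carries no statistics.
#'
#' @param x a \code{pattern_set} or pattern matrix.
#' @return numeric vector of length \code{d}.
#' @export
pattern_mean <- function(x) {
  m <- as_pattern_matrix(x)
  if (ncol(m) == 0L) stop("empty pattern set has no mean")
  rowMeans(m)
}

#' @export
dim.pattern_set <- function(x) dim(x$data)

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("Pattern set: d = %d, N = %d%s\n", nrow(x$data), ncol(x$data),
              if (is.null(x$labels)) "" else
                sprintf(", %d classes", length(unique(x$labels)))))
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
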