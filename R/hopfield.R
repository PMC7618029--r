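#' Classical Hopfield familiarity energy
#'
#' \eqn{E(q) = -\sum_i (q^\top x^{(i)})^2}: the energy of a classical Hopfield
#' associative memory storing the patterns \code{X}. There is no training
#' phase; the energy is evaluated directly from the stored patterns, and a
#' lower (more negative) value signals familiarity.
#'
#' @param q query pattern(s): vector, matrix (columns) or \code{pattern_set}.
#' @param x nonempty stored patterns.
#' @return numeric vector of nonpositive energies, one per query.
#' @examples
#' X <- cbind(c(1, 0), c(1, 1))
#' hn_energy(c(1, 2), X)  # -10
#' @export
hn_energy <- function(q, x) {
  X <- as_pattern_matrix(x)
  if (ncol(X) == 0L) stop("empty pattern set")
  Q <- as_pattern_matrix(q, d = nrow(X))
  -colSums(crossprod(X, Q)^2)
}

#' Hopfield energy in covariance form
#'
#' The algebraic rewriting \eqn{E(q) = -q^\top X X^\top q}, which equals
#' \code{\link{hn_energy}} exactly and, on centered data, is proportional to
#' \eqn{-q^\top \Sigma q = -\|\Sigma^{1/2} q\|^2} with
#' \eqn{\hat\Sigma = XX^\top/N}. Requires centered patterns (column mean zero);
#' centering is the caller's job.
#'
#' @inheritParams hn_energy
#' @param normalized if \code{TRUE}, return the \eqn{-q^\top\hat\Sigma q} form
#'   (the exact energy divided by \eqn{N}).
#' @param tol tolerance on the column mean for the centering check.
#' @return numeric vector of energies, one per query.
#' @export
hn_energy_cov <- function(q, x, normalized = FALSE, tol = 1e-8) {
  X <- as_pattern_matrix(x)
  if (ncol(X) == 0L) stop("empty pattern set")
  if (max(abs(rowMeans(X))) > tol)
    stop("patterns must be centered (column mean 0); center with the training mean first")
  Q <- as_pattern_matrix(q, d = nrow(X))
  e <- -colSums(Q * (X %*% crossprod(X, Q)))
  if (normalized) e / ncol(X) else e
}

#' Modern continuous Hopfield energy
#'
#' \eqn{E(q) = -\log \sum_i \exp(q^\top x^{(i)}) + \tfrac12 \|q\|_2^2},
#' evaluated with a numerically stable log-sum-exp. Like the classical
#' Hopfield energy it needs no training phase.
#'
#' @inheritParams hn_energy
#' @return numeric vector of energies, one per query.
#' @examples
#' mchn_energy(c(0, 0), diag(2))  # -log(2)
#' @export
mchn_energy <- function(q, x) {
  X <- as_pattern_matrix(x)
  if (ncol(X) == 0L) stop("empty pattern set")
  Q <- as_pattern_matrix(q, d = nrow(X))
  V <- crossprod(X, Q)                       # N x M of q' x_i
  m <- apply(V, 2, max)
  lse <- m + log(colSums(exp(sweep(V, 2, m))))
  -lse + 0.5 * colSums(Q^2)
}

#' Hopfield-family novelty model
#'
#' Wraps the training set for the classical or modern-continuous Hopfield
#' energy behind the same fit/predict surface as the trained models. By
#' default patterns (and later queries) are centered with the training mean,
#' matching the covariance form of the classical energy.
#'
#' @param x stored patterns (\code{pattern_set} or matrix), nonempty.
#' @param type \code{"classical"} or \code{"modern"}.
#' @param center center patterns and queries by the training mean.
#' @return object of class \code{"hopfield"}.
#' @export
hopfield <- function(x, type = c("classical", "modern"), center = TRUE) {
  type <- match.arg(type)
  X <- as_pattern_matrix(x)
  if (ncol(X) == 0L) stop("empty pattern set")
  mu <- if (center) rowMeans(X) else numeric(nrow(X))
  structure(list(X = X - mu, mu = mu, type = type, center = center,
                 d = nrow(X), N = ncol(X)),
            class = "hopfield")
}

#' @export
print.hopfield <- function(x, ...) {
  cat(sprintf("%s Hopfield novelty model: d = %d, N = %d stored patterns%s\n",
              if (x$type == "classical") "Classical" else "Modern continuous",
              x$d, x$N, if (x$center) " (centered)" else ""))
  invisible(x)
}

#' @export
predict.hopfield <- function(object, newdata, ...) {
  Q <- as_pattern_matrix(newdata, d = object$d) - object$mu
  if (object$type == "classical") hn_energy(Q, object$X) else mchn_energy(Q, object$X)
}
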