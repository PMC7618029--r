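#' Metric transform
#'
#' A member of the parameterised family of squared distances
#' \eqn{d^2(q) = c\,\|L(q - \bar x)\|_2^2}: the squared Euclidean distance of a
#' query from the data mean, measured in the space transformed by a
#' \code{d x d} matrix \eqn{L} and scaled by a constant \eqn{c}. Both the
#' Hopfield energy and the converged rPCN energy are members of this family
#' (with different \eqn{L}), which is what makes their behaviour under
#' correlated data directly comparable.
#'
#' @param L a \code{d x d} matrix.
#' @param c scalar multiplier.
#' @param center the reference point \eqn{\bar x} (vector or scalar 0).
#' @param sign orientation: \code{+1} if larger distance means more novel,
#'   \code{-1} if larger distance means more familiar (the Hopfield case,
#'   whose energy carries a negative sign).
#' @return an object of class \code{"metric_transform"}.
#' @export
metric_transform <- function(L, c = 1, center = 0, sign = 1) {
  if (!is.matrix(L) || nrow(L) != ncol(L)) stop("'L' must be a square matrix")
  if (!sign %in% c(-1, 1)) stop("'sign' must be +1 or -1")
  structure(list(L = L, c = c, center = rep_len(center, nrow(L)), sign = sign),
            class = "metric_transform")
}

#' @export
print.metric_transform <- function(x, ...) {
  cat(sprintf("Metric transform: d = %d, c = %g, %s\n", nrow(x$L), x$c,
              if (x$sign > 0) "distance = novelty" else "distance = familiarity (inverted)"))
  invisible(x)
}

#' Evaluate a metric transform
#'
#' \eqn{c\,\|L(q - \bar x)\|_2^2} for one or more queries.
#'
#' @param transform a \code{\link{metric_transform}}.
#' @param q query pattern(s): vector, matrix or \code{pattern_set}.
#' @return numeric vector, one nonnegative distance per query (before any
#'   orientation sign is applied; see \code{sign} in the transform for how to
#'   read it as novelty).
#' @export
metric_distance <- function(transform, q) {
  Q <- as_pattern_matrix(q, d = nrow(transform$L))
  transform$c * colSums((transform$L %*% (Q - transform$center))^2)
}

# symmetric PSD square root via eigen-decomposition, eigenvalues floored at 0
psd_sqrt <- function(Sigma, floor = 1e-12) {
  es <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(es$values, floor)
  es$vectors %*% (sqrt(lam) * t(es$vectors))
}

#' Hopfield-energy metric transform
#'
#' The classical Hopfield familiarity energy on centered data equals
#' \eqn{-\|\Sigma^{1/2} q\|_2^2} (up to the 1/N normalisation of
#' \eqn{\Sigma}): a squared distance measured after transforming by the
#' symmetric square root of the covariance, with inverted orientation (the
#' farther from the mean in that space, the more familiar). This is why the
#' Hopfield readout degrades on correlated data: the transform stretches
#' exactly the directions in which the data already vary most.
#'
#' @param Sigma symmetric positive semi-definite covariance matrix.
#' @param center data mean (default 0, the centered convention).
#' @return a \code{\link{metric_transform}} with \code{L = Sigma^{1/2}},
#'   \code{sign = -1}.
#' @export
l_hn <- function(Sigma, center = 0) {
  if (max(abs(Sigma - t(Sigma))) > 1e-8) stop("'Sigma' must be symmetric")
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("'Sigma' must be positive semi-definite")
  metric_transform(psd_sqrt(Sigma), c = 1, center = center, sign = -1)
}

#' Converged-rPCN metric transform
#'
#' At the fixed point of rPCN learning the network energy is a squared
#' distance with
#' \deqn{L = \mathrm{diagMat}(1 \oslash \mathrm{diag}(\Sigma^{-1}))\,\Sigma^{-1},}
#' i.e. each row of the precision matrix rescaled by its reciprocal diagonal,
#' so that \code{diag(L)} is exactly all ones. Row \eqn{j} of \eqn{I - L} is
#' the least-squares regression of coordinate \eqn{j} on all the others, which
#' is the statistical content of the converged recurrent weights. \eqn{L} is
#' invariant to rescaling \eqn{\Sigma}.
#'
#' @param Sigma symmetric positive-definite covariance matrix.
#' @param center data mean (default 0).
#' @return a \code{\link{metric_transform}} with \code{sign = +1} (distance =
#'   novelty).
#' @export
l_rpcn <- function(Sigma, center = 0) {
  if (max(abs(Sigma - t(Sigma))) > 1e-8) stop("'Sigma' must be symmetric")
  P <- tryCatch(solve(Sigma), error = function(e)
    stop("'Sigma' must be invertible (positive definite): ", conditionMessage(e)))
  L <- P / diag(P)          # divides row j by P[j, j]
  diag(L) <- 1
  metric_transform(L, c = 1, center = center, sign = 1)
}

#' Closed-form converged rPCN weights
#'
#' The analytic fixed point of rPCN learning on data with covariance
#' \code{Sigma}: \eqn{W^* = I - L_{rPCN}(\Sigma)}, whose row \eqn{j} holds the
#' regression coefficients of coordinate \eqn{j} on all other coordinates, and
#' whose diagonal is exactly zero. Used as the independent oracle for the
#' gradient-trained network.
#'
#' @param Sigma symmetric positive-definite covariance matrix.
#' @return a \code{d x d} matrix with zero diagonal.
#' @examples
#' converged_rpcn_weights(uniform_cov_matrix(2, 1, 0.6))  # off-diagonals = 0.6
#' @export
converged_rpcn_weights <- function(Sigma) {
  W <- diag(nrow(Sigma)) - l_rpcn(Sigma)$L
  diag(W) <- 0
  W
}

#' Check the metric-learning description of a trained rPCN
#'
#' Compares the energy of a trained network on queries against the closed-form
#' prediction \eqn{\tfrac12\|L_{rPCN}(\hat\Sigma)(q - \bar x)\|_2^2}, where
#' \eqn{\hat\Sigma} is the training-sample covariance (1/N normalisation,
#' immaterial since \eqn{L_{rPCN}} is scale invariant) and \eqn{\bar x} the
#' sample mean. The factor 1/2 matches the network energy convention; the bias
#' generalises the centered statement because \eqn{\nu} converges to
#' \eqn{(I - W^*)\bar x}.
#'
#' @param object a trained \code{\link{rpcn}} (tight convergence tolerance
#'   recommended).
#' @param x the training patterns; defaults to those stored in the fit.
#' @param q query pattern(s).
#' @return list with the network energies (\code{lhs}), closed-form energies
#'   (\code{rhs}), and per-query relative errors (\code{rel_err}).
#' @export
theorem1_check <- function(object, x = NULL, q) {
  X <- if (is.null(x)) object$x else as_pattern_matrix(x, d = object$d)
  xbar <- rowMeans(X)
  Sh <- tcrossprod(X - xbar) / ncol(X)
  tr <- l_rpcn(Sh, center = xbar)
  lhs <- rpcn_energy(object, q)
  rhs <- 0.5 * metric_distance(tr, q)
  denom <- pmax(abs(rhs), .Machine$double.eps)
  list(lhs = lhs, rhs = rhs, rel_err = abs(lhs - rhs) / denom)
}
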