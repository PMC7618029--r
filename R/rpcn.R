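#' Fit a recurrent predictive coding network
#'
#' Trains the single-layer recurrent predictive coding network (rPCN) on a set
#' of patterns. Each value neuron is predicted from the others through a
#' recurrent weight matrix \eqn{W} (zero diagonal, so a neuron never predicts
#' itself) plus a bias \eqn{\nu}; the error neurons carry
#' \eqn{\varepsilon = x - W x - \nu} and learning performs gradient descent on
#' the energy \eqn{E = \tfrac12 \|\varepsilon\|_2^2}:
#' \deqn{\Delta \nu = \alpha\,\bar\varepsilon, \qquad
#'       \Delta W = \alpha\,\overline{\varepsilon x^\top}\ \ (\mathrm{diag}=0).}
#' Both rules are local (a product of pre- and postsynaptic activity). After
#' training, the energy of a query is its novelty signal: low energy means
#' familiar.
#'
#' With the default \code{batch_size = NULL} the full-batch gradient is used,
#' computed from the sufficient statistics \eqn{XX^\top/N} and \eqn{\bar x}
#' (identical to averaging the per-pattern updates, but O(d^3) per epoch
#' instead of O(d^2 N)). Smaller batches fall back to explicit sequential
#' mini-batch updates, which is what the repetition-suppression experiment
#' uses with a single pattern.
#'
#' @param x patterns: a \code{\link{pattern_set}} or \code{d x N} matrix.
#' @param alpha learning rate. \code{NULL} (default) picks
#'   \eqn{0.9/(\lambda_{max}+1)} from a power-iteration estimate of the top
#'   eigenvalue of \eqn{XX^\top/N}, which keeps full-batch descent stable.
#' @param batch_size patterns per update; \code{NULL} means full batch.
#' @param max_epochs maximum number of passes over the data.
#' @param tol stop when the relative change of mean energy over an epoch falls
#'   below this; non-convergence is recorded in the fit, not an error.
#' @param trace_errors if \code{TRUE}, record the per-neuron mean absolute
#'   error after every epoch (for repetition-suppression plots).
#' @return An object of class \code{"rpcn"}: list with weights \code{W}
#'   (\code{diag(W) = 0}), bias \code{nu}, learning rate \code{alpha},
#'   \code{trace} (mean energy per epoch, starting at the untrained state),
#'   \code{abs_err} (optional \code{d x epochs} matrix), \code{converged},
#'   \code{epochs}, and the training data.
#' @seealso \code{\link{rpcn_energy}}, \code{\link{theorem1_check}},
#'   \code{\link{converged_rpcn_weights}}
#' @examples
#' ps <- sample_gaussian(20, 100, pairwise_cov = 0.4, seed = 1)
#' fit <- rpcn(ps)
#' novel <- sample_gaussian(20, 50, pairwise_cov = 0.4, seed = 2)
#' mean(predict(fit, ps)) < mean(predict(fit, novel))
#' @export
rpcn <- function(x, alpha = NULL, batch_size = NULL, max_epochs = 10000L,
                 tol = 1e-8, trace_errors = FALSE) {
  X <- as_pattern_matrix(x)
  d <- nrow(X); N <- ncol(X)
  if (N == 0L) stop("cannot train on an empty pattern set")
  full_batch <- is.null(batch_size) || batch_size >= N
  # sufficient-statistics path pays off once N exceeds d; both are the same update
  use_stats <- full_batch && N >= d
  Sxx <- tcrossprod(X) / N
  xbar <- rowMeans(X)
  if (is.null(alpha)) {
    v <- rep(1, d) / sqrt(d)
    for (i in 1:60) { v <- Sxx %*% v; v <- v / sqrt(sum(v^2)) }
    alpha <- 0.9 / (as.numeric(crossprod(v, Sxx %*% v)) + 1)
  }
  if (alpha <= 0) stop("'alpha' must be positive")

  W <- matrix(0, d, d); nu <- numeric(d)
  energy <- numeric(0)
  abs_err <- if (trace_errors) matrix(0, d, 0) else NULL
  converged <- FALSE

  record <- function() {
    if (use_stats && !trace_errors) {
      A <- diag(d) - W
      en <- 0.5 * (sum(A * (A %*% Sxx)) - 2 * sum(nu * (A %*% xbar)) + sum(nu^2))
    } else {
      E <- X - W %*% X - nu
      en <- 0.5 * mean(colSums(E^2))
      if (trace_errors) abs_err <<- cbind(abs_err, rowMeans(abs(E)))
    }
    energy[length(energy) + 1L] <<- en
  }

  record()  # untrained state (epoch 0)
  for (e in seq_len(max_epochs)) {
    if (use_stats) {
      A <- diag(d) - W
      Gw <- A %*% Sxx - tcrossprod(nu, xbar)      # mean eps x^T
      gnu <- as.vector(A %*% xbar) - nu           # mean eps
      diag(Gw) <- 0
      W <- W + alpha * Gw
      nu <- nu + alpha * gnu
    } else {
      starts <- seq(1L, N, by = if (full_batch) N else batch_size)
      for (s in starts) {
        j <- s:min(s + batch_size - 1L, N)
        B <- X[, j, drop = FALSE]
        E <- B - W %*% B - nu
        Gw <- tcrossprod(E, B) / length(j)
        diag(Gw) <- 0
        W <- W + alpha * Gw
        nu <- nu + alpha * rowMeans(E)
      }
    }
    record()
    n <- length(energy)
    if (abs(energy[n - 1L] - energy[n]) <= tol * max(energy[n - 1L], 1e-300)) {
      converged <- TRUE
      break
    }
  }

  structure(list(W = W, nu = nu, alpha = alpha, d = d, N = N,
                 trace = energy, abs_err = abs_err,
                 epochs = length(energy) - 1L, converged = converged,
                 tol = tol, xbar = xbar, x = X, call = match.call()),
            class = "rpcn")
}

#' Prediction errors of an rPCN
#'
#' The error-neuron activities \eqn{\varepsilon = x - W x - \nu} for one or
#' more patterns. Entries are unconstrained in sign.
#'
#' @param object an \code{\link{rpcn}} fit, or any list with elements \code{W}
#'   and \code{nu}.
#' @param x query pattern(s): vector, matrix (columns are patterns) or
#'   \code{pattern_set}.
#' @return matrix of errors, one column per query.
#' @export
rpcn_errors <- function(object, x) {
  Q <- as_pattern_matrix(x, d = nrow(object$W))
  Q - object$W %*% Q - object$nu
}

#' rPCN energy (novelty signal)
#'
#' \eqn{E(q) = \tfrac12 \|q - W q - \nu\|_2^2}: the post-training energy of a
#' query, read out as its novelty. Exactly \eqn{\tfrac12\|\varepsilon\|^2}.
#'
#' @inheritParams rpcn_errors
#' @param q query pattern(s).
#' @return numeric vector of nonnegative energies, one per query.
#' @export
rpcn_energy <- function(object, q) {
  E <- rpcn_errors(object, q)
  0.5 * colSums(E^2)
}

#' One batch update of an rPCN
#'
#' Applies a single Hebbian learning step on a batch:
#' \eqn{\Delta\nu = \alpha\,\bar\varepsilon},
#' \eqn{\Delta W = \alpha\,\overline{\varepsilon x^\top}} with the diagonal
#' zeroed afterwards, so \code{diag(W)} stays exactly 0.
#'
#' @param object an \code{\link{rpcn}} fit or list with \code{W}, \code{nu},
#'   \code{alpha}.
#' @param batch nonempty patterns (matrix or \code{pattern_set}).
#' @param alpha optional learning-rate override.
#' @return the updated object (same shape as the input list).
#' @export
rpcn_update <- function(object, batch, alpha = NULL) {
  B <- as_pattern_matrix(batch, d = nrow(object$W))
  if (ncol(B) == 0L) stop("empty batch")
  a <- if (is.null(alpha)) object$alpha else alpha
  E <- B - object$W %*% B - object$nu
  Gw <- tcrossprod(E, B) / ncol(B)
  diag(Gw) <- 0
  object$W <- object$W + a * Gw
  object$nu <- object$nu + a * rowMeans(E)
  object
}

#' @export
print.rpcn <- function(x, ...) {
  cat(sprintf("Recurrent predictive coding network (d = %d, N = %d)\n", x$d, x$N))
  cat(sprintf("  alpha = %.4g, epochs = %d, %s (tol %.1g)\n", x$alpha, x$epochs,
              if (x$converged) "converged" else "NOT converged", x$tol))
  cat(sprintf("  mean training energy: %.4g -> %.4g\n",
              x$trace[1], x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
summary.rpcn <- function(object, ...) {
  fam <- rpcn_energy(object, object$x)
  out <- list(d = object$d, N = object$N, alpha = object$alpha,
              epochs = object$epochs, converged = object$converged,
              initial_energy = object$trace[1],
              final_energy = object$trace[length(object$trace)],
              familiar_energy = summary(fam),
              max_abs_diag = max(abs(diag(object$W))))
  class(out) <- "summary.rpcn"
  out
}

#' @export
print.summary.rpcn <- function(x, ...) {
  cat(sprintf("rPCN fit: d = %d, N = %d, alpha = %.4g\n", x$d, x$N, x$alpha))
  cat(sprintf("  %d epochs, %s; mean energy %.4g -> %.4g\n", x$epochs,
              if (x$converged) "converged" else "not converged",
              x$initial_energy, x$final_energy))
  cat("  energy on training patterns:\n")
  print(x$familiar_energy)
  invisible(x)
}

#' @export
coef.rpcn <- function(object, ...) list(W = object$W, nu = object$nu)

#' Novelty energies for queries
#'
#' @param object an \code{\link{rpcn}} fit.
#' @param newdata query patterns; defaults to the training set.
#' @param type \code{"energy"} for the scalar novelty signal per query,
#'   \code{"errors"} for the full error-neuron activity matrix.
#' @param ... unused.
#' @return numeric vector of energies, or a matrix of errors.
#' @export
predict.rpcn <- function(object, newdata = NULL, type = c("energy", "errors"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$x
  if (type == "energy") rpcn_energy(object, newdata) else rpcn_errors(object, newdata)
}

#' @export
residuals.rpcn <- function(object, ...) rpcn_errors(object, object$x)

#' @export
plot.rpcn <- function(x, log = "y", ...) {
  graphics::plot(seq_along(x$trace) - 1L, pmax(x$trace, .Machine$double.xmin),
                 type = "l", log = log, xlab = "epoch",
                 ylab = "mean training energy", ...)
  invisible(x)
}
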