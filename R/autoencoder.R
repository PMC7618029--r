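#' Parameter-matched hidden size
#'
#' Hidden-layer size making a one-hidden-layer autoencoder's parameter count
#' approximately equal to the recurrent network's \eqn{d^2 - d + d}
#' parameters. For the plain autoencoder (params \eqn{2dh + h + d}) this is
#' \eqn{h = (d^2 - d)/(2d + 1)}; the variational model carries an extra
#' log-variance head (\eqn{dh + h} more parameters), giving
#' \eqn{h = (d^2 - d)/(3d + 2)}. A minimum of 1 is enforced.
#'
#' @param d input dimension, at least 2.
#' @param variational match the variational architecture's count.
#' @return integer hidden size.
#' @examples
#' param_matched_hidden(500)  # about d/2
#' @export
param_matched_hidden <- function(d, variational = FALSE) {
  if (d < 2) stop("'d' must be at least 2")
  h <- if (variational) round((d^2 - d) / (3 * d + 2)) else round((d^2 - d) / (2 * d + 1))
  max(1L, as.integer(h))
}

ae_param_count <- function(d, h, variational = FALSE) {
  n <- 2 * d * h + h + d
  if (variational) n <- n + d * h + h
  n
}

#' Fit a one-hidden-layer (variational) autoencoder
#'
#' Novelty-detection baseline: a single-hidden-layer autoencoder with tanh
#' hidden units and linear output, trained by full-batch gradient descent on
#' the mean squared reconstruction error. After training, the reconstruction
#' error of a query is its energy (novelty signal). The variational variant
#' adds a linear log-variance head, samples the hidden state
#' \eqn{z = \mu + e^{\lambda/2}\epsilon} during training and testing, and adds
#' a KL penalty toward a unit Gaussian prior; the sampling inflates the
#' variability of the reconstruction error at test time, which is the
#' behavioural difference the benchmark cares about. Hidden size defaults to
#' \code{\link{param_matched_hidden}} so parameter counts match the recurrent
#' network within 5\%.
#'
#' @param x training patterns (\code{pattern_set} or \code{d x N} matrix).
#' @param variational fit the variational model.
#' @param hidden hidden-layer size; default parameter-matched.
#' @param alpha gradient-descent learning rate.
#' @param epochs number of full-batch epochs.
#' @param kl_weight weight of the KL term (variational only).
#' @param n_samples latent samples averaged per query at test time
#'   (variational only).
#' @param seed RNG seed for weight initialisation and latent sampling.
#' @return object of class \code{"autoencoder"} with the weights, the loss
#'   trace and the configuration.
#' @export
autoencoder <- function(x, variational = FALSE, hidden = NULL, alpha = 0.05,
                        epochs = 500L, kl_weight = 0.01, n_samples = 5L,
                        seed = NULL) {
  X <- as_pattern_matrix(x)
  d <- nrow(X); N <- ncol(X)
  if (N == 0L) stop("cannot train on an empty pattern set")
  h <- if (is.null(hidden)) param_matched_hidden(d, variational) else as.integer(hidden)

  with_seed(seed, {
    W1 <- matrix(stats::rnorm(h * d, sd = 1 / sqrt(d)), h, d); b1 <- numeric(h)
    W2 <- matrix(stats::rnorm(d * h, sd = 1 / sqrt(h)), d, h); b2 <- numeric(d)
    Wv <- if (variational) matrix(stats::rnorm(h * d, sd = 1 / sqrt(d)), h, d) else NULL
    bv <- if (variational) numeric(h) else NULL
    loss <- numeric(epochs)

    for (e in seq_len(epochs)) {
      Mu <- tanh(W1 %*% X + b1)
      if (variational) {
        Lv <- Wv %*% X + bv
        S <- exp(0.5 * Lv)
        Eps <- matrix(stats::rnorm(h * N), h, N)
        Z <- Mu + S * Eps
      } else Z <- Mu
      R <- (W2 %*% Z + b2) - X                 # reconstruction residual
      l <- 0.5 * sum(R^2) / N
      if (variational) l <- l + kl_weight * 0.5 * sum(exp(Lv) + Mu^2 - 1 - Lv) / N
      if (!is.finite(l))
        stop(sprintf("autoencoder training diverged at epoch %d (loss not finite); reduce 'alpha'", e))
      loss[e] <- l

      dR <- R / N
      gW2 <- tcrossprod(dR, Z); gb2 <- rowSums(dR)
      dZ <- crossprod(W2, dR)
      if (variational) {
        dMu <- dZ + kl_weight * Mu / N
        dLv <- dZ * Eps * S * 0.5 + kl_weight * 0.5 * (exp(Lv) - 1) / N
        dPre <- dMu * (1 - Mu^2)
        gWv <- tcrossprod(dLv, X); gbv <- rowSums(dLv)
        Wv <- Wv - alpha * gWv; bv <- bv - alpha * gbv
      } else dPre <- dZ * (1 - Z^2)
      gW1 <- tcrossprod(dPre, X); gb1 <- rowSums(dPre)
      W1 <- W1 - alpha * gW1; b1 <- b1 - alpha * gb1
      W2 <- W2 - alpha * gW2; b2 <- b2 - alpha * gb2
    }

    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, Wv = Wv, bv = bv,
                   d = d, hidden = h, N = N, variational = variational,
                   alpha = alpha, epochs = epochs, kl_weight = kl_weight,
                   n_samples = as.integer(n_samples), loss = loss,
                   n_params = ae_param_count(d, h, variational),
                   call = match.call()),
              class = "autoencoder")
  })
}

#' Reconstruction-error energy
#'
#' \eqn{E(q) = \tfrac12 \|q - \mathrm{dec}(\mathrm{enc}(q))\|_2^2}. For the
#' variational model the hidden state is sampled and the energy is the mean
#' over \code{n_samples} latent draws (so repeated calls are stochastic unless
#' a seed is supplied); the plain autoencoder is deterministic.
#'
#' @param object a fitted \code{\link{autoencoder}}.
#' @param q query pattern(s).
#' @param n_samples latent draws for the variational model (default from fit).
#' @param seed optional RNG seed for the latent draws.
#' @return numeric vector of energies, one per query.
#' @export
recon_energy <- function(object, q, n_samples = NULL, seed = NULL) {
  Q <- as_pattern_matrix(q, d = object$d)
  Mu <- tanh(object$W1 %*% Q + object$b1)
  if (!object$variational) {
    R <- (object$W2 %*% Mu + object$b2) - Q
    return(0.5 * colSums(R^2))
  }
  ns <- if (is.null(n_samples)) object$n_samples else as.integer(n_samples)
  Lv <- object$Wv %*% Q + object$bv
  S <- exp(0.5 * Lv)
  with_seed(seed, {
    acc <- numeric(ncol(Q))
    for (k in seq_len(ns)) {
      Z <- Mu + S * matrix(stats::rnorm(length(Mu)), nrow(Mu), ncol(Mu))
      R <- (object$W2 %*% Z + object$b2) - Q
      acc <- acc + 0.5 * colSums(R^2)
    }
    acc / ns
  })
}

#' @export
predict.autoencoder <- function(object, newdata, n_samples = NULL, seed = NULL, ...) {
  recon_energy(object, newdata, n_samples = n_samples, seed = seed)
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("%s (d = %d, hidden = %d, %d parameters)\n",
              if (x$variational) "Variational autoencoder" else "Autoencoder",
              x$d, x$hidden, x$n_params))
  cat(sprintf("  %d epochs, final loss %.4g\n", x$epochs, x$loss[length(x$loss)]))
  invisible(x)
}

#' @export
coef.autoencoder <- function(object, ...) {
  out <- list(W1 = object$W1, b1 = object$b1, W2 = object$W2, b2 = object$b2)
  if (object$variational) { out$Wv <- object$Wv; out$bv <- object$bv }
  out
}
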