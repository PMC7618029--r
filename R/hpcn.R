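nonlinearity_fns <- function(name) {
  switch(name,
    tanh = list(f = tanh, fp = function(x) 1 - tanh(x)^2),
    identity = list(f = identity, fp = function(x) array(1, dim = dim(x)) ),
    relu = list(f = function(x) pmax(x, 0), fp = function(x) (x > 0) * 1),
    stop(sprintf("unknown nonlinearity '%s' (use tanh, identity or relu)", name)))
}

#' Local-connectivity mask
#'
#' Binary connectivity mask restricting each neuron of a \code{out_side^2}
#' layer to a contiguous \code{patch x patch} receptive field in an
#' \code{in_side^2} layer, tiled at stride 1 (so
#' \code{out_side = in_side - patch + 1}). Mimics the limited receptive
#' fields of early visual neurons.
#'
#' @param in_side side length of the (square) input layer.
#' @param out_side side length of the output layer.
#' @param patch receptive-field side length.
#' @return binary matrix of dimension \code{in_side^2 x out_side^2}; every
#'   column has exactly \code{patch^2} ones.
#' @examples
#' m <- make_local_mask(9, 1, 9)  # single all-ones patch
#' @export
make_local_mask <- function(in_side, out_side, patch) {
  in_side <- as.integer(in_side); out_side <- as.integer(out_side)
  patch <- as.integer(patch)
  if (out_side != in_side - patch + 1L)
    stop(sprintf("incompatible geometry: need out_side = in_side - patch + 1 (got %d, expected %d)",
                 out_side, in_side - patch + 1L))
  M <- matrix(0, in_side^2, out_side^2)
  off <- seq_len(patch) - 1L
  for (c0 in seq_len(out_side)) {
    xs <- c0 + off
    for (r0 in seq_len(out_side)) {
      ys <- r0 + off
      j <- r0 + (c0 - 1L) * out_side
      M[as.vector(outer(ys, (xs - 1L) * in_side, "+")), j] <- 1
    }
  }
  M
}

# Iterative inference on value neurons with layer 0 clamped to Q.
# weights[[l]]: s_{l-1} x s_l predicting layer l-1 from f(x^l); nu: top bias.
# Returns activities, errors, per-layer per-query energies E^l = 0.5||eps^l||^2.
infer_core <- function(weights, nu, f, fp, Q, step, max_steps, tol,
                       guard = 1e12, x_init = NULL) {
  L <- length(weights); B <- ncol(Q)
  xs <- vector("list", L + 1L)
  xs[[1L]] <- Q
  for (l in seq_len(L)) {
    xs[[l + 1L]] <- if (!is.null(x_init)) x_init[[l]]
    else matrix(0, ncol(weights[[l]]), B)
  }
  eps <- vector("list", L + 1L)
  layerE <- NULL
  prev <- Inf; steps <- 0L; converged <- FALSE
  repeat {
    for (l in seq_len(L)) eps[[l]] <- xs[[l]] - weights[[l]] %*% f(xs[[l + 1L]])
    eps[[L + 1L]] <- xs[[L + 1L]] - nu
    layerE <- do.call(rbind, lapply(eps, function(e) 0.5 * colSums(e^2)))
    tot <- mean(colSums(layerE))
    if (!is.finite(tot) || tot > guard)
      stop(sprintf("inference diverged (mean energy %.3g after %d steps); reduce 'infer_step'",
                   tot, steps))
    if (is.finite(prev) && abs(prev - tot) <= tol * max(prev, 1e-300)) {
      converged <- TRUE
      break
    }
    if (steps >= max_steps) break
    prev <- tot
    for (l in seq_len(L))
      xs[[l + 1L]] <- xs[[l + 1L]] +
        step * (-eps[[l + 1L]] + fp(xs[[l + 1L]]) * crossprod(weights[[l]], eps[[l]]))
    steps <- steps + 1L
  }
  rownames(layerE) <- paste0("layer", seq_len(L + 1L) - 1L)
  list(activities = xs, errors = eps, layer_energies = layerE,
       total_energy = colSums(layerE), steps_used = steps, converged = converged)
}

#' Fit a hierarchical predictive coding network
#'
#' Trains a hierarchical predictive coding network (hPCN): layer \eqn{l}
#' activities \eqn{x^l} are predicted top-down,
#' \eqn{\varepsilon^l = x^l - W^{l+1} f(x^{l+1})} for \eqn{l < L} and
#' \eqn{\varepsilon^L = x^L - \nu}, and the total energy is
#' \eqn{E = \sum_{l=0}^{L} \tfrac12 \|\varepsilon^l\|^2} (the sensory layer is
#' included, since its energy is part of the novelty readout). For each
#' training batch, layer 0 is clamped to the input and the hidden activities
#' run gradient descent on the energy,
#' \eqn{\dot x^l = -\varepsilon^l + f'(x^l)\odot (W^l)^\top \varepsilon^{l-1}},
#' until convergence; the weights then take one local Hebbian step
#' \eqn{\Delta W^l = \alpha\,\varepsilon^{l-1} f(x^l)^\top} (masked entries
#' stay exactly zero) and \eqn{\Delta\nu = \alpha\,\bar\varepsilon^L}.
#'
#' Training is full-batch by default with inference warm-started from the
#' previous epoch's converged activities (the energy landscape moves only
#' slightly per weight step, so inference then needs few iterations);
#' \code{batch_size = 1} recovers strict per-pattern updates.
#'
#' @param x training patterns (\code{pattern_set} or \code{d x N} matrix).
#' @param layer_sizes integer vector \code{c(s0, ..., sL)}; \code{s0} must
#'   equal the pattern dimension.
#' @param masks optional list of binary connectivity masks, entry \code{l}
#'   (possibly \code{NULL}) of dimension \code{s(l-1) x s(l)} constraining
#'   \code{W^l}; see \code{\link{make_local_mask}}.
#' @param nonlinearity \code{"tanh"} (default), \code{"identity"} or
#'   \code{"relu"}.
#' @param alpha weight learning rate.
#' @param epochs maximum number of weight updates (epochs).
#' @param tol stop when the relative change of mean total energy between
#'   epochs falls below this.
#' @param batch_size patterns per weight update; \code{NULL} = full batch.
#' @param infer_step inference step size \eqn{\eta}.
#' @param infer_max_steps,infer_tol inference iteration budget and
#'   relative-energy convergence tolerance.
#' @param init_scale weight initialisation scale multiplier (weights are
#'   Gaussian with sd \code{init_scale/sqrt(fan-in)}).
#' @param seed RNG seed for weight initialisation.
#' @param trace_errors record the distribution of absolute error-neuron
#'   activities (all layers pooled: quartiles and range) each epoch.
#' @return object of class \code{"hpcn"}: weights, \code{nu}, configuration,
#'   \code{trace} (mean total energy per epoch, entry 1 = untrained weights)
#'   and, if requested, \code{abs_err} (5 x epochs matrix of min/quartiles/max).
#' @seealso \code{\link{hpcn_infer}}, \code{\link{hierarchy_report}}
#' @export
hpcn <- function(x, layer_sizes, masks = NULL,
                 nonlinearity = c("tanh", "identity", "relu"),
                 alpha = 0.01, epochs = 200L, tol = 1e-7, batch_size = NULL,
                 infer_step = 0.05, infer_max_steps = 200L, infer_tol = 1e-8,
                 init_scale = 1, seed = NULL, trace_errors = FALSE) {
  X <- as_pattern_matrix(x)
  nonlinearity <- match.arg(nonlinearity)
  fns <- nonlinearity_fns(nonlinearity)
  sizes <- as.integer(layer_sizes)
  L <- length(sizes) - 1L
  if (L < 1L) stop("'layer_sizes' needs at least one hidden layer")
  if (sizes[1L] != nrow(X))
    stop(sprintf("layer 0 size (%d) must match pattern dimension (%d)", sizes[1L], nrow(X)))
  if (alpha <= 0 || infer_step <= 0) stop("'alpha' and 'infer_step' must be positive")
  N <- ncol(X)
  if (N == 0L) stop("cannot train on an empty pattern set")
  if (!is.null(masks)) {
    if (length(masks) != L) stop("'masks' must have one entry (or NULL) per weight matrix")
    for (l in seq_len(L)) if (!is.null(masks[[l]])) {
      m <- masks[[l]]
      if (!all(dim(m) == c(sizes[l], sizes[l + 1L])))
        stop(sprintf("mask %d must be %d x %d", l, sizes[l], sizes[l + 1L]))
      if (!all(m %in% c(0, 1))) stop("masks must be binary")
    }
  }

  weights <- with_seed(seed, lapply(seq_len(L), function(l) {
    W <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                             sd = init_scale / sqrt(sizes[l + 1L])),
                sizes[l], sizes[l + 1L])
    if (!is.null(masks) && !is.null(masks[[l]])) W * masks[[l]] else W
  }))
  nu <- numeric(sizes[L + 1L])

  full_batch <- is.null(batch_size) || batch_size >= N
  trace <- numeric(0)
  abs_err <- if (trace_errors) matrix(0, 5, 0) else NULL
  warm <- NULL
  converged <- FALSE

  run_infer <- function(Q, x_init = NULL)
    infer_core(weights, nu, fns$f, fns$fp, Q, infer_step, infer_max_steps,
               infer_tol, x_init = x_init)

  apply_update <- function(inf, B) {
    nb <- ncol(inf$activities[[1L]])
    for (l in seq_len(L)) {
      G <- tcrossprod(inf$errors[[l]], fns$f(inf$activities[[l + 1L]])) / nb
      if (!is.null(masks) && !is.null(masks[[l]])) G <- G * masks[[l]]
      weights[[l]] <<- weights[[l]] + alpha * G
    }
    nu <<- nu + alpha * rowMeans(inf$errors[[L + 1L]])
  }

  record <- function(inf) {
    trace[length(trace) + 1L] <<- mean(inf$total_energy)
    if (trace_errors) {
      a <- abs(unlist(lapply(inf$errors, as.vector)))
      abs_err <<- cbind(abs_err, stats::quantile(a, c(0, 0.25, 0.5, 0.75, 1)))
    }
  }

  inf <- run_infer(X)
  record(inf)
  for (e in seq_len(epochs)) {
    if (full_batch) {
      apply_update(inf, X)
      warm <- inf$activities[-1L]
      inf <- run_infer(X, x_init = warm)
    } else {
      starts <- seq(1L, N, by = batch_size)
      for (s in starts) {
        j <- s:min(s + batch_size - 1L, N)
        bi <- run_infer(X[, j, drop = FALSE])
        apply_update(bi, NULL)
      }
      inf <- run_infer(X)
    }
    record(inf)
    n <- length(trace)
    if (abs(trace[n - 1L] - trace[n]) <= tol * max(trace[n - 1L], 1e-300)) {
      converged <- TRUE
      break
    }
  }

  structure(list(weights = weights, nu = nu, masks = masks,
                 layer_sizes = sizes, L = L, nonlinearity = nonlinearity,
                 alpha = alpha, epochs = length(trace) - 1L,
                 converged = converged, tol = tol,
                 infer_step = infer_step, infer_max_steps = infer_max_steps,
                 infer_tol = infer_tol, trace = trace, abs_err = abs_err,
                 N = N, x = X, call = match.call()),
            class = "hpcn")
}

#' Layer-wise prediction errors from given activities
#'
#' Computes \eqn{\varepsilon^l = x^l - W^{l+1} f(x^{l+1})} (and
#' \eqn{\varepsilon^L = x^L - \nu}) for supplied activities, without running
#' inference.
#'
#' @param object a fitted \code{\link{hpcn}}.
#' @param activities list of \code{L + 1} activity vectors/matrices matching
#'   \code{layer_sizes}.
#' @return list of \code{L + 1} error matrices.
#' @export
hpcn_errors <- function(object, activities) {
  L <- object$L
  if (length(activities) != L + 1L) stop("need one activity block per layer (0..L)")
  xs <- lapply(activities, function(a) if (is.matrix(a)) a else matrix(a, ncol = 1L))
  for (l in seq_len(L + 1L))
    if (nrow(xs[[l]]) != object$layer_sizes[l])
      stop(sprintf("activity block %d has %d rows, expected %d",
                   l - 1L, nrow(xs[[l]]), object$layer_sizes[l]))
  f <- nonlinearity_fns(object$nonlinearity)$f
  eps <- vector("list", L + 1L)
  for (l in seq_len(L)) eps[[l]] <- xs[[l]] - object$weights[[l]] %*% f(xs[[l + 1L]])
  eps[[L + 1L]] <- xs[[L + 1L]] - object$nu
  eps
}

#' Run hPCN inference on queries
#'
#' Clamps layer 0 to the queries and relaxes the hidden activities by
#' gradient descent on the total energy until the relative energy change
#' falls below \code{infer_tol} (or the step budget is reached). The
#' layer-wise energies of the converged state are the multi-level novelty
#' readout: low-layer energy signals unfamiliar sensory detail, top-layer
#' energy signals an unfamiliar abstract (class-level) feature.
#'
#' @param object a fitted \code{\link{hpcn}}.
#' @param q query pattern(s).
#' @param x_init optional list of initial hidden activities (default zeros).
#' @param infer_step,infer_max_steps,infer_tol overrides of the fit settings.
#' @return list with \code{activities}, \code{errors},
#'   \code{layer_energies} (an \code{(L+1) x n} matrix of
#'   \eqn{E^l = \tfrac12\|\varepsilon^l\|^2} per query),
#'   \code{total_energy}, \code{steps_used} and \code{converged}.
#' @export
hpcn_infer <- function(object, q, x_init = NULL, infer_step = NULL,
                       infer_max_steps = NULL, infer_tol = NULL) {
  Q <- as_pattern_matrix(q, d = object$layer_sizes[1L])
  fns <- nonlinearity_fns(object$nonlinearity)
  infer_core(object$weights, object$nu, fns$f, fns$fp, Q,
             step = infer_step %||% object$infer_step,
             max_steps = infer_max_steps %||% object$infer_max_steps,
             tol = infer_tol %||% object$infer_tol,
             x_init = x_init)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hpcn <- function(x, ...) {
  cat(sprintf("Hierarchical predictive coding network: layers %s (%s)\n",
              paste(x$layer_sizes, collapse = "-"), x$nonlinearity))
  masked <- if (is.null(x$masks)) integer(0) else which(!vapply(x$masks, is.null, TRUE))
  if (length(masked))
    cat(sprintf("  locally connected weights: W%s\n", paste(masked, collapse = ", W")))
  cat(sprintf("  alpha = %.4g, %d epochs, %s; mean energy %.4g -> %.4g\n",
              x$alpha, x$epochs, if (x$converged) "converged" else "NOT converged",
              x$trace[1], x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
summary.hpcn <- function(object, ...) {
  inf <- hpcn_infer(object, object$x)
  out <- list(layer_sizes = object$layer_sizes,
              nonlinearity = object$nonlinearity,
              epochs = object$epochs, converged = object$converged,
              initial_energy = object$trace[1],
              final_energy = object$trace[length(object$trace)],
              layer_energy_means = rowMeans(inf$layer_energies))
  class(out) <- "summary.hpcn"
  out
}

#' @export
print.summary.hpcn <- function(x, ...) {
  cat(sprintf("hPCN fit: layers %s (%s), %d epochs, %s\n",
              paste(x$layer_sizes, collapse = "-"), x$nonlinearity, x$epochs,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  mean total energy %.4g -> %.4g\n", x$initial_energy, x$final_energy))
  cat("  mean layer energies on training set:\n")
  print(x$layer_energy_means)
  invisible(x)
}

#' @export
coef.hpcn <- function(object, ...) list(weights = object$weights, nu = object$nu)

#' Multi-level novelty energies for queries
#'
#' @param object a fitted \code{\link{hpcn}}.
#' @param newdata query patterns; defaults to the training set.
#' @param type \code{"energy"} for the total energy per query,
#'   \code{"layer_energy"} for the \code{(L+1) x n} matrix of per-layer
#'   energies \eqn{E^l = \tfrac12\|\varepsilon^l\|^2}.
#' @param ... passed to \code{\link{hpcn_infer}}.
#' @return numeric vector or matrix of energies.
#' @export
predict.hpcn <- function(object, newdata = NULL, type = c("energy", "layer_energy"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$x
  inf <- hpcn_infer(object, newdata, ...)
  if (type == "energy") inf$total_energy else inf$layer_energies
}

#' @export
residuals.hpcn <- function(object, ...) hpcn_infer(object, object$x)$errors

#' @export
plot.hpcn <- function(x, log = "y", ...) {
  graphics::plot(seq_along(x$trace) - 1L, pmax(x$trace, .Machine$double.xmin),
                 type = "l", log = log, xlab = "epoch",
                 ylab = "mean total energy", ...)
  invisible(x)
}
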