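#' Uniform-covariance matrix
#'
#' The covariance matrix with a common variance on the diagonal and a common
#' covariance \code{c} between every pair of distinct coordinates:
#' \eqn{\Sigma = (v - c) I + c \mathbf{1}\mathbf{1}^\top}. Its eigenvalues are
#' \eqn{v - c} (multiplicity \eqn{d-1}) and \eqn{v + (d-1)c}, so positive
#' definiteness requires \eqn{-v/(d-1) < c < v}.
#'
#' @param d dimension (number of coordinates), at least 1.
#' @param variance per-coordinate variance, positive. Default 1, so that
#'   \code{pairwise_cov} doubles as the pairwise correlation.
#' @param pairwise_cov common covariance between distinct coordinates.
#' @return a \code{d x d} symmetric positive-definite matrix.
#' @examples
#' uniform_cov_matrix(2, 1, 0.7)
#' @export
uniform_cov_matrix <- function(d, variance = 1, pairwise_cov = 0) {
  d <- as.integer(d)
  if (d < 1L) stop("'d' must be at least 1")
  if (variance <= 0) stop("'variance' must be positive")
  lo <- if (d > 1L) -variance / (d - 1) else -Inf
  if (pairwise_cov <= lo || pairwise_cov >= variance)
    stop(sprintf(
      "'pairwise_cov' must lie in (-variance/(d-1), variance) = (%g, %g) for positive definiteness",
      lo, variance))
  S <- matrix(pairwise_cov, d, d)
  diag(S) <- variance
  S
}

#' Sample correlated Gaussian patterns
#'
#' Draws \code{n} i.i.d. patterns from a zero-mean (optionally shifted)
#' multivariate Gaussian whose covariance is \code{\link{uniform_cov_matrix}}.
#' This is the stimulus ensemble used in the capacity experiments:
#' uncorrelated pixels (\code{pairwise_cov = 0}) or uniformly correlated
#' pixels (e.g. a 0.4 covariance between any two coordinates).
#'
#' @param d dimension of each pattern.
#' @param n number of patterns (0 gives an explicit empty set).
#' @param variance,pairwise_cov passed to \code{\link{uniform_cov_matrix}}.
#' @param mean optional mean vector (length \code{d}) or scalar; default 0.
#' @param seed RNG seed; identical seeds give bit-identical output and the
#'   ambient RNG stream is left untouched. \code{NULL} uses the current stream.
#' @return a \code{\link{pattern_set}} with \code{d} rows and \code{n} columns.
#' @examples
#' ps <- sample_gaussian(10, 5, pairwise_cov = 0.4, seed = 1)
#' @export
sample_gaussian <- function(d, n, variance = 1, pairwise_cov = 0, mean = 0,
                            seed = NULL) {
  n <- as.integer(n)
  if (n < 0L) stop("'n' must be nonnegative")
  S <- uniform_cov_matrix(d, variance, pairwise_cov)
  mu <- rep_len(mean, d)
  if (n == 0L) return(pattern_set(matrix(numeric(0), nrow = d, ncol = 0)))
  X <- with_seed(seed, t(MASS::mvrnorm(n, mu = mu, Sigma = S)))
  if (n == 1L) X <- matrix(X, ncol = 1L)
  pattern_set(X)
}

# bilinear lookup of img (side x side, rows = y) at fractional coords (ys, xs);
# coordinates are clamped to the image border
bilinear_sample <- function(img, ys, xs) {
  side <- nrow(img)
  ys <- pmin(pmax(ys, 1), side)
  xs <- pmin(pmax(xs, 1), side)
  y0 <- pmin(floor(ys), side - 1L); x0 <- pmin(floor(xs), side - 1L)
  fy <- ys - y0; fx <- xs - x0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - fy) * (1 - fx) + img[i10] * fy * (1 - fx) +
    img[i01] * (1 - fy) * fx + img[i11] * fy * fx
}

# smooth random scalar field on a side x side grid: a coarse Gaussian grid
# bilinearly upsampled, unit marginal scale
smooth_field <- function(side, coarse = 4L) {
  g <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  pos <- seq(1, coarse, length.out = side)
  bilinear_sample(g, rep(pos, times = side), rep(pos, each = side))
}

# deterministic stroke-based prototype: superposed oriented bars with a
# Gaussian cross-profile, normalised to [0, 1]
class_prototype <- function(side, n_strokes = 3L) {
  yy <- rep(seq_len(side), times = side)
  xx <- rep(seq_len(side), each = side)
  img <- numeric(side * side)
  for (k in seq_len(n_strokes)) {
    cy <- stats::runif(1, 0.25 * side, 0.75 * side)
    cx <- stats::runif(1, 0.25 * side, 0.75 * side)
    th <- stats::runif(1, 0, pi)
    len <- stats::runif(1, 0.5, 0.9) * side / 2
    width <- stats::runif(1, 0.06, 0.12) * side
    # signed coords along / across the stroke
    u <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
    v <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
    along <- pmax(abs(u) - len, 0)
    img <- img + exp(-(v^2 + along^2) / (2 * width^2))
  }
  img <- matrix(img, side, side)
  img / max(img)
}

#' Procedurally generated class-structured images
#'
#' A synthetic stand-in for handwritten-digit classes: each class has a fixed
#' smooth prototype (superposed oriented strokes placed deterministically from
#' the seed), and exemplars are the prototype warped by a smooth random
#' deformation field plus additive pixel noise, clipped to [0, 1] and flattened
#' to \code{side^2}-vectors. With zero deformation and zero noise all
#' exemplars of a class equal its prototype.
#'
#' @param side image side length in pixels (at least 9, so that downstream
#'   9x9 local receptive fields are well defined).
#' @param n_classes number of classes.
#' @param per_class exemplars generated per class.
#' @param deform_amplitude scale (in pixels) of the smooth within-class
#'   deformation. The default of 2 gives a within-class spread comparable to
#'   the variation among handwritten exemplars of one digit.
#' @param noise_sd standard deviation of additive pixel noise. Default 0.05.
#' @param seed RNG seed (prototypes and exemplars are reproducible under it).
#' @return a \code{\link{pattern_set}} with \code{d = side^2} rows,
#'   \code{n_classes * per_class} columns and labels in
#'   \code{0, ..., n_classes - 1}.
#' @examples
#' ps <- make_class_images(side = 9, n_classes = 2, per_class = 3, seed = 1)
#' @export
make_class_images <- function(side = 20L, n_classes = 2L, per_class = 50L,
                              deform_amplitude = 2, noise_sd = 0.05,
                              seed = NULL) {
  side <- as.integer(side)
  if (side < 9L) stop("'side' must be at least 9 (9x9 local receptive fields)")
  if (n_classes < 1L || per_class < 0L) stop("invalid class/exemplar counts")
  if (deform_amplitude < 0 || noise_sd < 0) stop("amplitudes must be nonnegative")
  with_seed(seed, {
    yy <- rep(seq_len(side), times = side)
    xx <- rep(seq_len(side), each = side)
    cols <- vector("list", n_classes)
    for (k in seq_len(n_classes)) {
      proto <- class_prototype(side)
      ex <- matrix(0, side * side, per_class)
      for (j in seq_len(per_class)) {
        if (deform_amplitude > 0) {
          dy <- deform_amplitude * smooth_field(side)
          dx <- deform_amplitude * smooth_field(side)
          img <- bilinear_sample(proto, yy + dy, xx + dx)
        } else img <- proto[cbind(yy, xx)]
        if (noise_sd > 0) img <- img + stats::rnorm(length(img), sd = noise_sd)
        ex[, j] <- pmin(pmax(img, 0), 1)
      }
      cols[[k]] <- ex
    }
    pattern_set(do.call(cbind, cols),
                labels = rep(seq_len(n_classes) - 1L, each = per_class))
  })
}

#' Split patterns into familiar (training) and held-out novel sets
#'
#' Implements the held-out-query protocol: a random disjoint split of the
#' columns into \code{n_train} familiar patterns and the remaining novel ones,
#' deterministic under \code{seed}.
#'
#' @param x a \code{\link{pattern_set}} or pattern matrix.
#' @param n_train number of training (familiar) patterns, at most \code{N}.
#' @param seed RNG seed for the permutation.
#' @return list with \code{pattern_set} elements \code{train} and \code{novel}.
#' @export
split_familiar_novel <- function(x, n_train, seed = NULL) {
  m <- as_pattern_matrix(x)
  labels <- if (inherits(x, "pattern_set")) x$labels else NULL
  N <- ncol(m)
  n_train <- as.integer(n_train)
  if (n_train > N) stop(sprintf("n_train (%d) exceeds the number of patterns (%d)", n_train, N))
  idx <- with_seed(seed, sample.int(N, n_train))
  rest <- setdiff(seq_len(N), idx)
  list(train = pattern_set(m[, idx, drop = FALSE], labels[idx]),
       novel = pattern_set(m[, rest, drop = FALSE], labels[rest]))
}
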