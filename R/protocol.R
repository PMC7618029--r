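#' Two-alternative forced-choice error probability
#'
#' The Standing-style familiarity task: each familiar item is paired with one
#' novel item (random pairing under \code{pairing_seed}; novel energies are
#' sampled with replacement only if there are fewer novel than familiar
#' items), and the model is scored as choosing the item with the lower
#' energy. A pair where the familiar energy exceeds the novel one is an
#' error; an exact tie scores half. Chance performance is 0.5. The error is
#' invariant to any strictly increasing transform applied jointly to all
#' energies.
#'
#' @param familiar_energy,novel_energy nonempty numeric vectors of energies.
#' @param pairing_seed RNG seed for the pairing.
#' @return error probability in [0, 1].
#' @export
twoafc_error <- function(familiar_energy, novel_energy, pairing_seed = NULL) {
  if (length(familiar_energy) == 0L || length(novel_energy) == 0L)
    stop("both energy vectors must be nonempty")
  nov <- with_seed(pairing_seed,
    novel_energy[sample(length(novel_energy), length(familiar_energy),
                        replace = length(novel_energy) < length(familiar_energy))])
  mean(familiar_energy > nov) + 0.5 * mean(familiar_energy == nov)
}

#' Patterns retained in memory
#'
#' Converts a 2AFC error probability into an effective count of remembered
#' items via the standard two-alternative correction for guessing:
#' \eqn{N (1 - 2 p_{err})}, clipped below at zero. Chance-level error retains
#' nothing; perfect discrimination retains all \code{N}.
#'
#' @param N number of presented patterns.
#' @param error_prob 2AFC error probability in [0, 1].
#' @return retained count (nonnegative, at most \code{N}).
#' @export
retained_count <- function(N, error_prob) {
  if (any(error_prob < 0 | error_prob > 1)) stop("'error_prob' must be in [0, 1]")
  pmax(0, N * (1 - 2 * error_prob))
}

#' d-prime separability of two score distributions
#'
#' \eqn{d' = |\bar a - \bar b| / \sqrt{(s_a^2 + s_b^2)/2}} with unbiased
#' sample variances: the mean separation of two distributions in units of
#' their pooled (equal-weight) standard deviation. Zero means
#' indistinguishable. If the pooled variance is zero, the result is 0 for
#' equal means and \code{Inf} otherwise.
#'
#' @param a,b numeric samples with at least 2 elements each.
#' @return nonnegative scalar (possibly \code{Inf}).
#' @examples
#' dprime(c(0, 1), c(2, 3))  # 2 / sqrt(0.5)
#' @export
dprime <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("both samples need at least 2 elements")
  pooled <- (stats::var(a) + stats::var(b)) / 2
  delta <- abs(mean(a) - mean(b))
  if (pooled == 0) return(if (delta == 0) 0 else Inf)
  delta / sqrt(pooled)
}

#' Repetition-suppression trace
#'
#' Trains a model on a single stimulus and records the decline of the energy
#' (and of the absolute error-neuron activities) over repeated exposures —
#' the model counterpart of repetition suppression. \code{epochs = 0} returns
#' the untrained state only.
#'
#' @param model \code{"rpcn"}, \code{"hpcn"}, or a function
#'   \code{function(x, epochs, ...)} returning a fit with elements
#'   \code{trace} and optionally \code{abs_err}.
#' @param stimulus a single pattern (vector or one-column matrix).
#' @param epochs number of training exposures.
#' @param alpha learning rate (the experiments use 3e-4).
#' @param ... further arguments to the trainer (e.g. \code{layer_sizes} for
#'   \code{"hpcn"}).
#' @return list with \code{energy} (length \code{epochs + 1}, entry 1 =
#'   untrained) and \code{abs_err} (per-epoch distribution summaries of
#'   absolute error activities).
#' @export
repetition_trace <- function(model, stimulus, epochs, alpha = 3e-4, ...) {
  s <- as_pattern_matrix(stimulus)
  if (ncol(s) != 1L) stop("'stimulus' must be a single pattern")
  fit <- if (is.function(model)) model(s, epochs = epochs, ...)
  else switch(match.arg(model, c("rpcn", "hpcn")),
    rpcn = rpcn(s, alpha = alpha, max_epochs = epochs, tol = 0,
                trace_errors = TRUE, ...),
    hpcn = hpcn(s, alpha = alpha, epochs = epochs, tol = 0,
                trace_errors = TRUE, ...))
  list(energy = fit$trace, abs_err = fit$abs_err, fit = fit)
}

#' Default model registry for capacity experiments
#'
#' Named list of model definitions usable with \code{\link{capacity_curve}}.
#' Each entry has a \code{fit(train, seed)} function and an
#' \code{energy(fit, queries, seed)} function (the seed only matters for
#' stochastic readouts such as the variational autoencoder's). The Hopfield entries center queries
#' with the training mean and need no training; \code{rpcn} and the
#' autoencoders are trained to convergence on each training set.
#'
#' @param models character subset of
#'   \code{c("rpcn", "hn", "mchn", "ae", "vae")}.
#' @param rpcn_args,ae_args lists of extra arguments for the trainers.
#' @return named list of model definitions.
#' @export
nd_models <- function(models = c("rpcn", "hn", "mchn"),
                      rpcn_args = list(), ae_args = list()) {
  defs <- list(
    rpcn = list(
      fit = function(train, seed)
        do.call(rpcn, c(list(x = train), rpcn_args)),
      energy = function(fit, queries, seed = NULL) rpcn_energy(fit, queries)),
    hn = list(
      fit = function(train, seed) hopfield(train, type = "classical"),
      energy = function(fit, queries, seed = NULL) predict(fit, queries)),
    mchn = list(
      fit = function(train, seed) hopfield(train, type = "modern"),
      energy = function(fit, queries, seed = NULL) predict(fit, queries)),
    ae = list(
      fit = function(train, seed)
        do.call(autoencoder, c(list(x = train, variational = FALSE, seed = seed), ae_args)),
      energy = function(fit, queries, seed = NULL) recon_energy(fit, queries)),
    vae = list(
      fit = function(train, seed)
        do.call(autoencoder, c(list(x = train, variational = TRUE, seed = seed), ae_args)),
      energy = function(fit, queries, seed = NULL)
        recon_energy(fit, queries, seed = seed_shift(seed, 7L))))
  unknown <- setdiff(models, names(defs))
  if (length(unknown)) stop("unknown models: ", paste(unknown, collapse = ", "))
  defs[models]
}

# derive a dependent 32-bit seed deterministically
seed_shift <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + 12345L * as.numeric(k)) %% 2147483647)
}

#' Capacity benchmark: 2AFC error versus number of stored patterns
#'
#' For every model, training-set size \code{N} and seed: draws \code{N}
#' training patterns and \code{N} fresh novel patterns from the same
#' generative specification, trains the model (the Hopfield energies need no
#' training), evaluates energies on the familiar and novel sets, and records
#' the 2AFC error probability and the retained-pattern count. A model failure
#' yields an \code{NA} row rather than aborting the sweep.
#'
#' @param models a registry from \code{\link{nd_models}}.
#' @param data_spec list describing the generator: either
#'   \code{list(type = "gaussian", d, variance, pairwise_cov)} or
#'   \code{list(type = "class_images", side, n_classes, per_class,
#'   deform_amplitude, noise_sd)} (for class images, familiar/novel sets are
#'   a random split of the generated exemplars).
#' @param Ns ascending vector of training-set sizes.
#' @param seeds vector of seeds; each (N, seed) cell regenerates data.
#' @return data.frame with columns \code{model}, \code{dataset}, \code{d},
#'   \code{N}, \code{seed}, \code{error_prob}, \code{retained}.
#' @export
capacity_curve <- function(models, data_spec, Ns, seeds) {
  if (is.unsorted(Ns)) stop("'Ns' must be ascending")
  rows <- list()
  for (N in Ns) for (seed in seeds) {
    data <- capacity_data(data_spec, N, seed)
    for (mn in names(models)) {
      def <- models[[mn]]
      rec <- tryCatch({
        fit <- def$fit(data$train, seed)
        fam <- def$energy(fit, data$train, seed)
        nov <- def$energy(fit, data$novel, seed)
        p <- twoafc_error(fam, nov, pairing_seed = seed_shift(seed, 3L))
        c(error_prob = p, retained = retained_count(N, p))
      }, error = function(e) {
        warning(sprintf("model '%s' failed at N=%d seed=%s: %s",
                        mn, N, format(seed), conditionMessage(e)))
        c(error_prob = NA_real_, retained = NA_real_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        model = mn, dataset = data$name, d = data$d, N = N, seed = seed,
        error_prob = unname(rec["error_prob"]), retained = unname(rec["retained"]))
    }
  }
  do.call(rbind, rows)
}

capacity_data <- function(spec, N, seed) {
  type <- spec$type %||% "gaussian"
  if (type == "gaussian") {
    d <- spec$d
    v <- spec$variance %||% 1
    c0 <- spec$pairwise_cov %||% 0
    train <- sample_gaussian(d, N, v, c0, seed = seed)
    novel <- sample_gaussian(d, N, v, c0, seed = seed_shift(seed, 1L))
    list(train = train, novel = novel, d = d,
         name = sprintf("gaussian(d=%d,c=%g)", d, c0))
  } else if (type == "class_images") {
    args <- spec[intersect(names(spec),
                           c("side", "n_classes", "per_class",
                             "deform_amplitude", "noise_sd"))]
    args$n_classes <- args$n_classes %||% 1L
    args$per_class <- args$per_class %||% ceiling(2 * N / args$n_classes)
    args$seed <- seed
    ps <- do.call(make_class_images, args)
    sp <- split_familiar_novel(ps, N, seed = seed_shift(seed, 2L))
    novel <- sp$novel
    if (ncol(novel$data) > N) novel <- pattern_set(novel$data[, seq_len(N), drop = FALSE])
    list(train = sp$train, novel = novel, d = nrow(ps$data),
         name = sprintf("class_images(d=%d)", nrow(ps$data)))
  } else stop(sprintf("unknown data_spec type '%s'", type))
}

#' Layer-wise novelty report for an hPCN
#'
#' Runs inference for every query in each named query set and reports, per
#' layer, the squared error norms \eqn{\|\varepsilon^l\|_2^2} (i.e. twice the
#' layer energy, the scale used for the violin plots) and the d-prime
#' separability between every pair of query sets.
#'
#' @param object a fitted \code{\link{hpcn}}.
#' @param queries named list of query sets (each a \code{pattern_set} or
#'   matrix of common dimension).
#' @param ... passed to \code{\link{hpcn_infer}}.
#' @return list of class \code{"hierarchy_report"} with \code{energies}
#'   (data.frame: \code{set}, \code{layer}, \code{query}, \code{sq_error})
#'   and \code{dprime} (data.frame: \code{layer}, \code{set_a}, \code{set_b},
#'   \code{dprime}).
#' @export
hierarchy_report <- function(object, queries, ...) {
  if (is.null(names(queries)) || any(names(queries) == ""))
    stop("'queries' must be a fully named list")
  Ls <- object$L + 1L
  samp <- lapply(queries, function(q) {
    inf <- hpcn_infer(object, q, ...)
    2 * inf$layer_energies        # ||eps^l||^2 per query
  })
  energies <- do.call(rbind, lapply(names(samp), function(nm) {
    m <- samp[[nm]]
    data.frame(set = nm,
               layer = rep(seq_len(Ls) - 1L, times = ncol(m)),
               query = rep(seq_len(ncol(m)), each = Ls),
               sq_error = as.vector(m))
  }))
  pairs <- utils::combn(names(samp), 2)
  dp <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- samp[[pairs[1, k]]]; b <- samp[[pairs[2, k]]]
    data.frame(layer = seq_len(Ls) - 1L,
               set_a = pairs[1, k], set_b = pairs[2, k],
               dprime = vapply(seq_len(Ls), function(l) dprime(a[l, ], b[l, ]), 0))
  }))
  structure(list(energies = energies, dprime = dp), class = "hierarchy_report")
}

#' @export
print.hierarchy_report <- function(x, ...) {
  cat("Layer-wise novelty report\n")
  cat(sprintf("  query sets: %s\n", paste(unique(x$energies$set), collapse = ", ")))
  cat("  d-prime separability by layer:\n")
  wide <- stats::reshape(x$dprime, idvar = c("set_a", "set_b"),
                         timevar = "layer", direction = "wide")
  names(wide) <- sub("^dprime\\.", "layer", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}
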