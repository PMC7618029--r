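#' Read MNIST-style IDX files
#'
#' Parses the big-endian IDX format used by the MNIST handwritten-digit
#' distribution: an image file (magic 2051) and optionally a label file
#' (magic 2049). Pixels are scaled to [0, 1] and images flattened to
#' \code{rows * cols} vectors.
#'
#' @param images_path path to an IDX image file (uncompressed).
#' @param labels_path optional path to the matching IDX label file.
#' @param keep optional label filter (e.g. \code{4L} keeps only the 4s); a
#'   filter matching nothing yields an empty set with a warning.
#' @return a \code{\link{pattern_set}}, with labels when supplied.
#' @export
read_mnist_idx <- function(images_path, labels_path = NULL, keep = NULL) {
  con <- file(images_path, "rb"); on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L))
    stop(sprintf("'%s' is not an IDX image file (magic %d, expected 2051)", images_path, magic))
  hdr <- readBin(con, "integer", 3, size = 4, endian = "big")
  n <- hdr[1]; rows <- hdr[2]; cols <- hdr[3]
  raw <- readBin(con, "integer", n * rows * cols, size = 1, signed = FALSE)
  if (length(raw) < n * rows * cols) stop("truncated IDX image file")
  X <- matrix(raw / 255, nrow = rows * cols, ncol = n)
  labels <- NULL
  if (!is.null(labels_path)) {
    lc <- file(labels_path, "rb"); on.exit(close(lc), add = TRUE)
    lmagic <- readBin(lc, "integer", 1, size = 4, endian = "big")
    if (!identical(lmagic, 2049L))
      stop(sprintf("'%s' is not an IDX label file (magic %d, expected 2049)", labels_path, lmagic))
    ln <- readBin(lc, "integer", 1, size = 4, endian = "big")
    if (ln != n) stop("image and label counts differ")
    labels <- readBin(lc, "integer", ln, size = 1, signed = FALSE)
    if (length(labels) < ln) stop("truncated IDX label file")
  }
  if (!is.null(keep)) {
    if (is.null(labels)) stop("'keep' requires a label file")
    sel <- labels %in% keep
    if (!any(sel)) warning("label filter matched no images; returning an empty pattern set")
    X <- X[, sel, drop = FALSE]; labels <- labels[sel]
  }
  pattern_set(X, labels)
}

#' Load a folder of grayscale images as patterns
#'
#' Reads every PNG in a folder (sorted paths, so the ordering is
#' deterministic), converts to grayscale by channel averaging, resizes to
#' \code{side x side} by bilinear interpolation, scales to [0, 1] and
#' flattens to \code{side^2} vectors. Unreadable files are skipped with a
#' warning; an empty result is an error. Requires the \pkg{png} package.
#'
#' @param path folder of PNG images.
#' @param side target side length (64 gives the d = 4096 used for small
#'   natural-image benchmarks).
#' @return a \code{\link{pattern_set}} with \code{d = side^2}.
#' @export
read_image_folder <- function(path, side = 64L) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read image folders")
  files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                           full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no PNG images found in '%s'", path))
  side <- as.integer(side)
  cols <- list()
  for (f in files) {
    img <- tryCatch(png::readPNG(f), error = function(e) {
      warning(sprintf("skipping unreadable image '%s': %s", f, conditionMessage(e)))
      NULL
    })
    if (is.null(img)) next
    if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                                             c(1, 2), mean)
    pos_y <- seq(1, nrow(img), length.out = side)
    pos_x <- seq(1, ncol(img), length.out = side)
    res <- bilinear_rect(img, rep(pos_y, times = side), rep(pos_x, each = side))
    cols[[length(cols) + 1L]] <- pmin(pmax(res, 0), 1)
  }
  if (length(cols) == 0L) stop(sprintf("no readable PNG images in '%s'", path))
  pattern_set(do.call(cbind, cols))
}

# bilinear lookup on a possibly non-square matrix
bilinear_rect <- function(img, ys, xs) {
  ys <- pmin(pmax(ys, 1), nrow(img)); xs <- pmin(pmax(xs, 1), ncol(img))
  y0 <- pmin(floor(ys), nrow(img) - 1L); x0 <- pmin(floor(xs), ncol(img) - 1L)
  if (nrow(img) == 1L) y0 <- rep(1L, length(ys))
  if (ncol(img) == 1L) x0 <- rep(1L, length(xs))
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1, nrow(img)); x1 <- pmin(x0 + 1, ncol(img))
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) + img[cbind(y1, x0)] * fy * (1 - fx) +
    img[cbind(y0, x1)] * (1 - fy) * fx + img[cbind(y1, x1)] * fy * fx
}

#' Run a named experiment from a configuration
#'
#' Thin driver tying the harness together for scripted use: dispatches on
#' \code{config$experiment} (\code{"capacity"}, \code{"repetition"},
#' \code{"hierarchy"} or \code{"theorem1"}), runs the corresponding protocol
#' function, and (optionally) writes the results plus the resolved
#' configuration to an output directory (CSV for tabular results, JSON
#' otherwise). Unknown configuration keys are rejected.
#'
#' @param config a named list (or path to a YAML file, read with the
#'   \pkg{yaml} package) with keys:
#'   \describe{
#'     \item{experiment}{one of capacity, repetition, hierarchy, theorem1.}
#'     \item{data}{data specification list, as in \code{\link{capacity_curve}}.}
#'     \item{models}{character vector for \code{\link{nd_models}} (capacity).}
#'     \item{Ns, seeds}{sweep settings (capacity).}
#'     \item{epochs, alpha, layer_sizes, d, N, pairwise_cov, n_queries, model}{
#'       experiment-specific settings.}
#'   }
#' @param seed master seed; overrides \code{config$seed}.
#' @param out_dir optional output directory.
#' @return the experiment result, invisibly when writing files.
#' @export
run_experiment <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  allowed <- c("experiment", "data", "models", "Ns", "seeds", "epochs", "alpha",
               "layer_sizes", "d", "N", "pairwise_cov", "n_queries", "model",
               "seed", "masks_patch")
  bad <- setdiff(names(config), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) config$seed <- seed
  exp <- match.arg(config$experiment, c("capacity", "repetition", "hierarchy", "theorem1"))

  result <- switch(exp,
    capacity = {
      reg <- nd_models(config$models %||% c("rpcn", "hn", "mchn"))
      seeds <- config$seeds %||% seed_shift(config$seed %||% 1L, 1:5)
      capacity_curve(reg, config$data, config$Ns %||% c(100L, 300L, 500L), seeds)
    },
    repetition = {
      stim <- make_class_images(n_classes = 1L, per_class = 1L,
                                seed = config$seed)$data
      mdl <- config$model %||% "rpcn"
      args <- list(model = mdl, stimulus = stim,
                   epochs = config$epochs %||% 3000L,
                   alpha = config$alpha %||% 3e-4)
      if (mdl == "hpcn")
        args$layer_sizes <- config$layer_sizes %||% c(nrow(stim), 144L, 72L)
      do.call(repetition_trace, args)[c("energy", "abs_err")]
    },
    hierarchy = {
      spec <- config$data %||% list()
      side <- spec$side %||% 20L
      n_tr <- config$N %||% 100L
      imgs <- make_class_images(side = side, n_classes = 2L,
                                per_class = 2L * n_tr,
                                seed = config$seed)
      A <- pattern_set(imgs$data[, imgs$labels == 0L, drop = FALSE])
      B <- pattern_set(imgs$data[, imgs$labels == 1L, drop = FALSE])
      sp <- split_familiar_novel(A, n_tr, seed = seed_shift(config$seed, 2L))
      patch <- config$masks_patch %||% 9L
      hid <- side - patch + 1L
      sizes <- config$layer_sizes %||% c(side^2, hid^2, 72L)
      masks <- if (sizes[2] == hid^2) list(make_local_mask(side, hid, patch), NULL) else NULL
      fit <- hpcn(sp$train, layer_sizes = sizes, masks = masks,
                  alpha = config$alpha %||% 0.2,
                  epochs = config$epochs %||% 1000L,
                  seed = seed_shift(config$seed, 3L))
      novA <- pattern_set(sp$novel$data[, seq_len(min(n_tr, ncol(sp$novel$data))), drop = FALSE])
      novB <- pattern_set(B$data[, seq_len(min(n_tr, ncol(B$data))), drop = FALSE])
      hierarchy_report(fit, list(familiar = sp$train, novel_same_class = novA,
                                 other_class = novB))
    },
    theorem1 = {
      d <- config$d %||% 20L; N <- config$N %||% 500L
      cc <- config$pairwise_cov %||% 0.4
      train <- sample_gaussian(d, N, pairwise_cov = cc, seed = config$seed)
      fit <- rpcn(train, tol = 1e-10, max_epochs = 100000L)
      Q <- sample_gaussian(d, config$n_queries %||% 100L, pairwise_cov = cc,
                           seed = seed_shift(config$seed, 4L))
      chk <- theorem1_check(fit, q = Q)
      list(median_rel_err = stats::median(chk$rel_err),
           max_rel_err = max(chk$rel_err), converged = fit$converged)
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (is.data.frame(result)) {
      utils::write.csv(result, file.path(out_dir, paste0(exp, ".csv")),
                       row.names = FALSE)
    } else if (inherits(result, "hierarchy_report")) {
      utils::write.csv(result$energies, file.path(out_dir, "layer_energies.csv"),
                       row.names = FALSE)
      utils::write.csv(result$dprime, file.path(out_dir, "dprime.csv"),
                       row.names = FALSE)
    } else {
      jsonlite::write_json(result, file.path(out_dir, paste0(exp, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    writeLines(c(sprintf("experiment: %s", exp),
                 sprintf("seed: %s", format(config$seed %||% NA)),
                 sprintf("package: pcnd %s", as.character(utils::packageVersion("pcnd"))),
                 sprintf("R: %s", R.version.string)),
               file.path(out_dir, "run_log.txt"))
    return(invisible(result))
  }
  result
}
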