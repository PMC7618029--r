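test_that("layer-wise errors follow the top-down prediction structure", {
  # 1-1-1 linear chain that the activities satisfy exactly
  fit <- structure(list(weights = list(matrix(3), matrix(2)), nu = 1,
                        layer_sizes = c(1L, 1L, 1L), L = 2L,
                        nonlinearity = "identity"), class = "hpcn")
  eps <- hpcn_errors(fit, list(6, 2, 1))
  expect_equal(unlist(eps), c(0, 0, 0))
  # zero weights and bias: errors equal activities
  z <- structure(list(weights = list(matrix(0, 3, 2)), nu = c(0, 0),
                      layer_sizes = c(3L, 2L), L = 1L, nonlinearity = "tanh"),
                 class = "hpcn")
  eps2 <- hpcn_errors(z, list(c(1, 2, 3), c(4, 5)))
  expect_equal(as.vector(eps2[[1]]), c(1, 2, 3))
  expect_equal(as.vector(eps2[[2]]), c(4, 5))
  # top-layer error vanishes when the top activity equals the bias
  z$nu <- c(4, 5)
  expect_equal(as.vector(hpcn_errors(z, list(c(1, 2, 3), c(4, 5)))[[2]]), c(0, 0))
  expect_error(hpcn_errors(z, list(c(1, 2), c(4, 5))), "rows")
})

test_that("local masks tile receptive fields with the right geometry", {
  m <- make_local_mask(28, 20, 9)
  expect_equal(dim(m), c(784L, 400L))
  expect_true(all(colSums(m) == 81))
  expect_equal(make_local_mask(9, 1, 9), matrix(1, 81, 1))
  m2 <- make_local_mask(10, 2, 9)
  expect_equal(dim(m2), c(100L, 4L))
  expect_true(all(colSums(m2) == 81))
  # neighbouring output neurons along a row share an 8x9 block of pixels
  overlap <- sum(m2[, 1] * m2[, 2])
  expect_equal(overlap, 72)
  expect_error(make_local_mask(16, 10, 9), "incompatible geometry")
})

test_that("linear single-hidden-layer inference solves the quadratic exactly", {
  set.seed(22)
  d <- 6; h <- 3
  fit <- hpcn(matrix(stats::rnorm(d * 4), d), layer_sizes = c(d, h),
              nonlinearity = "identity", epochs = 0, seed = 23)
  q <- stats::rnorm(d)
  inf <- hpcn_infer(fit, q, infer_max_steps = 20000, infer_tol = 1e-15)
  W <- fit$weights[[1]]
  xstar <- solve(diag(h) + crossprod(W), crossprod(W, q) + fit$nu)
  expect_lt(max(abs(inf$activities[[2]] - xstar)), 1e-6)
  # layer energies match the errors at the solution
  expect_equal(inf$total_energy, sum(inf$layer_energies[, 1]))
  expect_true(all(inf$layer_energies >= 0))
})

test_that("inference started at a fixed point stays there", {
  set.seed(24)
  d <- 6; h <- 3
  fit <- hpcn(matrix(stats::rnorm(d * 4), d), layer_sizes = c(d, h),
              nonlinearity = "identity", epochs = 0, seed = 25)
  q <- stats::rnorm(d)
  W <- fit$weights[[1]]
  xstar <- solve(diag(h) + crossprod(W), crossprod(W, q) + fit$nu)
  inf <- hpcn_infer(fit, q, x_init = list(matrix(xstar, ncol = 1)))
  expect_lte(inf$steps_used, 2)
  expect_lt(max(abs(inf$activities[[2]] - xstar)), 1e-8)
})

test_that("inference monotonically reduces the total energy", {
  set.seed(26)
  fit <- hpcn(matrix(stats::rnorm(12 * 3), 12), layer_sizes = c(12, 6, 3),
              epochs = 0, seed = 27)
  q <- stats::rnorm(12)
  en <- vapply(0:10, function(k)
    hpcn_infer(fit, q, infer_max_steps = k, infer_tol = 0)$total_energy, 0)
  expect_true(all(diff(en) <= 1e-12 * en[1]))
})

test_that("masked weights stay exactly zero through training", {
  ps <- make_class_images(side = 10, n_classes = 1, per_class = 20, seed = 28)
  mask <- make_local_mask(10, 2, 9)
  fit <- hpcn(ps, layer_sizes = c(100, 4, 3), masks = list(mask, NULL),
              epochs = 40, seed = 29)
  expect_true(all(fit$weights[[1]][mask == 0] == 0))
  expect_gt(sum(fit$weights[[1]] != 0), 0)
})

test_that("training reduces energy and distinguishes familiar from novel inputs", {
  ps <- make_class_images(side = 10, n_classes = 1, per_class = 30, seed = 30)
  sp <- split_familiar_novel(ps, 20, seed = 31)
  fit <- hpcn(sp$train, layer_sizes = c(100, 40, 10), alpha = 0.05,
              epochs = 150, seed = 32)
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1])
  expect_true(all(diff(fit$trace) <= 1e-10 * fit$trace[1]))
  # layer-0 energy on familiar inputs is lower than on novel same-class inputs
  fam <- predict(fit, sp$train, type = "layer_energy")
  nov <- predict(fit, sp$novel, type = "layer_energy")
  expect_lt(mean(fam["layer0", ]), mean(nov["layer0", ]))
})

test_that("different seeds give different weights but the same energy decline", {
  ps <- make_class_images(side = 10, n_classes = 1, per_class = 10, seed = 33)
  f1 <- hpcn(ps, layer_sizes = c(100, 10, 4), epochs = 30, seed = 1)
  f2 <- hpcn(ps, layer_sizes = c(100, 10, 4), epochs = 30, seed = 2)
  expect_gt(max(abs(f1$weights[[1]] - f2$weights[[1]])), 0)
  expect_lt(f1$trace[length(f1$trace)], f1$trace[1])
  expect_lt(f2$trace[length(f2$trace)], f2$trace[1])
})

test_that("hpcn fit exposes the standard model interface", {
  ps <- make_class_images(side = 10, n_classes = 1, per_class = 8, seed = 34)
  fit <- hpcn(ps, layer_sizes = c(100, 8, 4), epochs = 10, seed = 35)
  expect_s3_class(fit, "hpcn")
  expect_named(coef(fit), c("weights", "nu"))
  expect_length(predict(fit), 8)
  expect_equal(dim(predict(fit, type = "layer_energy")), c(3L, 8L))
  expect_length(residuals(fit), 3)
  expect_output(print(fit), "Hierarchical")
  expect_output(print(summary(fit)), "layer")
})
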