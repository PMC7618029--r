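test_that("2AFC error scores pairs by lower-energy-is-familiar with half-credit ties", {
  expect_equal(twoafc_error(c(1, 2, 3), c(5, 6, 7), pairing_seed = 1), 0)
  expect_equal(twoafc_error(c(5, 6, 7), c(1, 2, 3), pairing_seed = 1), 1)
  # familiar [1, 3] vs novel [2, 2]: any pairing gives one correct, one error
  expect_equal(twoafc_error(c(1, 3), c(2, 2), pairing_seed = 2), 0.5)
  expect_equal(twoafc_error(c(1, 1), c(1, 1), pairing_seed = 3), 0.5)  # pure ties
  expect_error(twoafc_error(numeric(0), 1), "nonempty")
})

test_that("2AFC error is invariant to joint monotone transforms of the energies", {
  set.seed(40)
  fam <- stats::rnorm(200); nov <- stats::rnorm(200, mean = 0.5)
  base <- twoafc_error(fam, nov, pairing_seed = 7)
  expect_equal(twoafc_error(fam + 10, nov + 10, pairing_seed = 7), base)
  expect_equal(twoafc_error(exp(fam), exp(nov), pairing_seed = 7), base)
})

test_that("indistinguishable energies calibrate to chance", {
  set.seed(41)
  err <- twoafc_error(stats::rnorm(1000), stats::rnorm(1000), pairing_seed = 8)
  expect_lt(abs(err - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("retained-pattern count applies the correction for guessing", {
  expect_equal(retained_count(100, 0.5), 0)
  expect_equal(retained_count(100, 0), 100)
  expect_equal(retained_count(10000, 0.17), 6600)
  expect_equal(retained_count(50, 0.8), 0)       # clipped at zero
  # monotone decreasing in the error probability
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(retained_count(100, p)) <= 0))
  expect_error(retained_count(10, 1.2), "must be in")
})

test_that("d-prime measures separation in pooled standard deviations", {
  expect_equal(dprime(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dprime(c(0, 1), c(2, 3)), 2 / sqrt(0.5))
  set.seed(42)
  a <- stats::rnorm(5000, 0, 1); b <- stats::rnorm(5000, 2, 1)
  expect_equal(dprime(a, b), 2, tolerance = 0.1)
  expect_equal(dprime(a, b), dprime(b, a))
  expect_equal(dprime(c(1, 1), c(2, 2)), Inf)    # zero variance, unequal means
  expect_error(dprime(1, c(1, 2)), "at least 2")
})

test_that("repetition traces decline monotonically and honor epochs = 0", {
  stim <- make_class_images(side = 10, n_classes = 1, per_class = 1, seed = 43)$data
  tr0 <- repetition_trace("rpcn", stim, epochs = 0)
  expect_length(tr0$energy, 1)
  tr <- repetition_trace("rpcn", stim, epochs = 400)
  expect_length(tr$energy, 401)
  expect_true(all(diff(tr$energy) <= 1e-12 * tr$energy[1]))
  # median absolute error-neuron activity declines as the stimulus repeats
  med <- apply(tr$abs_err, 2, stats::median)
  expect_lt(med[length(med)], med[1])
  expect_true(all(diff(med) <= 1e-12 * med[1]))
})

test_that("capacity sweep emits one record per model/N/seed and is reproducible", {
  reg <- nd_models(c("hn", "mchn"))
  spec <- list(type = "gaussian", d = 10, pairwise_cov = 0)
  tab <- capacity_curve(reg, spec, Ns = c(5, 8), seeds = 1:2)
  expect_equal(nrow(tab), 2 * 2 * 2)
  expect_true(all(tab$error_prob >= 0 & tab$error_prob <= 1))
  expect_true(all(tab$retained <= tab$N))
  tab2 <- capacity_curve(reg, spec, Ns = c(5, 8), seeds = 1:2)
  expect_identical(tab, tab2)
  expect_error(capacity_curve(reg, spec, Ns = c(8, 5), seeds = 1), "ascending")
  # trained models (incl. the stochastic variational readout) run through the sweep
  reg2 <- nd_models(c("rpcn", "ae", "vae"), ae_args = list(epochs = 30))
  tab3 <- capacity_curve(reg2, spec, Ns = 6, seeds = 5)
  expect_equal(nrow(tab3), 3L)
  expect_true(all(is.finite(tab3$error_prob)))
  expect_identical(tab3, capacity_curve(reg2, spec, Ns = 6, seeds = 5))
  # class-image data specification draws familiar/novel splits of exemplars
  tab4 <- capacity_curve(nd_models("hn"),
                         list(type = "class_images", side = 10), Ns = 4, seeds = 2)
  expect_equal(tab4$d, 100)
  expect_true(is.finite(tab4$error_prob))
})

test_that("hierarchy report covers all set pairs and is zero on identical sets", {
  ps <- make_class_images(side = 10, n_classes = 1, per_class = 12, seed = 44)
  fit <- hpcn(ps, layer_sizes = c(100, 10, 4), epochs = 10, seed = 45)
  q <- ps$data[, 1:6]
  rep4 <- hierarchy_report(fit, list(a = q, b = q + 0.1, c = q + 0.2, d = q + 0.3))
  expect_equal(nrow(rep4$dprime), 6 * 3)          # 6 pairs x 3 layers
  expect_equal(sort(unique(rep4$dprime$layer)), 0:2)
  same <- hierarchy_report(fit, list(a = q, b = q))
  expect_true(all(same$dprime$dprime == 0))
  # energies table holds ||eps||^2 = 2 * layer energy per query
  le <- predict(fit, q, type = "layer_energy")
  e0 <- same$energies[same$energies$set == "a" & same$energies$layer == 0, "sq_error"]
  expect_equal(e0, unname(2 * le["layer0", ]))
  expect_error(hierarchy_report(fit, list(q, q)), "named")
})
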