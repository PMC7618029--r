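test_that("classical Hopfield energy matches its defining sum", {
  X <- cbind(c(1, 0), c(1, 1))
  expect_equal(hn_energy(c(1, 2), X), -10)          # -(1^2 + 3^2)
  expect_equal(hn_energy(c(0, 1), cbind(c(1, 0))), 0)   # orthogonal query
  q <- c(0.6, 0.8)                                   # unit norm, stored pattern
  expect_equal(hn_energy(q, cbind(q)), -1)
  expect_error(hn_energy(c(1, 2), matrix(numeric(0), 2, 0)), "empty")
})

test_that("covariance form agrees with the direct energy on centered data", {
  set.seed(9)
  X <- matrix(stats::rnorm(5 * 40), 5)
  X <- X - rowMeans(X)
  Q <- matrix(stats::rnorm(5 * 7), 5)
  expect_equal(hn_energy_cov(Q, X), hn_energy(Q, X), tolerance = 1e-10)
  expect_equal(hn_energy_cov(rep(0, 5), X), 0)
  expect_equal(hn_energy_cov(Q, X, normalized = TRUE), hn_energy(Q, X) / 40,
               tolerance = 1e-10)
  # two-pattern hand example (already centered)
  X2 <- cbind(c(1, -1), c(-1, 1))
  expect_equal(hn_energy_cov(c(2, 1), X2), hn_energy(c(2, 1), X2))
  expect_error(hn_energy_cov(Q, X + 1), "centered")
})

test_that("modern Hopfield energy has its closed values and is order invariant", {
  q <- c(1.5, -2)
  expect_equal(mchn_energy(q, cbind(q)), -0.5 * sum(q^2))   # single stored = query
  X <- diag(2)
  expect_equal(mchn_energy(c(0, 0), X), -log(2))
  expect_equal(mchn_energy(c(1, 0), X), -log(exp(1) + 1) + 0.5)
  expect_equal(mchn_energy(q, X[, 2:1]), mchn_energy(q, X))
  # log-sum-exp guard: dot products around 1e4 stay finite
  big <- cbind(c(100, 0), c(0, 100))
  expect_true(is.finite(mchn_energy(c(100, 0), big)))
  expect_equal(mchn_energy(c(100, 0), big), -1e4 + 0.5 * 1e4, tolerance = 1e-6)
})

test_that("hopfield wrapper centers queries with the training mean", {
  X <- sample_gaussian(6, 30, pairwise_cov = 0.2, seed = 10)
  hn <- hopfield(X, type = "classical")
  Q <- sample_gaussian(6, 4, seed = 11)$data
  mu <- rowMeans(X$data)
  expect_equal(predict(hn, Q), hn_energy(Q - mu, X$data - mu))
  mc <- hopfield(X, type = "modern")
  expect_equal(predict(mc, Q), mchn_energy(Q - mu, X$data - mu))
})

test_that("parameter matching keeps baselines within 5% of the rPCN count", {
  expect_equal(param_matched_hidden(500), 249L)
  expect_equal(param_matched_hidden(2), 1L)       # degenerate guard
  for (d in c(50, 100, 237, 500)) {
    h <- param_matched_hidden(d)
    expect_lt(abs((2 * d * h + h + d) - d^2) / d^2, 0.05)
    hv <- param_matched_hidden(d, variational = TRUE)
    expect_lt(abs((3 * d * hv + 2 * hv + d) - d^2) / d^2, 0.05)
  }
  fit <- autoencoder(sample_gaussian(50, 20, seed = 1), epochs = 2, seed = 1)
  expect_lt(abs(fit$n_params - 50^2) / 50^2, 0.05)
})

test_that("an autoencoder memorizes a single pattern", {
  x <- sample_gaussian(20, 1, seed = 13)$data
  fit <- autoencoder(x, epochs = 3000, alpha = 0.1, seed = 14)
  e_fam <- recon_energy(fit, x)
  e_nov <- recon_energy(fit, sample_gaussian(20, 1, seed = 15)$data)
  expect_lt(e_fam, 1e-2)
  expect_gt(e_nov, 10 * e_fam)
})

test_that("a hand-built near-identity autoencoder reconstructs any query", {
  d <- 5
  obj <- structure(list(W1 = diag(d) * 1e-4, b1 = numeric(d),
                        W2 = diag(d) * 1e4, b2 = numeric(d),
                        Wv = NULL, bv = NULL, d = d, hidden = d,
                        variational = FALSE, n_samples = 1L),
                   class = "autoencoder")
  q <- c(0.3, -1, 2, 0.5, -0.2)
  expect_lt(recon_energy(obj, q), 1e-10)
})

test_that("variational sampling inflates test-time energy variability", {
  X <- sample_gaussian(30, 40, pairwise_cov = 0.2, seed = 16)
  ae <- autoencoder(X, epochs = 200, seed = 17)
  vae <- autoencoder(X, variational = TRUE, epochs = 200, seed = 17)
  q <- sample_gaussian(30, 1, seed = 18)$data
  # AE is deterministic across calls
  expect_identical(recon_energy(ae, q), recon_energy(ae, q))
  vs <- replicate(20, recon_energy(vae, q, n_samples = 1))
  expect_gt(stats::var(vs), 0)
  # averaging latent draws shrinks the estimator variance roughly as 1/n
  v1 <- stats::var(replicate(40, recon_energy(vae, q, n_samples = 1)))
  v25 <- stats::var(replicate(40, recon_energy(vae, q, n_samples = 25)))
  expect_lt(v25, v1 / 5)
})

test_that("under pixel correlation the Hopfield energies err more than rPCN", {
  errs <- sapply(1:5, function(seed) {
    train <- sample_gaussian(100, 300, pairwise_cov = 0.4, seed = seed)
    novel <- sample_gaussian(100, 300, pairwise_cov = 0.4, seed = seed + 50)
    fit <- rpcn(train, max_epochs = 4000)
    hn <- hopfield(train, "classical")
    mc <- hopfield(train, "modern")
    c(rpcn = twoafc_error(rpcn_energy(fit, train), rpcn_energy(fit, novel), seed),
      hn = twoafc_error(predict(hn, train), predict(hn, novel), seed),
      mchn = twoafc_error(predict(mc, train), predict(mc, novel), seed))
  })
  m <- rowMeans(errs)
  expect_gt(m["hn"], m["rpcn"] + 0.1)
  expect_gt(m["mchn"], m["rpcn"] + 0.1)
})
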