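# shared fixture helpers (all fixtures are generated in code)

# random symmetric positive-definite matrix with well-separated spectrum
random_pd <- function(d, seed = NULL) {
  gen <- function() {
    A <- matrix(stats::rnorm(d * d), d, d)
    crossprod(A) / d + diag(d) * 0.5
  }
  if (is.null(seed)) gen() else { set.seed(seed); gen() }
}

# minimal untrained rPCN-like state
blank_rpcn_state <- function(d, alpha = 0.1)
  list(W = matrix(0, d, d), nu = numeric(d), alpha = alpha)
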