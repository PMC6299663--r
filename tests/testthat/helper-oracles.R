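# Shared oracles and Monte-Carlo helpers.

# batch-means standard error of the mean of a (possibly autocorrelated)
# chain; robust against slow mixing, unlike sd/sqrt(n)
mc_se <- function(x, n_batches = 25) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  sd(means) / sqrt(n_batches)
}

# exact draws of the cumulative probabilities (p_1, ..., p_S) whose
# increments are Dirichlet(gamma) — the distributional oracle for the DP
# prior restricted to the dose partition
rdirichlet_cum <- function(n, gamma) {
  k <- length(gamma)
  x <- matrix(rgamma(n * k, shape = rep(gamma, each = n)), n, k)
  cum <- t(apply(x / rowSums(x), 1, cumsum))
  cum[, -k, drop = FALSE]
}

# the six per-scenario base-curve rows as printed alongside the scenarios
# (2 dp): used to pin down the (mu, sigma) pairings
scenario_f0_rows <- list(
  c(0.006, 0.02, 0.07, 0.16, 0.31, 0.50, 0.69, 0.84),
  c(0.006, 0.02, 0.07, 0.16, 0.31, 0.50, 0.69, 0.84),
  c(0.04, 0.05, 0.08, 0.12, 0.16, 0.21, 0.27, 0.34),
  c(0.04, 0.05, 0.08, 0.12, 0.16, 0.21, 0.27, 0.34),
  c(0.31, 0.40, 0.50, 0.60, 0.69, 0.77, 0.84, 0.89),
  c(0.31, 0.40, 0.50, 0.60, 0.69, 0.77, 0.84, 0.89)
)

# tiny sampler settings for fast structural tests
fast_sampler <- function(seed = NULL) {
  sampler_config(n_burnin = 100L, n_keep = 150L, seed = seed)
}
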