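test_that("dose grid and trial state enforce their invariants", {
  expect_error(dose_grid(c(1, 1, 2)), "strictly increasing")
  expect_error(dose_grid(1:8, theta = 1.2), "probability")
  expect_error(dose_grid(3), "at least two")
  g <- dose_grid(1:8, 0.3)
  expect_equal(g$K, 8L)

  expect_error(trial_state(c(3, 3), c(1, 4)), "0 <= y_k <= n_k")
  expect_error(trial_state(c(3, 0, 3), c(0, 0, 1)), "contiguous")
  tr <- trial_state(c(3, 6, 0), c(1, 2, 0))
  expect_equal(tr$S, 2L)
  expect_equal(trial_state(c(0, 0), c(0, 0))$S, 0L)
})

test_that("base CDF is the normal CDF centred at the prior MTD guess", {
  expect_equal(base_cdf(6, mu = 6, sigma = 2), 0.5)
  expect_equal(base_cdf(99, mu = 6, sigma = 0.5), 1)
  # printed base-curve values at 2 dp
  expect_equal(round(base_cdf(5, 6, 2), 2), 0.31)
  expect_equal(round(base_cdf(8, 10, 5), 2), 0.34)
  expect_true(all(diff(base_cdf(seq(-5, 5, 0.1), 0, 1)) >= 0))
  expect_error(base_cdf(1, 0, -1), "sigma")
})

test_that("Dirichlet weights are the scaled base-CDF increments", {
  g <- dose_grid(1:8)
  for (al in c(0.5, 5, 20)) {
    gam <- dirichlet_weights(g, S = 8, alpha = al, mu = 6, sigma = 2)
    expect_length(gam, 9L)
    expect_true(all(gam > 0))
    expect_equal(sum(gam), al)
  }
  gam <- dirichlet_weights(g, S = 8, alpha = 5, mu = 6, sigma = 2)
  expect_equal(gam[1], 5 * pnorm(-2.5))
  # F0(d_1) = 0.5 splits a precision of 4 into equal halves
  expect_equal(dirichlet_weights(g, S = 1, alpha = 4, mu = 1, sigma = 3),
               c(2, 2))
  expect_error(dirichlet_weights(g, S = 9, alpha = 5, mu = 6, sigma = 2))
})

test_that("prior kernel matches the ordered-Dirichlet density", {
  # flat kernel for unit weights
  expect_equal(log_prior_density(c(0.2, 0.5, 0.9), rep(1, 4)), 0)
  expect_equal(log_prior_density(0.5, c(2, 2)), 2 * log(0.5))
  expect_error(log_prior_density(c(0.5, 0.4), rep(1, 3)), "monotonicity")

  # kernel * normaliser integrates to 1 over the ordered simplex (S = 2):
  # uniform MC over {0 < p1 < p2 < 1}, which has volume 1/2
  gam <- c(2, 3, 2)
  set.seed(42)
  u <- matrix(runif(2 * 2e5), ncol = 2)
  u <- cbind(pmin(u[, 1], u[, 2]), pmax(u[, 1], u[, 2]))
  vals <- exp(apply(u, 1, log_prior_density, gamma = gam))
  integral <- mean(vals) * 0.5 * exp(log_dirichlet_normalizer(gam))
  expect_lt(abs(integral - 1), 0.02)
})

test_that("likelihood and posterior kernels combine correctly", {
  g <- dose_grid(1:8)
  expect_equal(log_likelihood(numeric(0), trial_state(c(0, 0), c(0, 0))), 0)
  tr <- trial_state(c(3, 0, 0), c(1, 0, 0))
  expect_equal(log_likelihood(0.3, tr), log(0.3) + 2 * log(0.7))
  # boundary: all-toxic data at p -> 1 has kernel 0
  expect_equal(log_likelihood(1, trial_state(3, 3)), 0)
  expect_equal(log_likelihood(1, tr), -Inf)

  # no data: posterior is the prior
  gam <- dirichlet_weights(g, 2, 5, 6, 2)
  tr0 <- trial_state(c(0, 0), c(0, 0))
  p <- c(0.1, 0.3)
  expect_error(log_likelihood(p, tr0), "tried doses")

  # S = 1: posterior kernel is the Beta(y + g1, n - y + g2) log kernel up
  # to a constant
  gam1 <- dirichlet_weights(g, 1, 4, 1, 3)  # (2, 2)
  ps <- seq(0.05, 0.95, by = 0.05)
  lp <- vapply(ps, function(pv) log_posterior(pv, tr, gam1), numeric(1))
  beta_kernel <- (1 + gam1[1] - 1) * log(ps) + (2 + gam1[2] - 1) * log(1 - ps)
  expect_equal(diff(range(lp - beta_kernel)), 0, tolerance = 1e-12)
})

test_that("full conditional of p_i is the constrained Beta-like kernel", {
  g <- dose_grid(1:8)
  tr <- trial_state(c(3, 3, 0), c(1, 2, 0))
  gam <- dirichlet_weights(g, 2, 5, 6, 2)
  p <- c(0.2, 0.5)
  expect_identical(conditional_logdensity_p(1, 0.6, p, tr, gam), -Inf)
  expect_identical(conditional_logdensity_p(2, 0.1, p, tr, gam), -Inf)
  expect_error(conditional_logdensity_p(3, 0.1, p, tr, gam), "index")

  # flat case: unit weights and no data at the coordinate give a constant
  lc2 <- conditional_logdensity_p(2, c(0.35, 0.6, 0.99), c(0.2, 0.5),
                                  trial_state(c(3, 0), c(1, 0)), c(1, 1, 1))
  expect_equal(diff(range(lc2)), 0)

  # S = 1: grid-normalised conditional matches the Beta density
  tr1 <- trial_state(3, 1)
  gam1 <- dirichlet_weights(g, 1, 4, 1, 3)  # (2, 2)
  xs <- seq(1e-4, 1 - 1e-4, length.out = 20001)
  lv <- conditional_logdensity_p(1, xs, 0.5, tr1, gam1)
  dens <- exp(lv - max(lv))
  dens <- dens / (sum(dens) * (xs[2] - xs[1]))
  expect_lt(max(abs(dens - dbeta(xs, 1 + gam1[1], 2 + gam1[2]))), 1e-3)
})

test_that("alpha conditional reduces to its closed form at a split base", {
  g <- dose_grid(1:8)
  p1 <- 0.37
  a <- 2; b <- 2
  # F0(d_1) = 0.5 at mu = 1: kernel reduces to
  # lgamma(al) - 2 lgamma(al/2) + (al/2 - 1) log(p (1-p)) + prior terms
  for (al in c(1.5, 5, 12)) {
    got <- conditional_logdensity_alpha(al, p1, mu = 1, sigma = 3,
                                        grid = g, a = a, b = b)
    want <- lgamma(al) - 2 * lgamma(al / 2) +
      (al / 2 - 1) * log(p1 * (1 - p1)) + (a - 1) * log(al) - b * al
    expect_equal(got, want)
  }
  # larger rate b pulls mass toward zero: kappa(2) - kappa(1) decreases in b
  d21 <- vapply(c(1, 2, 4), function(bb) {
    conditional_logdensity_alpha(2, p1, 1, 3, g, a, bb) -
      conditional_logdensity_alpha(1, p1, 1, 3, g, a, bb)
  }, numeric(1))
  expect_true(all(diff(d21) < 0))
  expect_error(conditional_logdensity_alpha(-1, p1, 1, 3, g, a, b),
               "positive")
})

test_that("(mu, sigma) conditional weights normalise and match kernels", {
  g <- dose_grid(1:8)
  p <- c(0.05, 0.15, 0.35)
  pr1 <- dp_prior(alpha = 5, mu0 = 6, sigma0 = 2)   # single grid point
  cw1 <- conditional_logweights_mu_sigma(p, 5, pr1, g)
  expect_equal(as.vector(cw1$weights), 1)

  pr <- dp_prior(alpha = 5, mu0 = 6, sigma0 = 2, r_mu = 1, r_sigma = 1)
  cw <- conditional_logweights_mu_sigma(p, 5, pr, g)
  expect_equal(sum(cw$weights), 1)
  expect_true(all(cw$weights >= 0))

  # two-point grid: weight ratio equals the direct kernel ratio
  pr2 <- dp_prior(alpha = 5, mu0 = 6, sigma0 = 2, mu_grid = c(5.5, 6.5))
  cw2 <- conditional_logweights_mu_sigma(p, 5, pr2, g)
  kern <- vapply(c(5.5, 6.5), function(m) {
    gam <- dirichlet_weights(g, 3, 5, m, 2)
    -sum(lgamma(gam)) + log_prior_density(p, gam)
  }, numeric(1))
  expect_equal(cw2$weights[1, 1] / cw2$weights[2, 1],
               exp(kern[1] - kern[2]), tolerance = 1e-10)
})

test_that("DP prior mean identity holds: E[p_k] telescopes to F0(d_k)", {
  g <- dose_grid(1:8)
  set.seed(7)
  for (al in c(2, 20)) {
    gam <- dirichlet_weights(g, 8, al, 6, 2)
    cum <- rdirichlet_cum(2e4, gam)
    expect_lt(max(abs(colMeans(cum) - base_cdf(1:8, 6, 2))), 0.01)
  }
})

test_that("dp_prior validates and builds hyperparameter grids", {
  expect_error(dp_prior(mu0 = 6, sigma0 = 2), "hyperparameters")
  expect_error(dp_prior(alpha = -1, mu0 = 6, sigma0 = 2), "positive")
  pr <- dp_prior(a = 2, b = 2, mu0 = 6, sigma0 = 2, r_mu = 1, r_sigma = 2)
  expect_false(pr$alpha_fixed)
  expect_equal(pr$alpha, 1)                # prior mean a/b
  expect_length(pr$mu_grid, 10L)
  expect_equal(range(pr$mu_grid), c(5, 7))
  # sigma grid [0, 4] drops the non-positive point
  expect_length(pr$sigma_grid, 9L)
  expect_true(all(pr$sigma_grid > 0))
})
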