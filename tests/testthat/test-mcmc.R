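test_that("envelope of a linear log-target is that line everywhere", {
  lt <- function(x) 2 * x - 1
  env <- build_envelope(lt, abscissae = c(0.2, 0.4, 0.6, 0.8),
                        lower = 0, upper = 1)
  probe <- seq(0.01, 0.99, length.out = 101)
  expect_equal(envelope_eval(env, probe), lt(probe), tolerance = 1e-12)
})

test_that("envelope dominates a log-concave target between abscissae", {
  lt <- function(x) dbeta(x, 3, 2, log = TRUE)
  env <- build_envelope(lt, abscissae = seq(0.15, 0.85, length.out = 5),
                        lower = 0.001, upper = 0.999)
  probe <- seq(0.002, 0.998, length.out = 100)
  expect_true(all(envelope_eval(env, probe) >= lt(probe) - 1e-10))
})

test_that("two abscissae leave a single defined chord as the hull", {
  lt <- function(x) dbeta(x, 3, 2, log = TRUE)
  x12 <- c(0.3, 0.7)
  env <- build_envelope(lt, x12, lower = 0.01, upper = 0.99)
  slope <- diff(lt(x12)) / diff(x12)
  chordline <- function(x) lt(x12[1]) + slope * (x - x12[1])
  probe <- seq(0.02, 0.98, length.out = 50)
  expect_equal(envelope_eval(env, probe), chordline(probe),
               tolerance = 1e-12)
})

test_that("non-finite log-target at an abscissa is rejected", {
  expect_error(build_envelope(function(x) if (x > 0.5) log(x - 0.5) else -Inf,
                              c(0.2, 0.6), lower = 0.1, upper = 0.9),
               "non-finite")
})

test_that("piecewise exponential sampling matches its closed-form CDF", {
  # flat hull on (0, 1): uniform draws
  envf <- build_envelope(function(x) 0, c(0.3, 0.7), lower = 0, upper = 1)
  set.seed(1)
  u <- sample_piecewise_exponential(envf, 1e4)
  expect_true(all(u > 0 & u < 1))
  expect_lt(abs(mean(u) - 0.5), 3 * sqrt(1 / 12 / 1e4))

  # linear hull with slope s: truncated-exponential CDF at the midpoint
  s <- 3
  envs <- build_envelope(function(x) s * x, c(0.3, 0.7),
                         lower = 0, upper = 1)
  set.seed(2)
  xs <- sample_piecewise_exponential(envs, 1e4)
  cdf_mid <- (exp(s * 0.5) - 1) / (exp(s) - 1)
  expect_lt(abs(mean(xs < 0.5) - cdf_mid), 3 * sqrt(cdf_mid * (1 - cdf_mid) / 1e4))

  # determinism under a fixed seed
  set.seed(3); a <- sample_piecewise_exponential(envs, 50)
  set.seed(3); b <- sample_piecewise_exponential(envs, 50)
  expect_identical(a, b)
})

test_that("ARMS recovers Beta(2, 2) moments and is exact on repeats", {
  lt <- function(x) dbeta(x, 2, 2, log = TRUE)
  set.seed(11)
  n <- 2e4
  x <- numeric(n)
  x[1] <- 0.5
  for (i in 2:n) x[i] <- arms_draw(lt, 0, 1, x[i - 1])
  expect_lt(abs(mean(x) - 0.5), 3 * mc_se(x))
  expect_lt(abs(var(x) - 0.05), 0.005)

  # log-concave target: the envelope dominates, so the Metropolis step
  # never rejects and the chain never repeats a value
  lt32 <- function(x) dbeta(x, 3, 2, log = TRUE)
  set.seed(12)
  y <- numeric(2000)
  y[1] <- 0.6
  for (i in 2:2000) y[i] <- arms_draw(lt32, 0, 1, y[i - 1])
  expect_equal(sum(diff(y) == 0), 0)

  # fixed seed reproducibility
  set.seed(13); d1 <- replicate(20, arms_draw(lt, 0, 1, 0.5))
  set.seed(13); d2 <- replicate(20, arms_draw(lt, 0, 1, 0.5))
  expect_identical(d1, d2)
})

test_that("alpha chain converges to its grid-normalised conditional", {
  g <- dose_grid(1:8)
  p <- c(0.05, 0.2, 0.45)
  a <- 2; b <- 0.5
  set.seed(21)
  n <- 6000
  al <- numeric(n)
  al[1] <- 4
  for (i in 2:n) al[i] <- mh_update_alpha(al[i - 1], p, 6, 2, g, a, b)
  expect_true(all(al >= 1 & al <= 20))
  # oracle: normalise the conditional kernel on a fine grid over [1, 20]
  gridx <- seq(1, 20, length.out = 2000)
  lk <- conditional_logdensity_alpha(gridx, p, 6, 2, g, a, b)
  w <- exp(lk - max(lk)); w <- w / sum(w)
  oracle_cdf <- cumsum(w)
  for (q in c(3, 6, 10, 15)) {
    expect_lt(abs(mean(al < q) - oracle_cdf[max(which(gridx < q))]),
              3 * mc_se(as.numeric(al < q)) + 0.01)
  }
})

test_that("(mu, sigma) Gibbs draw follows the categorical conditional", {
  g <- dose_grid(1:8)
  p <- c(0.05, 0.2, 0.45)
  pr1 <- dp_prior(alpha = 5, mu0 = 6, sigma0 = 2)
  expect_equal(gibbs_update_mu_sigma(p, 5, pr1, g), list(mu = 6, sigma = 2))

  pr <- dp_prior(alpha = 5, mu0 = 6, sigma0 = 2,
                 mu_grid = c(5, 6, 7), sigma_grid = c(1.5, 2.5))
  cw <- conditional_logweights_mu_sigma(p, 5, pr, g)
  set.seed(31)
  draws <- replicate(4000, {
    d <- gibbs_update_mu_sigma(p, 5, pr, g)
    paste(d$mu, d$sigma)
  })
  freq <- table(factor(draws, levels = c(t(outer(c(5, 6, 7), c(1.5, 2.5),
                                                 paste))))) / 4000
  want <- as.vector(t(cw$weights))
  expect_lt(max(abs(as.numeric(freq) - want)),
            3 * max(sqrt(want * (1 - want) / 4000)) + 0.005)

  # sequential variant targets the same stationary distribution
  set.seed(32)
  seqd <- replicate(2000, {
    d <- gibbs_update_mu_sigma(p, 5, pr, g, current_sigma = 2.5,
                               joint = FALSE)
    d$mu
  })
  expect_true(all(seqd %in% c(5, 6, 7)))
})

test_that("Gibbs sampler hits the single-dose Beta closed form", {
  g <- dose_grid(1:8)
  # gamma = (1, 1) via alpha = 2 and F0(d_1) = 0.5
  pr <- dp_prior(alpha = 2, mu0 = 1, sigma0 = 3)
  tr <- trial_state(c(3, rep(0, 7)), c(1, rep(0, 7)))
  fit <- run_gibbs(tr, g, pr, config = sampler_config(500, 10000, seed = 5))
  x <- as.vector(fit$p)
  # Beta(2, 3): mean 0.4, variance 0.04
  expect_lt(abs(mean(x) - 0.4), 3 * mc_se(x))
  expect_lt(abs(var(x) - 0.04), 0.005)
  expect_true(all(x > 0 & x < 1))
})

test_that("with no data the sampler reproduces the DP prior means", {
  g <- dose_grid(1:8)
  pr <- dp_prior(alpha = 5, mu0 = 6, sigma0 = 2)
  tr0 <- trial_state(rep(0L, 8), rep(0L, 8))
  fit <- run_gibbs(tr0, g, pr, config = sampler_config(500, 6000, seed = 9),
                   S = 8)
  f0 <- base_cdf(1:8, 6, 2)
  for (k in 1:8) {
    expect_lt(abs(mean(fit$p[, k]) - f0[k]), 3 * mc_se(fit$p[, k]) + 0.004)
  }
  # every retained draw is strictly ordered
  expect_true(all(apply(fit$p, 1, function(r) all(diff(r) > 0))))
})

test_that("sampler is deterministic given a seed and handles hyperpriors", {
  g <- dose_grid(1:8)
  tr <- trial_state(c(3, 3, 0, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0, 0, 0))
  pr <- dp_prior(a = 2, b = 2, mu0 = 6, sigma0 = 2, r_mu = 1, r_sigma = 1)
  f1 <- run_gibbs(tr, g, pr, config = fast_sampler(seed = 4))
  f2 <- run_gibbs(tr, g, pr, config = fast_sampler(seed = 4))
  expect_identical(f1$p, f2$p)
  expect_identical(f1$alpha, f2$alpha)
  # alpha proposals live in [1, 20]; mu/sigma on their grids
  expect_true(all(f1$alpha >= 1 & f1$alpha <= 20))
  expect_true(all(f1$mu %in% pr$mu_grid))
  expect_true(all(f1$sigma %in% pr$sigma_grid))
})

test_that("posterior summary reports means and sub-target probabilities", {
  fake <- structure(list(p = cbind(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7)),
                         S = 2L), class = "posterior_draws")
  s <- posterior_summary(fake, theta = 0.4)
  expect_equal(s$p_hat, c(0.2, 0.6))
  expect_equal(s$prob_below, c(1, 0))

  # S = 1 Beta case: Pr(p < theta) matches the incomplete beta function
  g <- dose_grid(1:8)
  pr <- dp_prior(alpha = 2, mu0 = 1, sigma0 = 3)   # gamma = (1, 1)
  tr <- trial_state(c(3, rep(0, 7)), c(1, rep(0, 7)))
  fit <- run_gibbs(tr, g, pr, config = sampler_config(500, 8000, seed = 6))
  s1 <- posterior_summary(fit, theta = 0.3)
  expect_lt(abs(s1$prob_below - pbeta(0.3, 2, 3)),
            3 * mc_se(as.numeric(fit$p < 0.3)))
})
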