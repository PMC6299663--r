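# ARMS-within-Gibbs sampler: R surface over the compiled core (src/).

#' MCMC settings
#'
#' @param n_burnin burn-in iterations discarded before retention.
#' @param n_keep retained iterations.
#' @param n0_init number of initial ARMS envelope abscissae per update.
#' @param max_rejects cap on envelope refinements within one ARMS draw.
#' @param seed optional RNG seed applied by [run_gibbs()]; `NULL` leaves the
#'   RNG state untouched.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_burnin = 700L, n_keep = 1000L, n0_init = 5L,
                           max_rejects = 100L, seed = NULL) {
  stopifnot(n_burnin >= 0L, n_keep > 0L, n0_init >= 2L, max_rejects > 0L)
  structure(
    list(n_burnin = as.integer(n_burnin), n_keep = as.integer(n_keep),
         n0_init = as.integer(n0_init), max_rejects = as.integer(max_rejects),
         seed = seed),
    class = "sampler_config"
  )
}

#' Build an ARMS proposal envelope
#'
#' Constructs the piecewise-linear log envelope
#' \eqn{h_i(x) = \max\{l_{i,i+1}, \min\{l_{i-1,i}, l_{i+1,i+2}\}\}} on each
#' segment between consecutive abscissae (chords \eqn{l_{jk}} of the
#' log-target; an undefined chord is replaced by its defined partner, and 0
#' when all are undefined), together with the log mass of each exponential
#' piece.
#'
#' @param log_target function returning the log target density at a point.
#' @param abscissae strictly increasing points interior to the support.
#' @param lower,upper support interval.
#' @return An object of class `arms_envelope`.
#' @export
build_envelope <- function(log_target, abscissae, lower, upper) {
  stopifnot(length(abscissae) >= 2L, all(diff(abscissae) > 0),
            all(abscissae > lower), all(abscissae < upper))
  hx <- vapply(abscissae, log_target, numeric(1))
  if (any(!is.finite(hx))) {
    stop("non-finite log-target at an envelope abscissa")
  }
  env <- .cpp_build_envelope(abscissae, hx, lower, upper)
  env$abscissae <- abscissae
  env$log_values <- hx
  env$lower <- lower
  env$upper <- upper
  class(env) <- "arms_envelope"
  env
}

#' Evaluate an ARMS envelope
#'
#' @param env an [build_envelope()] result.
#' @param x points at which to evaluate the piecewise-linear hull.
#' @return Hull values (log scale).
#' @export
envelope_eval <- function(env, x) {
  stopifnot(inherits(env, "arms_envelope"))
  .cpp_envelope_eval(unclass(env), as.numeric(x))
}

#' Sample from the piecewise exponential proposal
#'
#' Draws from the density proportional to `exp(hull(x))` on the support:
#' a piece is chosen by its normalised mass, then the position is drawn by
#' the closed-form inverse CDF of the exponential of a line (with a stable
#' uniform fallback when the slope is numerically zero).
#'
#' @param env an [build_envelope()] result.
#' @param n number of draws.
#' @return Numeric vector of draws in `(lower, upper)`.
#' @export
sample_piecewise_exponential <- function(env, n = 1L) {
  stopifnot(inherits(env, "arms_envelope"))
  .cpp_sample_envelope(unclass(env), as.integer(n))
}

#' One adaptive rejection Metropolis sampling transition
#'
#' Rejection sampling from the envelope with refinement (each rejected
#' proposal is added to the abscissa set and the envelope rebuilt), followed
#' by a Metropolis accept/reject against the previous point using
#' \eqn{\min\{\pi, e^h\}} terms, which keeps the draw exact even when the
#' envelope does not dominate a non-log-concave target.
#'
#' @param log_target function returning the log target density.
#' @param lower,upper support interval.
#' @param previous current chain position, inside the support.
#' @param n0_init number of initial abscissae (equally spaced in the
#'   interior).
#' @param max_rejects cap on envelope refinements.
#' @return The next chain position (accepted proposal or `previous`).
#' @export
arms_draw <- function(log_target, lower, upper, previous,
                      n0_init = 5L, max_rejects = 100L) {
  stopifnot(previous > lower, previous < upper)
  .cpp_arms_draw(log_target, lower, upper, previous,
                 as.integer(n0_init), as.integer(max_rejects))
}

#' Independence-Metropolis update of the DP precision
#'
#' Proposes \eqn{\alpha^* \sim U(1, 20)} and accepts with probability
#' \eqn{\min\{1, \kappa(\alpha^*)/\kappa(\alpha)\}} where \eqn{\kappa} is
#' the full-conditional kernel [conditional_logdensity_alpha()].  With a
#' uniform independence proposal the proposal density cancels, but the
#' chain consequently lives in [1, 20] regardless of the Gamma prior's
#' support.
#'
#' @param current current precision value.
#' @param p ordered toxicity probabilities for the tried doses.
#' @param mu,sigma base-distribution parameters.
#' @param grid a [dose_grid()].
#' @param a,b Gamma hyperparameters.
#' @return The updated precision.
#' @export
mh_update_alpha <- function(current, p, mu, sigma, grid, a, b) {
  alpha_star <- stats::runif(1, 1, 20)
  lr <- conditional_logdensity_alpha(alpha_star, p, mu, sigma, grid, a, b) -
    conditional_logdensity_alpha(current, p, mu, sigma, grid, a, b)
  if (log(stats::runif(1)) <= min(0, lr)) alpha_star else current
}

#' Gibbs update of the base-distribution parameters
#'
#' Exact categorical draw of (mu, sigma) from the normalised conditional
#' weights over the discrete prior grids.  By default the draw is joint
#' over the product grid; `joint = FALSE` updates mu given the current
#' sigma and then sigma given the new mu (same stationary distribution).
#'
#' @inheritParams conditional_logweights_mu_sigma
#' @param current_sigma current sigma value, used only when
#'   `joint = FALSE`.
#' @param joint draw jointly over the product grid?
#' @return A list with elements `mu` and `sigma`.
#' @export
gibbs_update_mu_sigma <- function(p, alpha, prior, grid,
                                  current_sigma = prior$sigma0,
                                  joint = TRUE) {
  cw <- conditional_logweights_mu_sigma(p, alpha, prior, grid)
  if (joint) {
    pick <- sample.int(length(cw$weights), 1L, prob = as.vector(cw$weights))
    im <- (pick - 1L) %% length(cw$mu_grid) + 1L
    is <- (pick - 1L) %/% length(cw$mu_grid) + 1L
    return(list(mu = cw$mu_grid[im], sigma = cw$sigma_grid[is]))
  }
  is0 <- which.min(abs(cw$sigma_grid - current_sigma))
  wmu <- cw$weights[, is0]
  im <- sample.int(length(cw$mu_grid), 1L, prob = wmu / sum(wmu))
  wsg <- cw$weights[im, ]
  is <- sample.int(length(cw$sigma_grid), 1L, prob = wsg / sum(wsg))
  list(mu = cw$mu_grid[im], sigma = cw$sigma_grid[is])
}

#' Run the ARMS-within-Gibbs sampler
#'
#' Cyclically updates the DP precision (independence Metropolis against its
#' full conditional, skipped when `alpha` is fixed), the base-distribution
#' parameters (exact categorical over the grids, skipped when fixed), and
#' each ordered toxicity probability \eqn{p_1, \dots, p_S} via one ARMS
#' transition on its full conditional.  Only the `S` tried doses are
#' parameterised; untried upper doses enter through the residual Dirichlet
#' increment \eqn{1 - p_S}.
#'
#' @param trial a [trial_state()] with at least one tried dose.
#' @param grid a [dose_grid()].
#' @param prior a [dp_prior()].
#' @param init_p initial ordered probabilities for the tried doses; the
#'   default uses the base CDF at the tried doses.
#' @param config a [sampler_config()].
#' @param S number of doses to parameterise; defaults to the number of
#'   tried doses, and may be raised up to `K` (doses without data are then
#'   sampled from their conditional prior, which is how the prior itself
#'   can be simulated with an all-zero trial state).
#' @return An object of class `posterior_draws`: matrix `p`
#'   (`n_keep` x `S`), vectors `alpha`, `mu`, `sigma`, plus the
#'   configuration.
#' @examples
#' tr <- trial_state(n = c(3, 3), y = c(0, 1))
#' g <- dose_grid(1:8)
#' pr <- dp_prior(alpha = 5, mu0 = 6, sigma0 = 2)
#' fit <- run_gibbs(tr, g, pr, config = sampler_config(100, 200, seed = 1))
#' posterior_summary(fit, theta = 0.3)
#' @export
run_gibbs <- function(trial, grid, prior, init_p = NULL,
                      config = sampler_config(), S = trial$S) {
  stopifnot(inherits(trial, "trial_state"), inherits(grid, "dose_grid"),
            inherits(prior, "dp_prior"), inherits(config, "sampler_config"))
  S <- as.integer(S)
  if (S < max(1L, trial$S) || S > grid$K) {
    stop("S must cover every tried dose and not exceed K")
  }
  if (length(trial$n) < S) stop("trial state is shorter than S")
  if (is.null(init_p)) {
    init_p <- base_cdf(grid$d[seq_len(S)], prior$mu0, prior$sigma0)
  }
  init_p <- repair_monotone(init_p)
  if (length(init_p) != S) stop("init_p must have one entry per tried dose")
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .cpp_run_gibbs(
    trial$n[seq_len(S)], trial$y[seq_len(S)], grid$d[seq_len(S)],
    prior$alpha, prior$alpha_fixed,
    if (prior$alpha_fixed) 1 else prior$a,
    if (prior$alpha_fixed) 1 else prior$b,
    prior$mu_grid, prior$sigma_grid, prior$eta_fixed,
    init_p, config$n_burnin, config$n_keep, config$n0_init,
    config$max_rejects, 1e-10
  )
  structure(
    list(p = res$p, alpha = res$alpha, mu = res$mu, sigma = res$sigma,
         S = S, config = config),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", nrow(x$p), "retained iterations over", x$S,
      "tried dose(s)\n")
  cat("  posterior means p:", paste(sprintf("%.4f", colMeans(x$p)),
                                    collapse = " "), "\n")
  invisible(x)
}

#' Posterior summaries for the tried doses
#'
#' Per-dose posterior means \eqn{\hat p_k} and posterior probabilities
#' \eqn{\Pr(p_k < \theta)} (the fraction of retained draws below the
#' target), the two quantities the adaptive design consumes.
#'
#' @param draws a [run_gibbs()] result.
#' @param theta target toxicity probability.
#' @return A data frame with columns `dose`, `p_hat`, `prob_below`.
#' @export
posterior_summary <- function(draws, theta) {
  stopifnot(inherits(draws, "posterior_draws"))
  data.frame(
    dose = seq_len(draws$S),
    p_hat = colMeans(draws$p),
    prob_below = colMeans(draws$p < theta)
  )
}

# enforce strict monotonicity inside (0,1); used to sanitise initial values
repair_monotone <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  for (i in seq_along(p)[-1]) {
    if (p[i] <= p[i - 1]) p[i] <- min(p[i - 1] + eps, 1 - eps / 2)
  }
  p
}
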