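# Dirichlet-process model for the monotone dose-toxicity curve.
#
# The curve F is given a DP(alpha * F0) prior with normal-CDF base
# F0(x) = Phi((x - mu) / sigma).  Over the partition induced by the tried
# doses d_1 < ... < d_S (with d_0 = -Inf, d_{S+1} = +Inf) the increments of
# (p_1, ..., p_S, 1) are Dirichlet with weights gamma_i = alpha * dF0; the
# functions here evaluate that prior kernel, the binomial likelihood kernel
# and every full conditional the Gibbs sampler needs.

#' Normal-CDF base distribution
#'
#' The prior central dose-toxicity curve \eqn{F_0(x) = \Phi((x-\mu)/\sigma)}.
#' Its hyperparameters are chosen so that the median of \eqn{F_0} matches
#' the prior guess of the MTD, i.e. \eqn{F_0(d_\nu) = \theta} at the guessed
#' target level \eqn{d_\nu}.
#'
#' @param x dose value(s) at which to evaluate the CDF.
#' @param mu location, in dose-label units.
#' @param sigma positive scale.
#' @return Probabilities \eqn{\Phi((x-\mu)/\sigma)}.
#' @examples
#' base_cdf(1:8, mu = 6, sigma = 2)
#' @export
base_cdf <- function(x, mu, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("invalid base distribution: sigma must be a single positive number")
  }
  stats::pnorm((x - mu) / sigma)
}

#' Dirichlet-process prior specification
#'
#' The DP precision `alpha` is either fixed or given a Gamma(shape `a`,
#' rate `b`) hyperprior (mean `a/b`).  The base-distribution parameters
#' (`mu0`, `sigma0`) are either fixed or given discrete uniform priors on
#' equally spaced grids over `[mu0 - r_mu, mu0 + r_mu]` and
#' `[sigma0 - r_sigma, sigma0 + r_sigma]`; grid points at or below zero on
#' the sigma axis are dropped, since the scale must be positive.
#'
#' @param alpha fixed DP precision (> 0), or `NULL` to use the Gamma
#'   hyperprior.
#' @param a,b Gamma shape and rate for `alpha` when it is not fixed.
#' @param mu0,sigma0 centre of the base distribution (`sigma0 > 0`).
#' @param r_mu,r_sigma half-widths of the hyperprior grids (typically 1 or
#'   2); `NULL` fixes the corresponding parameter at its centre.
#' @param G number of equally spaced grid points per axis.
#' @param mu_grid,sigma_grid explicit grids overriding the half-width
#'   construction.
#'
#' @return An object of class `dp_prior`.
#' @examples
#' dp_prior(alpha = 5, mu0 = 6, sigma0 = 2)                   # all fixed
#' dp_prior(a = 2, b = 2, mu0 = 6, sigma0 = 2, r_mu = 1, r_sigma = 1)
#' @export
dp_prior <- function(alpha = NULL, a = NULL, b = NULL, mu0, sigma0,
                     r_mu = NULL, r_sigma = NULL, G = 10L,
                     mu_grid = NULL, sigma_grid = NULL) {
  if (sigma0 <= 0) stop("sigma0 must be positive")
  alpha_fixed <- !is.null(alpha)
  if (alpha_fixed) {
    if (alpha <= 0) stop("alpha must be positive")
    a <- b <- NA_real_
  } else {
    if (is.null(a) || is.null(b) || a <= 0 || b <= 0) {
      stop("when alpha is not fixed, Gamma hyperparameters a > 0, b > 0 ",
           "are required")
    }
  }
  if (is.null(mu_grid)) {
    mu_grid <- if (is.null(r_mu)) mu0 else
      seq(mu0 - r_mu, mu0 + r_mu, length.out = G)
  }
  if (is.null(sigma_grid)) {
    sigma_grid <- if (is.null(r_sigma)) sigma0 else
      seq(sigma0 - r_sigma, sigma0 + r_sigma, length.out = G)
  }
  sigma_grid <- sigma_grid[sigma_grid > 0]
  if (!length(mu_grid) || !length(sigma_grid)) {
    stop("hyperparameter grids must be non-empty")
  }
  if (is.unsorted(mu_grid, strictly = TRUE) ||
      is.unsorted(sigma_grid, strictly = TRUE)) {
    stop("hyperparameter grids must be strictly increasing")
  }
  eta_fixed <- length(mu_grid) == 1L && length(sigma_grid) == 1L
  structure(
    list(alpha = if (alpha_fixed) alpha else a / b,
         alpha_fixed = alpha_fixed, a = a, b = b,
         mu0 = mu0, sigma0 = sigma0,
         mu_grid = mu_grid, sigma_grid = sigma_grid,
         eta_fixed = eta_fixed),
    class = "dp_prior"
  )
}

#' @export
print.dp_prior <- function(x, ...) {
  cat("DP prior on the dose-toxicity curve\n")
  if (x$alpha_fixed) {
    cat("  precision alpha =", x$alpha, "(fixed)\n")
  } else {
    cat("  precision alpha ~ Gamma(shape", x$a, ", rate", x$b, ")\n")
  }
  cat("  base F0 = Phi((x -", x$mu0, ") /", x$sigma0, ")",
      if (x$eta_fixed) "(fixed)\n" else
        sprintf("with %d x %d (mu, sigma) grid\n",
                length(x$mu_grid), length(x$sigma_grid)))
  invisible(x)
}

#' Dirichlet weights over the tried-dose partition
#'
#' Weights \eqn{\gamma_i = \alpha\{F_0(d_i) - F_0(d_{i-1})\}} for
#' \eqn{i = 1, \dots, S+1}, with \eqn{F_0(d_0) = 0} and the last increment
#' \eqn{\alpha\{1 - F_0(d_S)\}} absorbing all untried upper doses.  They sum
#' to `alpha` exactly.
#'
#' @param grid a [dose_grid()].
#' @param S number of tried doses (1..K).
#' @param alpha DP precision.
#' @param mu,sigma base-distribution parameters.
#' @return Positive numeric vector of length `S + 1`.
#' @examples
#' g <- dose_grid(1:8)
#' dirichlet_weights(g, S = 8, alpha = 5, mu = 6, sigma = 2)
#' @export
dirichlet_weights <- function(grid, S, alpha, mu, sigma) {
  stopifnot(inherits(grid, "dose_grid"))
  if (S < 1L || S > grid$K) stop("S must be in 1..K")
  F0 <- base_cdf(grid$d[seq_len(S)], mu, sigma)
  gam <- alpha * diff(c(0, F0, 1))
  pmax(gam, .Machine$double.xmin)
}

#' Log Dirichlet prior kernel of the ordered toxicity probabilities
#'
#' Evaluates \eqn{\sum_{i=1}^{S+1} (\gamma_i - 1)\log(p_i - p_{i-1})} with
#' the padding \eqn{p_0 = 0}, \eqn{p_{S+1} = 1}.  This is the prior density
#' up to the Dirichlet normalising constant (see
#' [log_dirichlet_normalizer()]).
#'
#' @param p strictly increasing probabilities \eqn{p_1 < \dots < p_S}.
#' @param gamma Dirichlet weights of length `length(p) + 1`.
#' @return The log kernel (a single number).
#' @export
log_prior_density <- function(p, gamma) {
  if (length(gamma) != length(p) + 1L) {
    stop("gamma must have length length(p) + 1")
  }
  dp <- diff(c(0, p, 1))
  if (any(dp <= 0)) stop("monotonicity violation: p must satisfy 0 < p_1 < ... < p_S < 1")
  sum((gamma - 1) * log(dp))
}

#' Log normalising constant of the ordered-Dirichlet prior
#'
#' \eqn{\log\Gamma(\sum_i \gamma_i) - \sum_i \log\Gamma(\gamma_i)}.  The
#' sampler only ever needs the kernel, so this constant is exposed
#' separately.
#'
#' @param gamma positive Dirichlet weights.
#' @return The log normaliser.
#' @export
log_dirichlet_normalizer <- function(gamma) {
  lgamma(sum(gamma)) - sum(lgamma(gamma))
}

#' Binomial log-likelihood kernel of the tried doses
#'
#' \eqn{\sum_{i=1}^{S} \{y_i\log p_i + (n_i-y_i)\log(1-p_i)\}}, omitting
#' the combinatorial constants.  Terms with a zero count contribute zero
#' even at boundary probabilities; conflicting counts at \eqn{p_i \in
#' \{0,1\}} yield `-Inf`.
#'
#' @param p toxicity probabilities for the `S` tried doses.
#' @param trial a [trial_state()]; only the first `length(p)` doses are
#'   used and must match `trial$S`.
#' @return The log-likelihood kernel.
#' @export
log_likelihood <- function(p, trial) {
  stopifnot(inherits(trial, "trial_state"))
  S <- length(p)
  if (S != trial$S) stop("length(p) must equal the number of tried doses")
  if (S == 0L) return(0)
  y <- trial$y[seq_len(S)]
  n <- trial$n[seq_len(S)]
  term <- function(cnt, lp) ifelse(cnt == 0, 0, cnt * lp)
  sum(term(y, log(p)) + term(n - y, log1p(-p)))
}

#' Unnormalised log posterior of the ordered toxicity probabilities
#'
#' Sum of [log_likelihood()] and [log_prior_density()].
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior_density
#' @return The unnormalised log posterior.
#' @export
log_posterior <- function(p, trial, gamma) {
  log_likelihood(p, trial) + log_prior_density(p, gamma)
}

#' Full-conditional log density of a single toxicity probability
#'
#' The Gibbs full conditional of \eqn{p_i} given the others:
#' \deqn{p^{y_i}(1-p)^{n_i-y_i}(p-p_{i-1})^{\gamma_i-1}(p_{i+1}-p)^{\gamma_{i+1}-1}}
#' on the support \eqn{(p_{i-1}, p_{i+1})}, in log form; `-Inf` outside the
#' support.
#'
#' @param i coordinate index in 1..S.
#' @param p_value point at which to evaluate.
#' @param p current vector of ordered toxicity probabilities.
#' @inheritParams log_likelihood
#' @param gamma Dirichlet weights of length `length(p) + 1`.
#' @return The conditional log density (up to a constant).
#' @export
conditional_logdensity_p <- function(i, p_value, p, trial, gamma) {
  S <- length(p)
  if (i < 1L || i > S) stop("coordinate index out of range 1..S")
  plo <- if (i == 1L) 0 else p[i - 1L]
  phi <- if (i == S) 1 else p[i + 1L]
  vapply(p_value, function(pv) {
    if (pv <= plo || pv >= phi) return(-Inf)
    yi <- trial$y[i]
    ni <- trial$n[i]
    lik <- (if (yi > 0) yi * log(pv) else 0) +
      (if (ni - yi > 0) (ni - yi) * log1p(-pv) else 0)
    lik + (gamma[i] - 1) * log(pv - plo) + (gamma[i + 1L] - 1) * log(phi - pv)
  }, numeric(1))
}

#' Full-conditional log kernel of the DP precision
#'
#' \deqn{\log\Gamma(\alpha) - \sum_i \log\Gamma(\gamma_i(\alpha)) +
#'       \sum_i (\gamma_i(\alpha)-1)\log(p_i-p_{i-1}) +
#'       (a-1)\log\alpha - b\alpha,}
#' with \eqn{\gamma_i(\alpha)} recomputed from `alpha_value` at the fixed
#' base distribution.
#'
#' @param alpha_value positive precision value(s) at which to evaluate.
#' @param p ordered toxicity probabilities for the tried doses.
#' @param mu,sigma base-distribution parameters.
#' @param grid a [dose_grid()].
#' @param a,b Gamma hyperparameters (shape, rate).
#' @return The conditional log kernel.
#' @export
conditional_logdensity_alpha <- function(alpha_value, p, mu, sigma, grid,
                                         a, b) {
  S <- length(p)
  F0 <- base_cdf(grid$d[seq_len(S)], mu, sigma)
  w <- pmax(diff(c(0, F0, 1)), .Machine$double.xmin)
  ldp <- log(diff(c(0, p, 1)))
  vapply(alpha_value, function(al) {
    if (al <= 0) stop("alpha must be positive")
    gam <- al * w
    lgamma(al) - sum(lgamma(gam)) + sum((gam - 1) * ldp) +
      (a - 1) * log(al) - b * al
  }, numeric(1))
}

#' Conditional weights of the base-distribution parameters
#'
#' Evaluates the Dirichlet kernel over every (mu, sigma) pair of the prior
#' grids, with the weights recomputed per pair, and normalises in log space
#' (so simultaneous underflow across the grid cannot produce an all-zero
#' table).
#'
#' @param p ordered toxicity probabilities for the tried doses.
#' @param alpha current DP precision.
#' @param prior a [dp_prior()] supplying the grids.
#' @param grid a [dose_grid()].
#' @return A list with `mu_grid`, `sigma_grid`, the normalised `weights`
#'   matrix (rows = mu, columns = sigma, summing to 1) and the raw
#'   `log_weights`.
#' @export
conditional_logweights_mu_sigma <- function(p, alpha, prior, grid) {
  stopifnot(inherits(prior, "dp_prior"), inherits(grid, "dose_grid"))
  S <- length(p)
  ldp <- log(diff(c(0, p, 1)))
  d <- grid$d[seq_len(S)]
  lw <- outer(
    seq_along(prior$mu_grid), seq_along(prior$sigma_grid),
    Vectorize(function(im, is) {
      F0 <- base_cdf(d, prior$mu_grid[im], prior$sigma_grid[is])
      gam <- pmax(alpha * diff(c(0, F0, 1)), .Machine$double.xmin)
      -sum(lgamma(gam)) + sum((gam - 1) * ldp)
    })
  )
  w <- exp(lw - max(lw))
  list(mu_grid = prior$mu_grid, sigma_grid = prior$sigma_grid,
       weights = w / sum(w), log_weights = lw)
}
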