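# Classical one-parameter CRM comparators: indifference-interval skeletons,
# posterior mean of beta by deterministic quadrature, and the model-based
# dose-assignment rule.

#' Indifference-interval skeleton
#'
#' Builds the prior guess \eqn{p_{01} < \dots < p_{0K}} for the empiric
#' (power) CRM so that consecutive doses have indifference intervals
#' \eqn{[\theta - \delta, \theta + \delta]}: the skeleton is anchored at
#' \eqn{p_{0\nu} = \theta} and extended outward by the recursion in which
#' the power-model slope putting the current dose at one edge of the
#' interval maps the next dose onto the target.
#'
#' @param delta indifference half-width, in `(0, min(theta, 1 - theta))`.
#' @param theta target toxicity probability.
#' @param nu prior guess of the MTD position (1..K).
#' @param K number of dose levels.
#' @return An object of class `crm_skeleton`: the numeric skeleton with
#'   attributes `delta`, `theta`, `nu`.
#' @examples
#' get_skeleton(0.05, 0.3, 5, 8)
#' @export
get_skeleton <- function(delta, theta, nu, K) {
  if (delta <= 0 || delta >= min(theta, 1 - theta)) {
    stop("delta must lie in (0, min(theta, 1 - theta))")
  }
  if (nu < 1 || nu > K) stop("nu must be in 1..K")
  p0 <- numeric(K)
  p0[nu] <- theta
  if (nu < K) {
    for (k in nu:(K - 1)) {
      # slope that puts dose k at the lower interval edge maps k+1 to target
      expb <- log(theta - delta) / log(p0[k])
      p0[k + 1] <- (theta + delta)^(1 / expb)
    }
  }
  if (nu > 1) {
    for (k in nu:2) {
      expb <- log(theta + delta) / log(p0[k])
      p0[k - 1] <- (theta - delta)^(1 / expb)
    }
  }
  if (any(p0 <= 0) || any(p0 >= 1) || any(diff(p0) <= 0)) {
    stop("infeasible delta: skeleton left (0, 1) or lost monotonicity")
  }
  structure(p0, class = "crm_skeleton", delta = delta, theta = theta, nu = nu)
}

#' @export
print.crm_skeleton <- function(x, ...) {
  cat("CRM skeleton (delta =", attr(x, "delta"), ", anchor dose",
      attr(x, "nu"), "at theta =", attr(x, "theta"), "):\n")
  print(round(as.numeric(x), 4))
  invisible(x)
}

#' One-parameter CRM model
#'
#' Either the empiric power model \eqn{p_k(\beta) = p_{0k}^{\exp(\beta)}}
#' or the one-parameter logistic model
#' \eqn{p_k(\beta) = \mathrm{expit}(a_0 + \beta x_k)} with standardised
#' doses \eqn{x_k = \mathrm{logit}(p_{0k}) - a_0}, so that \eqn{\beta = 1}
#' recovers the skeleton.  The prior on \eqn{\beta} is normal with mean 0
#' and variance `beta_prior_var`.
#'
#' @param variant `"power"` or `"logistic"`.
#' @param skeleton skeleton probabilities (e.g. from [get_skeleton()]).
#' @param theta target toxicity probability.
#' @param a0 fixed logistic intercept.
#' @param beta_prior_var prior variance of `beta`.
#' @return An object of class `crm_model`.
#' @export
crm_model <- function(variant = c("power", "logistic"), skeleton,
                      theta = 0.3, a0 = 3, beta_prior_var = 1.34) {
  variant <- match.arg(variant)
  skeleton <- as.numeric(skeleton)
  if (any(skeleton <= 0) || any(skeleton >= 1) || any(diff(skeleton) <= 0)) {
    stop("skeleton must be strictly increasing within (0, 1)")
  }
  if (beta_prior_var <= 0) stop("beta_prior_var must be positive")
  structure(
    list(variant = variant, skeleton = skeleton, K = length(skeleton),
         theta = theta, a0 = a0, beta_prior_var = beta_prior_var,
         xstd = stats::qlogis(skeleton) - a0),
    class = "crm_model"
  )
}

#' @export
print.crm_model <- function(x, ...) {
  cat("One-parameter", x$variant, "CRM,", x$K, "doses, theta =", x$theta,
      ", beta ~ N(0,", x$beta_prior_var, ")\n")
  cat("  skeleton:", paste(round(x$skeleton, 3), collapse = " "), "\n")
  invisible(x)
}

#' Model-implied toxicity probabilities
#'
#' @param model a [crm_model()].
#' @param beta slope parameter value.
#' @param k dose indices (defaults to all).
#' @return Toxicity probabilities at the requested doses.
#' @examples
#' m <- crm_model("power", get_skeleton(0.05, 0.3, 5, 8))
#' crm_dose_toxicity(m, beta = 0)   # the skeleton itself
#' @export
crm_dose_toxicity <- function(model, beta, k = seq_len(model$K)) {
  stopifnot(inherits(model, "crm_model"))
  if (any(k < 1) || any(k > model$K)) stop("invalid dose index")
  switch(model$variant,
    power = model$skeleton[k]^exp(beta),
    logistic = stats::plogis(model$a0 + beta * model$xstd[k])
  )
}

# log posterior kernel of beta on a vector of beta values, given per-dose
# aggregated counts (n, y); vectorised over beta
crm_log_post_beta <- function(model, n, y, beta) {
  lp <- dnorm(beta, 0, sqrt(model$beta_prior_var), log = TRUE)
  used <- which(n > 0)
  for (k in used) {
    pk <- crm_dose_toxicity(model, beta, k)
    pk <- pmin(pmax(pk, 1e-300), 1 - 1e-16)
    lp <- lp + y[k] * log(pk) + (n[k] - y[k]) * log1p(-pk)
  }
  lp
}

#' Posterior mean of the CRM slope parameter
#'
#' \eqn{\hat\beta = \int \beta L(\beta) f(\beta) d\beta / \int L(\beta)
#' f(\beta) d\beta} with the normal prior \eqn{f}, computed by
#' deterministic trapezoidal quadrature on \eqn{\beta \in [-10, 10]}.
#'
#' @param model a [crm_model()].
#' @param n,y per-dose aggregated patient and toxicity counts (length K).
#' @param n_nodes number of quadrature nodes (odd counts recommended).
#' @return The posterior mean of beta (0 with no data).
#' @export
crm_posterior_mean_beta <- function(model, n, y, n_nodes = 4001L) {
  stopifnot(inherits(model, "crm_model"))
  if (sum(n) == 0) return(0)
  beta <- seq(-10, 10, length.out = n_nodes)
  lp <- crm_log_post_beta(model, n, y, beta)
  w <- exp(lp - max(lp))
  # trapezoid weights on the uniform grid
  tw <- rep(1, n_nodes); tw[c(1, n_nodes)] <- 0.5
  denom <- sum(tw * w)
  if (denom <= 0 || !is.finite(denom)) {
    stop("vanishing posterior normaliser in beta quadrature")
  }
  sum(tw * w * beta) / denom
}

#' CRM dose recommendation
#'
#' The dose whose model-implied toxicity probability is closest to the
#' target; ties go to the lower dose.
#'
#' @param model a [crm_model()].
#' @param beta_hat posterior mean of beta.
#' @return The recommended dose index.
#' @export
crm_next_dose <- function(model, beta_hat) {
  stopifnot(inherits(model, "crm_model"))
  which.min(abs(crm_dose_toxicity(model, beta_hat) - model$theta))
}
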