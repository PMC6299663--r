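# Built-in simulation scenarios: six true dose-toxicity curves over eight
# dose levels (d_k = k) with target theta = 0.3, each with its CRM skeleton
# (indifference-interval construction at the scenario's delta and anchor)
# and the matching normal base curve F0 whose median sits at the prior MTD
# guess.

#' Built-in toxicity scenarios
#'
#' Six single-agent scenarios over eight dose levels with target
#' \eqn{\theta = 0.3}: a steadily increasing curve with the MTD at level 5;
#' the same with a sudden jump to unacceptable toxicity above the MTD; two
#' flat curves with the MTD at (or just beyond) the top dose; and two
#' curves where every dose is at or above the target so the lowest dose is
#' the only defensible choice.  Each scenario carries its true
#' probabilities, CRM skeleton, skeleton half-width `delta`, anchor
#' position `nu`, base-curve parameters (`mu`, `sigma`) and the true MTD
#' index (`NA` when no dose hits the target exactly).
#'
#' @return A named list of six `ncrm_scenario` objects.
#' @examples
#' sc <- builtin_scenarios()
#' sc[[1]]$true_p
#' @export
builtin_scenarios <- function() {
  mk <- function(id, true_p, skeleton, delta, nu, mu, sigma, target_dose) {
    structure(
      list(id = id, true_p = true_p, skeleton = skeleton, delta = delta,
           nu = nu, mu = mu, sigma = sigma, target_dose = target_dose,
           theta = 0.3, doses = seq_along(true_p)),
      class = "ncrm_scenario"
    )
  }
  list(
    scenario1 = mk(1L,
      true_p = c(0.05, 0.08, 0.12, 0.20, 0.30, 0.45, 0.60, 0.70),
      skeleton = c(0.03, 0.06, 0.12, 0.20, 0.30, 0.40, 0.50, 0.59),
      delta = 0.05, nu = 5L, mu = 6, sigma = 2, target_dose = 5L),
    scenario2 = mk(2L,
      true_p = c(0.05, 0.08, 0.12, 0.20, 0.30, 0.60, 0.80, 0.90),
      skeleton = c(0.002, 0.01, 0.06, 0.16, 0.30, 0.45, 0.59, 0.71),
      delta = 0.075, nu = 5L, mu = 6, sigma = 2, target_dose = 5L),
    scenario3 = mk(3L,
      true_p = c(0.01, 0.05, 0.10, 0.14, 0.18, 0.22, 0.25, 0.30),
      skeleton = c(0.02, 0.04, 0.06, 0.10, 0.14, 0.18, 0.24, 0.30),
      delta = 0.03, nu = 8L, mu = 10, sigma = 5, target_dose = 8L),
    scenario4 = mk(4L,
      true_p = c(0.01, 0.05, 0.08, 0.12, 0.16, 0.20, 0.24, 0.26),
      skeleton = c(0.003, 0.01, 0.03, 0.05, 0.10, 0.15, 0.22, 0.30),
      delta = 0.04, nu = 8L, mu = 10, sigma = 5, target_dose = NA_integer_),
    scenario5 = mk(5L,
      true_p = c(0.30, 0.40, 0.50, 0.60, 0.70, 0.80, 0.90, 0.95),
      skeleton = c(0.30, 0.44, 0.58, 0.69, 0.78, 0.84, 0.89, 0.92),
      delta = 0.07, nu = 1L, mu = 3, sigma = 4, target_dose = 1L),
    scenario6 = mk(6L,
      true_p = c(0.40, 0.45, 0.50, 0.55, 0.60, 0.65, 0.70, 0.80),
      skeleton = c(0.30, 0.40, 0.50, 0.59, 0.67, 0.74, 0.80, 0.84),
      delta = 0.05, nu = 1L, mu = 3, sigma = 4, target_dose = NA_integer_)
  )
}

#' @export
print.ncrm_scenario <- function(x, ...) {
  cat("Scenario", x$id, "- theta =", x$theta, "\n")
  df <- data.frame(dose = x$doses, true_p = x$true_p, skeleton = x$skeleton,
                   F0 = round(base_cdf(x$doses, x$mu, x$sigma), 3))
  print(df, row.names = FALSE)
  if (!is.na(x$target_dose)) cat("True MTD: dose", x$target_dose, "\n")
  invisible(x)
}

#' DP prior matched to a scenario
#'
#' Convenience constructor: the base distribution is centred at the
#' scenario's (`mu`, `sigma`); `alpha` may be fixed or given the Gamma
#' hyperprior, and half-widths add the discrete uniform grids used when the
#' base parameters are treated as unknown.
#'
#' @param scenario a scenario from [builtin_scenarios()].
#' @inheritParams dp_prior
#' @return A [dp_prior()].
#' @export
scenario_prior <- function(scenario, alpha = NULL, a = NULL, b = NULL,
                           r_mu = NULL, r_sigma = NULL, G = 10L) {
  dp_prior(alpha = alpha, a = a, b = b, mu0 = scenario$mu,
           sigma0 = scenario$sigma, r_mu = r_mu, r_sigma = r_sigma, G = G)
}

#' CRM comparator model for a scenario
#'
#' @param scenario a scenario from [builtin_scenarios()].
#' @param variant `"power"` or `"logistic"`.
#' @return A [crm_model()] built on the scenario skeleton.
#' @export
scenario_crm <- function(scenario, variant = c("power", "logistic")) {
  crm_model(match.arg(variant), scenario$skeleton, theta = scenario$theta)
}

#' Simulate the outcomes of one cohort
#'
#' Independent Bernoulli toxicity indicators for `m` patients treated at a
#' dose with true toxicity probability `p_true`.
#'
#' @param p_true true toxicity probability at the administered dose.
#' @param m cohort size.
#' @return A list with the binary `outcomes` and their sum `count`.
#' @export
sample_cohort_outcomes <- function(p_true, m) {
  stopifnot(p_true >= 0, p_true <= 1, m >= 1)
  outcomes <- as.integer(stats::runif(m) < p_true)
  list(outcomes = outcomes, count = sum(outcomes))
}
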