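# Two-stage adaptive dose-finding design and full-trial orchestration.
#
# Stage I escalates one level per cohort from the lowest dose until the
# first toxicity.  Stage II then repeats the current dose once and, after
# every subsequent cohort, refits the posterior and applies threshold rules
# to Pr(p_k < theta) at the current dose: escalate above c_e, de-escalate
# below c_d, stay in between, always by at most one level.  At the maximum
# sample size the tried dose with posterior mean toxicity closest to theta
# is declared the MTD.

#' Design settings for an adaptive trial
#'
#' @param N total number of patients.
#' @param m cohort size.
#' @param J number of cohorts; must satisfy `N = J * m`.
#' @param c_e escalation threshold on \eqn{\Pr(p_k < \theta)}.
#' @param c_d de-escalation threshold; `c_e + c_d > 1` is required.
#' @param engine `"ncrm"` (nonparametric), `"crm-power"` or
#'   `"crm-logistic"`.
#' @return An object of class `design_config`.
#' @export
design_config <- function(N = 60L, m = 3L, J = N / m,
                          c_e = 0.70, c_d = 0.35,
                          engine = c("ncrm", "crm-power", "crm-logistic")) {
  engine <- match.arg(engine)
  N <- as.integer(N); m <- as.integer(m); J <- as.integer(J)
  if (N != J * m) stop("N must equal J * m")
  if (c_e <= 0 || c_e >= 1 || c_d <= 0 || c_d >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  if (c_e + c_d <= 1) stop("thresholds must satisfy c_e + c_d > 1")
  structure(list(N = N, m = m, J = J, c_e = c_e, c_d = c_d, engine = engine),
            class = "design_config")
}

#' Start-up stage transition
#'
#' Given the trial state after the latest cohort, returns the next dose and
#' whether the design switches to stage II: at least one toxicity in the
#' last cohort triggers the switch and the next cohort repeats the same
#' dose; otherwise the next cohort moves one level up (staying at the top
#' dose once reached).
#'
#' @param trial a [trial_state()] whose `cohort_log` holds at least one
#'   cohort.
#' @param grid a [dose_grid()].
#' @return A list with `next_dose` and logical `stage2`.
#' @export
startup_next <- function(trial, grid) {
  log <- trial$cohort_log
  if (is.null(log) || nrow(log) == 0L) {
    return(list(next_dose = 1L, stage2 = FALSE))
  }
  last <- log[nrow(log), ]
  if (last$y >= 1L) {
    list(next_dose = as.integer(last$dose_level), stage2 = TRUE)
  } else {
    list(next_dose = min(as.integer(last$dose_level) + 1L, grid$K),
         stage2 = FALSE)
  }
}

#' Stage-II threshold decision
#'
#' @param current current dose index.
#' @param prob_below posterior probability \eqn{\Pr(p_k < \theta)} at the
#'   current dose.
#' @param config a [design_config()].
#' @param grid a [dose_grid()].
#' @return The next dose index (moves at most one level, clamped to
#'   `1..K`).
#' @export
stage2_decision <- function(current, prob_below, config, grid) {
  stopifnot(inherits(config, "design_config"))
  if (prob_below > config$c_e) {
    min(current + 1L, grid$K)
  } else if (prob_below < config$c_d) {
    max(current - 1L, 1L)
  } else {
    as.integer(current)
  }
}

#' MTD selection at the end of a trial
#'
#' The tried dose whose posterior mean toxicity is closest to the target;
#' ties go to the lower dose.
#'
#' @param p_hat posterior mean toxicity probabilities for the tried doses.
#' @param theta target toxicity probability.
#' @return The selected dose index.
#' @export
select_mtd <- function(p_hat, theta) {
  if (!length(p_hat)) stop("at least one tried dose is required")
  which.min(abs(p_hat - theta))
}

#' Simulate one adaptive dose-finding trial
#'
#' Runs a complete trial of `config$J` cohorts under the true toxicities of
#' `scenario`, using either the nonparametric engine (posterior refits via
#' [run_gibbs()] after every stage-II cohort, initialised at the scenario
#' skeleton restricted to the tried doses) or a parametric CRM engine
#' (posterior mean of beta by quadrature after every cohort, one-level
#' moves toward the model recommendation).  Refits are independent runs;
#' no chain state is carried between cohorts.
#'
#' @param scenario a scenario object (see [builtin_scenarios()]) or any
#'   list with `true_p`, `skeleton`, `theta`, `mu`, `sigma`.
#' @param config a [design_config()].
#' @param prior a [dp_prior()] (ncrm engine) or [crm_model()] (crm
#'   engines).
#' @param sampler a [sampler_config()] used by the ncrm engine.
#' @param seed optional RNG seed for the whole trial.
#' @return An object of class `ncrm_trial`: vectors `assignments` and
#'   per-cohort toxicity counts, the outcome matrix, final counts `n`,
#'   `y`, the selected `mtd`, and the per-cohort `p_hat` trace.
#' @export
run_trial <- function(scenario, config, prior,
                      sampler = sampler_config(), seed = NULL) {
  stopifnot(inherits(config, "design_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- length(scenario$true_p)
  grid <- dose_grid(seq_len(K), theta = scenario$theta)
  if (config$engine == "ncrm") {
    stopifnot(inherits(prior, "dp_prior"))
  } else {
    stopifnot(inherits(prior, "crm_model"))
  }

  n <- integer(K); y <- integer(K)
  assignments <- integer(config$J)
  outcomes <- matrix(NA_integer_, config$J, config$m)
  p_hat_trace <- vector("list", config$J)
  stage2 <- FALSE
  cur <- 1L

  for (j in seq_len(config$J)) {
    out <- sample_cohort_outcomes(scenario$true_p[cur], config$m)
    assignments[j] <- cur
    outcomes[j, ] <- out$outcomes
    n[cur] <- n[cur] + config$m
    y[cur] <- y[cur] + out$count

    if (config$engine == "ncrm") {
      if (!stage2) {
        # stage I: escalate until the first toxicity; the first stage-II
        # cohort then repeats the current dose before any refit
        if (out$count >= 1L) {
          stage2 <- TRUE
          nxt <- cur
        } else {
          nxt <- min(cur + 1L, K)
        }
      } else {
        S <- max(which(n > 0L))
        tr <- trial_state(n, y)
        init_p <- repair_monotone(scenario$skeleton[seq_len(S)])
        fit <- run_gibbs(tr, grid, prior, init_p = init_p, config = sampler)
        summ <- posterior_summary(fit, grid$theta)
        p_hat_trace[[j]] <- summ$p_hat
        nxt <- stage2_decision(cur, summ$prob_below[cur], config, grid)
      }
    } else {
      beta_hat <- crm_posterior_mean_beta(prior, n, y)
      target <- crm_next_dose(prior, beta_hat)
      p_hat_trace[[j]] <- crm_dose_toxicity(prior, beta_hat)
      nxt <- cur + sign(target - cur)           # one level at a time
      nxt <- min(max(nxt, 1L), K)
    }
    if (j < config$J) cur <- as.integer(nxt)
  }

  if (config$engine == "ncrm") {
    S <- max(which(n > 0L))
    p_hat <- p_hat_trace[[config$J]]
    if (is.null(p_hat)) {
      # no toxicity ever observed: fit once at the end over the tried doses
      tr <- trial_state(n, y)
      fit <- run_gibbs(tr, grid, prior,
                       init_p = repair_monotone(scenario$skeleton[seq_len(S)]),
                       config = sampler)
      p_hat <- posterior_summary(fit, grid$theta)$p_hat
      p_hat_trace[[config$J]] <- p_hat
    }
    mtd <- select_mtd(p_hat, grid$theta)
  } else {
    beta_hat <- crm_posterior_mean_beta(prior, n, y)
    mtd <- crm_next_dose(prior, beta_hat)
  }

  structure(
    list(assignments = assignments, outcomes = outcomes, n = n, y = y,
         n_tox = sum(y), mtd = mtd, p_hat_trace = p_hat_trace,
         engine = config$engine),
    class = "ncrm_trial"
  )
}

#' @export
print.ncrm_trial <- function(x, ...) {
  cat("Simulated trial (", x$engine, "): ", sum(x$n), " patients, ",
      x$n_tox, " toxicities, MTD = dose ", x$mtd, "\n", sep = "")
  cat("  allocation:", paste(x$n, collapse = " "), "\n")
  invisible(x)
}
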