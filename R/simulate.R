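# Replicated-trial engine and operating characteristics.

#' Operating characteristics over replicated trials
#'
#' Replicates [run_trial()] with independent per-trial seeds drawn once
#' from the master seed (so results depend only on `seed` and `n_trials`,
#' not on execution order) and aggregates the per-dose MTD selection
#' frequencies, the mean patient allocation and the mean number of
#' toxicities per trial.
#'
#' @param scenario a scenario from [builtin_scenarios()] (or compatible
#'   list).
#' @param config a [design_config()].
#' @param prior a [dp_prior()] or [crm_model()] matching the engine.
#' @param sampler a [sampler_config()] for the nonparametric engine.
#' @param n_trials number of replicated trials.
#' @param seed master seed.
#' @return An object of class `ncrm_oc` with `selection_prob`,
#'   `avg_patients`, `avg_toxicities` (and its integer rounding, the form
#'   in which toxicity burden is usually tabulated), `n_trials`, `seed`.
#' @export
run_operating_characteristics <- function(scenario, config, prior,
                                          sampler = sampler_config(),
                                          n_trials = 1000L, seed = 1L) {
  stopifnot(n_trials >= 1L)
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)
  K <- length(scenario$true_p)
  sel <- integer(K)
  alloc <- numeric(K)
  tox <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    tr <- run_trial(scenario, config, prior, sampler, seed = trial_seeds[t])
    sel[tr$mtd] <- sel[tr$mtd] + 1L
    alloc <- alloc + tr$n
    tox[t] <- tr$n_tox
  }
  structure(
    list(selection_prob = sel / n_trials,
         avg_patients = alloc / n_trials,
         avg_toxicities = mean(tox),
         avg_toxicities_rounded = round(mean(tox)),
         n_trials = n_trials, seed = seed,
         engine = config$engine, scenario_id = scenario$id),
    class = "ncrm_oc"
  )
}

#' @export
print.ncrm_oc <- function(x, ...) {
  cat("Operating characteristics (", x$engine, ", scenario ", x$scenario_id,
      ", ", x$n_trials, " trials)\n", sep = "")
  df <- data.frame(dose = seq_along(x$selection_prob),
                   selection = sprintf("%.3f", x$selection_prob),
                   patients = sprintf("%.3f", x$avg_patients))
  print(df, row.names = FALSE)
  cat("Average toxicities per trial:", sprintf("%.2f", x$avg_toxicities),
      "(~", x$avg_toxicities_rounded, ")\n")
  invisible(x)
}

#' Calibrate the stage-II thresholds
#'
#' Grid search over escalation / de-escalation threshold pairs (subject to
#' `c_e + c_d > 1`) maximising the probability of selecting the scenario's
#' target dose over pilot replicates.  The thresholds are design
#' parameters that published operating characteristics rarely print; this
#' utility makes the data-dependent choice reproducible.
#'
#' @inheritParams run_operating_characteristics
#' @param ce_grid,cd_grid candidate threshold values.
#' @param n_pilot pilot replicates per threshold pair.
#' @return A list with the best `c_e`, `c_d`, and the full `results` data
#'   frame (one row per admissible pair).
#' @export
calibrate_thresholds <- function(scenario, prior,
                                 sampler = sampler_config(),
                                 ce_grid = seq(0.50, 0.90, by = 0.05),
                                 cd_grid = seq(0.40, 0.90, by = 0.05),
                                 n_pilot = 50L, seed = 1L) {
  if (is.na(scenario$target_dose)) {
    stop("threshold calibration needs a scenario with a true target dose")
  }
  grid_df <- expand.grid(c_e = ce_grid, c_d = cd_grid)
  grid_df <- grid_df[grid_df$c_e + grid_df$c_d > 1, , drop = FALSE]
  grid_df$correct <- NA_real_
  for (r in seq_len(nrow(grid_df))) {
    cfg <- design_config(c_e = grid_df$c_e[r], c_d = grid_df$c_d[r],
                         engine = "ncrm")
    oc <- run_operating_characteristics(scenario, cfg, prior, sampler,
                                        n_trials = n_pilot, seed = seed)
    grid_df$correct[r] <- oc$selection_prob[scenario$target_dose]
  }
  best <- grid_df[which.max(grid_df$correct), ]
  list(c_e = best$c_e, c_d = best$c_d, results = grid_df)
}
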