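# Configuration and file I/O: YAML run configuration, trial-data CSV, and
# deterministic CSV writers for traces and operating characteristics.

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the constructor arguments of
#' [dose_grid()], [dp_prior()], [design_config()] and [sampler_config()],
#' applies the package defaults for omitted fields, and validates
#' cross-field consistency.  A minimal file needs only a `scenario` id.
#'
#' @param path path to the YAML file.
#' @return A validated list with components `scenario` (id or `NULL`),
#'   `true_p`, `grid`, `prior`, `design`, `sampler`, `n_trials`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  get <- function(name, default = NULL) {
    if (is.null(raw[[name]])) default else raw[[name]]
  }

  scenario_id <- get("scenario")
  scenario <- NULL
  if (!is.null(scenario_id)) {
    sc <- builtin_scenarios()
    if (!scenario_id %in% seq_along(sc)) {
      stop("unknown scenario id: ", scenario_id)
    }
    scenario <- sc[[scenario_id]]
  }
  true_p <- get("true_p", scenario$true_p)
  theta <- get("theta", if (is.null(scenario)) 0.3 else scenario$theta)
  doses <- get("dose_values",
               if (is.null(true_p)) 1:8 else seq_along(true_p))
  grid <- dose_grid(doses, theta = theta)

  ds <- get("design", list())
  # note: total patients is `n_total`, since a bare `N` is a boolean in YAML
  n_total <- ds$n_total %||% ds[["N"]] %||% 60L
  design <- design_config(
    N = n_total, m = ds$m %||% 3L,
    J = ds$J %||% (n_total / (ds$m %||% 3L)),
    c_e = ds$c_e %||% 0.70, c_d = ds$c_d %||% 0.35,
    engine = ds$engine %||% "ncrm"
  )

  pr <- get("prior", list())
  prior <- NULL
  if (design$engine == "ncrm") {
    if (is.null(pr$alpha) && is.null(pr$a)) pr$alpha <- 5
    mu0 <- pr$mu0 %||% scenario$mu %||% stop("prior mu0 is required")
    sigma0 <- pr$sigma0 %||% scenario$sigma %||%
      stop("prior sigma0 is required")
    prior <- dp_prior(alpha = pr$alpha, a = pr$a, b = pr$b,
                      mu0 = mu0, sigma0 = sigma0,
                      r_mu = pr$r_mu, r_sigma = pr$r_sigma,
                      G = pr$G %||% 10L)
  } else {
    skel <- pr$skeleton %||% scenario$skeleton
    if (is.null(skel) && !is.null(pr$delta)) {
      skel <- get_skeleton(pr$delta, theta, pr$nu %||% grid$K, grid$K)
    }
    if (is.null(skel)) stop("a skeleton (or delta and nu) is required ",
                            "for a CRM engine")
    prior <- crm_model(sub("^crm-", "", design$engine), skel, theta = theta,
                       a0 = pr$a0 %||% 3,
                       beta_prior_var = pr$beta_prior_var %||% 1.34)
  }

  sm <- get("sampler", list())
  sampler <- sampler_config(
    n_burnin = sm$n_burnin %||% 700L, n_keep = sm$n_keep %||% 1000L,
    n0_init = sm$n0_init %||% 5L, max_rejects = sm$max_rejects %||% 100L,
    seed = sm$seed
  )

  list(scenario = scenario, true_p = true_p, grid = grid, prior = prior,
       design = design, sampler = sampler,
       n_trials = get("n_trials", 1000L), seed = get("seed", 1L),
       output = get("output"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read accumulated trial data from CSV
#'
#' Expects the header `cohort,dose_level,n,y` with one row per cohort
#' (1-based dose levels) and aggregates to a [trial_state()], validating
#' that tried doses are contiguous from the lowest level.
#'
#' @param path path to the CSV file.
#' @param K total number of dose levels (defaults to the highest level in
#'   the file).
#' @return A [trial_state()] whose `cohort_log` is the per-cohort table.
#' @export
read_trial_csv <- function(path, K = NULL) {
  df <- utils::read.csv(path)
  required <- c("cohort", "dose_level", "n", "y")
  if (!all(required %in% names(df))) {
    stop("trial CSV must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("trial CSV contains no cohorts")
  if (any(df$y > df$n) || any(df$y < 0) || any(df$n <= 0)) {
    stop("each cohort needs 0 <= y <= n with n > 0")
  }
  K <- K %||% max(df$dose_level)
  if (any(df$dose_level < 1) || any(df$dose_level > K)) {
    stop("unknown dose level in trial CSV")
  }
  n <- y <- integer(K)
  for (r in seq_len(nrow(df))) {
    k <- df$dose_level[r]
    n[k] <- n[k] + df$n[r]
    y[k] <- y[k] + df$y[r]
  }
  trial_state(n, y, cohort_log = df[order(df$cohort), ])
}

#' Write a per-cohort trial trace as CSV
#'
#' One row per cohort: cohort index, assigned dose, individual outcomes and
#' the per-dose posterior mean estimates available after that cohort
#' (4 decimal places; empty for untried doses and for start-up cohorts
#' before the first refit).
#'
#' @param trial a [run_trial()] result.
#' @param path output path.
#' @return The written data frame, invisibly.
#' @export
write_trace_csv <- function(trial, path) {
  stopifnot(inherits(trial, "ncrm_trial"))
  J <- length(trial$assignments)
  K <- length(trial$n)
  m <- ncol(trial$outcomes)
  ph <- matrix("", J, K)
  for (j in seq_len(J)) {
    est <- trial$p_hat_trace[[j]]
    if (!is.null(est)) ph[j, seq_along(est)] <- sprintf("%.4f", est)
  }
  out <- data.frame(cohort = seq_len(J), dose_level = trial$assignments)
  for (s in seq_len(m)) out[[paste0("y", s)]] <- trial$outcomes[, s]
  for (k in seq_len(K)) out[[paste0("p_hat_", k)]] <- ph[, k]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Write operating characteristics as CSV
#'
#' One row per engine/scenario with per-dose selection probabilities
#' (3 decimal places), per-dose average allocations (3 decimal places) and
#' the toxicity summary.
#'
#' @param oc an `ncrm_oc` object (or list of them) from
#'   [run_operating_characteristics()].
#' @param path output path.
#' @return The written data frame, invisibly.
#' @export
write_oc_csv <- function(oc, path) {
  if (inherits(oc, "ncrm_oc")) oc <- list(oc)
  rows <- lapply(oc, function(x) {
    K <- length(x$selection_prob)
    row <- data.frame(scenario = x$scenario_id, engine = x$engine,
                      n_trials = x$n_trials)
    for (k in seq_len(K)) {
      row[[paste0("sel_", k)]] <- sprintf("%.3f", x$selection_prob[k])
    }
    for (k in seq_len(K)) {
      row[[paste0("pat_", k)]] <- sprintf("%.3f", x$avg_patients[k])
    }
    row$avg_tox <- sprintf("%.3f", x$avg_toxicities)
    row$tox_rounded <- x$avg_toxicities_rounded
    row
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
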