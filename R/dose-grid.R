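#' Dose grid for a single-agent trial
#'
#' The set of pre-specified dose levels and the target toxicity probability.
#' Dose values are unitless labels; by convention (and in all built-in
#' scenarios) they are simply `1:K`.
#'
#' @param dose_values strictly increasing numeric vector of dose labels.
#' @param theta target toxicity probability, in (0, 1).
#'
#' @return An object of class `dose_grid` with elements `d`, `K`, `theta`.
#' @examples
#' dose_grid(1:8, theta = 0.3)
#' @export
dose_grid <- function(dose_values, theta = 0.3) {
  dose_values <- as.numeric(dose_values)
  if (length(dose_values) < 2L) {
    stop("a dose grid needs at least two dose levels")
  }
  if (any(diff(dose_values) <= 0)) {
    stop("dose values must be strictly increasing")
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    stop("theta must be a single probability in (0, 1)")
  }
  structure(
    list(d = dose_values, K = length(dose_values), theta = theta),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("Dose grid:", x$K, "levels (", paste(x$d, collapse = ", "),
      "), target theta =", x$theta, "\n")
  invisible(x)
}

#' Accumulated trial data
#'
#' Per-dose patient and toxicity counts after some number of cohorts.  Tried
#' doses must be contiguous from the lowest level (the design never skips an
#' untried dose), so the number of tried doses `S` is the index of the
#' highest dose with patients.
#'
#' @param n integer vector of per-dose patient counts.
#' @param y integer vector of per-dose toxicity counts.
#' @param cohort_log optional data frame logging one row per cohort
#'   (`cohort`, `dose_level`, `n`, `y`).
#'
#' @return An object of class `trial_state` with elements `n`, `y`, `S`,
#'   `cohort_log`.
#' @examples
#' trial_state(n = c(3, 3, 6, 0), y = c(0, 1, 2, 0))
#' @export
trial_state <- function(n, y, cohort_log = NULL) {
  n <- as.integer(n)
  y <- as.integer(y)
  if (length(n) != length(y)) {
    stop("n and y must have the same length")
  }
  if (any(n < 0L) || any(y < 0L) || any(y > n)) {
    stop("counts must satisfy 0 <= y_k <= n_k")
  }
  tried <- which(n > 0L)
  S <- if (length(tried)) max(tried) else 0L
  if (S > 0L && any(n[seq_len(S)] == 0L)) {
    stop("tried doses must be contiguous from the lowest level")
  }
  structure(
    list(n = n, y = y, S = S, cohort_log = cohort_log),
    class = "trial_state"
  )
}

#' @export
print.trial_state <- function(x, ...) {
  cat("Trial state:", sum(x$n), "patients,", sum(x$y), "toxicities over",
      x$S, "tried dose level(s)\n")
  if (x$S > 0L) {
    print(data.frame(dose = seq_along(x$n), n = x$n, y = x$y))
  }
  invisible(x)
}
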