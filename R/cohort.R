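#' Generate a development cohort
#'
#' Draws `n` subjects from the five-step two-timepoint mechanism of a
#' calibrated scenario:
#' \enumerate{
#'   \item \eqn{X_0 \sim N(0, 1)},
#'   \item \eqn{A_0 \sim \mathrm{Bern}(\mathrm{expit}(\alpha_0 + \phi x_0))},
#'   \item \eqn{X_1 \sim N(X_0 + \gamma A_0, 1)},
#'   \item \eqn{A_1 \sim \mathrm{Bern}(\theta a_0)} under the RCT design
#'     (treated subjects retained with probability \eqn{\theta}, untreated
#'     subjects never start), or \eqn{A_1 \sim
#'     \mathrm{Bern}(\mathrm{expit}(\alpha_1 + \phi x_1 + \theta a_0))} under
#'     the observational design,
#'   \item \eqn{Y \sim \mathrm{Bern}(\mathrm{expit}(\alpha_Y + \beta_{X0} x_0 +
#'     \beta_{X1} x_1 + \beta_{A0} a_0 + \beta_{A1} a_1))}.
#' }
#' Identical `(config, n, seed)` give a bit-identical cohort.
#'
#' @param config A calibrated [scenario_config()].
#' @param n Number of subjects.
#' @param seed Integer seed for this cohort's stream.
#' @return A `data.frame` of class `"msm_cohort"` with columns
#'   `x0, a0, x1, a1, y`.
#' @seealso [generate_test_mt()], [generate_test_ntt()], [subset_nbt()]
#' @export
generate_development <- function(config, n, seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is_calibrated(config))
    stop("scenario intercepts are not calibrated; run calibrate_scenario()")
  if (n < 1) stop("'n' must be >= 1")
  state <- local_rng(seed)
  on.exit(restore_rng(state))
  x0 <- stats::rnorm(n)
  a0 <- stats::rbinom(n, 1L, stats::plogis(config$alpha0 + config$phi * x0))
  x1 <- stats::rnorm(n, mean = x0 + config$gamma * a0)
  a1 <- if (config$design == "rct") {
    stats::rbinom(n, 1L, config$theta * a0)
  } else {
    stats::rbinom(n, 1L, stats::plogis(
      config$alpha1 + config$phi * x1 + config$theta * a0))
  }
  y <- stats::rbinom(n, 1L, stats::plogis(
    config$alpha_y + config$beta_x0 * x0 + config$beta_x1 * x1 +
      config$beta_a0 * a0 + config$beta_a1 * a1))
  new_cohort(x0, a0, x1, a1, y, scenario = config$name)
}

#' Generate the mix-of-treatment test cohort
#'
#' The first test set is drawn under exactly the same process as the
#' development cohort; independence is obtained by passing a seed from a
#' different stream (see [child_seed()]), not by a different mechanism.
#'
#' @inheritParams generate_development
#' @return A cohort, as for [generate_development()].
#' @export
generate_test_mt <- function(config, n, seed) {
  generate_development(config, n, seed)
}

#' Generate the no-treatment-throughout test cohort
#'
#' Treatment is withheld from everyone: \eqn{A_0 = A_1 = 0},
#' \eqn{X_1 \sim N(X_0, 1)}, and the outcome is drawn from the same outcome
#' model with both treatment terms zero. This is the population on which the
#' treatment-naive estimand (risk under no intervention now or later) can be
#' observed directly.
#'
#' @inheritParams generate_development
#' @return A cohort with `a0 = a1 = 0` everywhere.
#' @export
generate_test_ntt <- function(config, n, seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is_calibrated(config))
    stop("scenario intercepts are not calibrated; run calibrate_scenario()")
  if (n < 1) stop("'n' must be >= 1")
  state <- local_rng(seed)
  on.exit(restore_rng(state))
  x0 <- stats::rnorm(n)
  x1 <- stats::rnorm(n, mean = x0)
  y <- stats::rbinom(n, 1L, stats::plogis(
    config$alpha_y + config$beta_x0 * x0 + config$beta_x1 * x1))
  new_cohort(x0, rep(0L, n), x1, rep(0L, n), y, scenario = config$name)
}

#' Restrict a cohort to subjects untreated at baseline
#'
#' Returns exactly the rows with `a0 == 0`, order preserved. This is both the
#' fitting set of the treatment-naive modelling strategy and the
#' no-baseline-treatment evaluation population.
#'
#' @param cohort A cohort data frame with an `a0` column.
#' @return The untreated-at-baseline subset; a warning is issued if empty.
#' @export
subset_nbt <- function(cohort) {
  stopifnot(is.data.frame(cohort), "a0" %in% names(cohort))
  if (nrow(cohort) == 0L) stop("'cohort' is empty")
  out <- cohort[cohort$a0 == 0, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no subjects are untreated at baseline; returning empty cohort")
  out
}

new_cohort <- function(x0, a0, x1, a1, y, scenario = NULL) {
  out <- data.frame(x0 = x0, a0 = as.integer(a0), x1 = x1,
                    a1 = as.integer(a1), y = as.integer(y))
  class(out) <- c("msm_cohort", "data.frame")
  attr(out, "scenario") <- scenario
  out
}

#' Read or write a cohort as delimited text
#'
#' Cohorts serialize as comma-separated text with header `x0,a0,x1,a1,y`
#' (plus `sw` if weights have been appended).
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort()` returns the cohort; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path)
  need <- c("x0", "a0", "x1", "a1", "y")
  if (!all(need %in% names(raw)))
    stop("cohort file must have columns ", paste(need, collapse = ", "))
  out <- new_cohort(raw$x0, raw$a0, raw$x1, raw$a1, raw$y)
  if ("sw" %in% names(raw)) out$sw <- raw$sw
  out
}
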