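#' Define a two-timepoint simulation scenario
#'
#' A scenario bundles every parameter of the two-timepoint data-generating
#' mechanism: a standard-normal baseline covariate \eqn{X_0}, binary treatment
#' \eqn{A_0} assigned with log-odds \eqn{\alpha_0 + \phi x_0}, a follow-up
#' covariate \eqn{X_1 \sim N(X_0 + \gamma A_0, 1)}, a second treatment
#' decision \eqn{A_1} (carry-over \eqn{\theta}), and a binary outcome with
#' log-odds \eqn{\alpha_Y + \beta_{X0} x_0 + \beta_{X1} x_1 + \beta_{A0} a_0 +
#' \beta_{A1} a_1}.
#'
#' Under `design = "rct"` baseline treatment is randomized (\eqn{\phi = 0} in
#' the shipped preset) and the follow-up decision is pure retention:
#' \eqn{A_1 \sim \mathrm{Bern}(\theta a_0)} with `theta` a retention
#' *probability* in \[0, 1\], so nobody untreated at baseline starts treatment.
#' Under `design = "observational"`, \eqn{A_1 \sim
#' \mathrm{Bern}(\mathrm{expit}(\alpha_1 + \phi x_1 + \theta a_0))} with
#' `theta` a log-odds carry-over, which is what creates treatment drop-in.
#'
#' The intercepts `alpha0`, `alpha1`, `alpha_y` are usually left `NA` and
#' filled by [calibrate_scenario()] so that the marginal rates hit
#' `target_pa0`, `target_pa1`, `target_py`.
#'
#' @param name Scenario label.
#' @param design `"rct"` or `"observational"`.
#' @param phi Log-odds of treatment per unit of the current covariate.
#' @param theta Retention probability (RCT) or log-odds carry-over of prior
#'   treatment (observational).
#' @param gamma Mean shift of \eqn{X_1} per unit of \eqn{A_0}; a protective
#'   treatment that lowers the risk factor has `gamma <= 0`.
#' @param alpha0,alpha1,alpha_y Intercepts (log-odds); `NA` until calibrated.
#'   `alpha1` is unused under the RCT design.
#' @param beta_x0,beta_x1 Log-odds of outcome per unit covariate at each time.
#' @param beta_a0,beta_a1 Log-odds of outcome per treatment at each time.
#' @param n_dev,n_test Default development and test cohort sizes.
#' @param target_pa0,target_pa1,target_py Marginal probabilities the intercepts
#'   must achieve.
#' @return An object of class `"scenario_config"`.
#' @seealso [scenario_preset()], [calibrate_scenario()], [generate_development()]
#' @export
scenario_config <- function(name, design = c("rct", "observational"),
                            phi, theta, gamma = 0,
                            alpha0 = NA_real_, alpha1 = NA_real_,
                            alpha_y = NA_real_,
                            beta_x0 = log(1.5), beta_x1 = log(1.5),
                            beta_a0 = log(0.5), beta_a1 = log(0.5),
                            n_dev = 10000L, n_test = 100000L,
                            target_pa0 = 0.5, target_pa1 = target_pa0,
                            target_py = 0.2) {
  design <- match.arg(design)
  stopifnot(is.numeric(phi), length(phi) == 1L, is.finite(phi),
            is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (design == "rct" && (theta < 0 || theta > 1))
    stop("under the RCT design 'theta' is a retention probability in [0, 1]")
  for (p in c(target_pa0 = target_pa0, target_pa1 = target_pa1,
              target_py = target_py))
    if (!is.finite(p) || p <= 0 || p >= 1)
      stop("target probabilities must lie strictly inside (0, 1)")
  if (n_dev < 1 || n_test < 1) stop("cohort sizes must be >= 1")
  structure(
    list(name = as.character(name), design = design,
         phi = phi, theta = theta, gamma = gamma,
         alpha0 = alpha0, alpha1 = alpha1, alpha_y = alpha_y,
         beta_x0 = beta_x0, beta_x1 = beta_x1,
         beta_a0 = beta_a0, beta_a1 = beta_a1,
         n_dev = as.integer(n_dev), n_test = as.integer(n_test),
         target_pa0 = target_pa0, target_pa1 = target_pa1,
         target_py = target_py),
    class = "scenario_config")
}

#' Shipped simulation scenarios
#'
#' The three study designs used throughout the package: a randomized trial
#' with 50% treated at baseline and 10% treatment dropout by the second
#' timepoint, and two observational designs in which one unit of the covariate
#' doubles the odds of treatment at each time and prior treatment doubles the
#' odds of staying treated, with 50% or 20% of the population treated at each
#' timepoint. All three target a 20% marginal event rate, with
#' covariate log-odds-ratios of log(1.5) and treatment log-odds-ratios of
#' log(0.5) on the outcome at both timepoints.
#'
#' @param preset One of `"rct_10pct_dropout"`, `"obs_50pct_treated"`,
#'   `"obs_20pct_treated"`.
#' @param gamma Covariate-lowering effect of baseline treatment on \eqn{X_1}.
#' @return An uncalibrated [scenario_config()].
#' @export
scenario_preset <- function(preset = c("rct_10pct_dropout", "obs_50pct_treated",
                                       "obs_20pct_treated"),
                            gamma = 0) {
  preset <- match.arg(preset)
  switch(preset,
    rct_10pct_dropout = scenario_config(
      name = preset, design = "rct", phi = 0, theta = 0.9, gamma = gamma,
      target_pa0 = 0.5),
    obs_50pct_treated = scenario_config(
      name = preset, design = "observational", phi = log(2), theta = log(2),
      gamma = gamma, target_pa0 = 0.5),
    obs_20pct_treated = scenario_config(
      name = preset, design = "observational", phi = log(2), theta = log(2),
      gamma = gamma, target_pa0 = 0.2))
}

#' @export
print.scenario_config <- function(x, ...) {
  cal <- if (is_calibrated(x)) "calibrated" else "intercepts not yet calibrated"
  cat(sprintf("Two-timepoint scenario '%s' (%s design, %s)\n",
              x$name, x$design, cal))
  cat(sprintf("  phi = %.4g, theta = %.4g, gamma = %.4g\n",
              x$phi, x$theta, x$gamma))
  cat(sprintf("  targets: P(A0=1) = %.3g, P(A1=1) = %.3g, P(Y=1) = %.3g\n",
              x$target_pa0, x$target_pa1, x$target_py))
  if (is_calibrated(x))
    cat(sprintf("  intercepts: alpha0 = %.4f, alpha1 = %s, alphaY = %.4f\n",
                x$alpha0,
                if (is.na(x$alpha1)) "(unused)" else sprintf("%.4f", x$alpha1),
                x$alpha_y))
  invisible(x)
}

is_calibrated <- function(config) {
  !is.na(config$alpha0) && !is.na(config$alpha_y) &&
    (config$design == "rct" || !is.na(config$alpha1))
}

#' Calibrate an intercept to a target marginal probability
#'
#' Solves \eqn{f(\alpha) = p} for the intercept \eqn{\alpha} of a logistic
#' mechanism, where `marginal_prob_fn` maps an intercept to the achieved
#' marginal probability (typically a fixed-draw Monte-Carlo average of
#' `plogis(alpha + eta)`, which is smooth and strictly increasing in `alpha`).
#' The bracket is expanded geometrically until it straddles the target.
#'
#' @param target_prob Target marginal probability, strictly inside (0, 1).
#' @param marginal_prob_fn Monotone increasing function of the intercept
#'   returning the achieved marginal probability.
#' @param interval Initial search bracket for the intercept.
#' @param tol Required accuracy on the probability scale.
#' @return The calibrated intercept (log-odds).
#' @examples
#' calibrate_intercept(0.5, function(a) plogis(a))  # 0 by symmetry
#' @export
calibrate_intercept <- function(target_prob, marginal_prob_fn,
                                interval = c(-10, 10), tol = 1e-3) {
  if (!is.finite(target_prob) || target_prob <= 0 || target_prob >= 1)
    stop("'target_prob' must lie strictly inside (0, 1)")
  lo <- interval[1]; hi <- interval[2]
  f <- function(a) marginal_prob_fn(a) - target_prob
  flo <- f(lo); fhi <- f(hi)
  expansions <- 0L
  while (flo * fhi > 0 && expansions < 60L) {
    width <- hi - lo
    if (flo > 0) { lo <- lo - width; flo <- f(lo) }
    else { hi <- hi + width; fhi <- f(hi) }
    expansions <- expansions + 1L
  }
  if (flo * fhi > 0)
    stop(sprintf(
      "could not bracket the target: f(%.3g) = %.3g, f(%.3g) = %.3g",
      lo, flo + target_prob, hi, fhi + target_prob))
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-9)$root
  achieved <- marginal_prob_fn(root)
  if (abs(achieved - target_prob) >= tol)
    stop(sprintf("calibration missed the target: achieved %.5f, wanted %.5f",
                 achieved, target_prob))
  root
}

#' Calibrate all scenario intercepts by fixed-seed Monte Carlo
#'
#' Fills `alpha0`, `alpha1` (observational designs) and `alpha_y` so that the
#' simulated marginal rates of \eqn{A_0}, \eqn{A_1} and \eqn{Y} hit the
#' scenario's targets. Calibration is sequential, mirroring the generating
#' mechanism: `alpha0` is solved on draws of \eqn{X_0}, then \eqn{A_0} and
#' \eqn{X_1} are drawn and `alpha1` solved on them, then \eqn{A_1} drawn and
#' `alpha_y` solved on the full histories. Each marginal is a large-sample
#' average over a fixed internal set of draws, so the calibration is
#' deterministic for a given configuration and independent of the caller's RNG
#' state.
#'
#' @param config A [scenario_config()].
#' @param n_mc Number of Monte-Carlo draws used for each marginal.
#' @param tol Required accuracy on the probability scale.
#' @param mc_seed Internal seed for the calibration draws.
#' @return The configuration with intercepts filled in.
#' @export
calibrate_scenario <- function(config, n_mc = 2e5, tol = 1e-3,
                               mc_seed = 104729L) {
  stopifnot(inherits(config, "scenario_config"))
  state <- local_rng(mc_seed)
  on.exit(restore_rng(state))
  x0 <- stats::rnorm(n_mc)
  config$alpha0 <- calibrate_intercept(
    config$target_pa0, function(a) mean(stats::plogis(a + config$phi * x0)),
    tol = tol)
  a0 <- stats::rbinom(n_mc, 1L, stats::plogis(config$alpha0 + config$phi * x0))
  x1 <- stats::rnorm(n_mc, mean = x0 + config$gamma * a0)
  if (config$design == "rct") {
    config$alpha1 <- NA_real_
    a1 <- stats::rbinom(n_mc, 1L, config$theta * a0)
  } else {
    config$alpha1 <- calibrate_intercept(
      config$target_pa1,
      function(a) mean(stats::plogis(a + config$phi * x1 + config$theta * a0)),
      tol = tol)
    a1 <- stats::rbinom(
      n_mc, 1L,
      stats::plogis(config$alpha1 + config$phi * x1 + config$theta * a0))
  }
  eta <- config$beta_x0 * x0 + config$beta_x1 * x1 +
    config$beta_a0 * a0 + config$beta_a1 * a1
  config$alpha_y <- calibrate_intercept(
    config$target_py, function(a) mean(stats::plogis(a + eta)), tol = tol)
  config
}

#' Read or write a scenario configuration as JSON
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `read_scenario()` returns a [scenario_config()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  scenario_config(
    name = raw$name, design = raw$design, phi = raw$phi, theta = raw$theta,
    gamma = raw$gamma, alpha0 = num(raw$alpha0), alpha1 = num(raw$alpha1),
    alpha_y = num(raw$alpha_y), beta_x0 = raw$beta_x0, beta_x1 = raw$beta_x1,
    beta_a0 = raw$beta_a0, beta_a1 = raw$beta_a1,
    n_dev = raw$n_dev, n_test = raw$n_test,
    target_pa0 = raw$target_pa0, target_pa1 = raw$target_pa1,
    target_py = raw$target_py)
}

# Swap in a seeded RNG state, returning what must be restored afterwards.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a child seed from a root seed
#'
#' Deterministic splitting rule used by the experiment harness so that each
#' cohort, replicate and scenario cell draws from its own reproducible stream:
#' `child_seed(root, i)` applies a Lehmer-style mixing step and folds in the
#' stream index, keeping the result a positive 32-bit integer. Distinct
#' `(root, stream)` pairs map to distinct seeds for the stream ranges used
#' here.
#'
#' @param seed Root seed (positive integer).
#' @param stream Stream index (non-negative integer).
#' @return A positive integer seed below 2^31.
#' @export
child_seed <- function(seed, stream) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  s <- (as.numeric(seed) %% m) + 1
  v <- (s * 48271) %% m
  v <- (v * 69621 + as.numeric(stream) * 268435399) %% m
  as.integer(v + 1)
}
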