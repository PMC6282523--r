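#' Fit treatment-assignment models for stabilized weights
#'
#' Fits the four logistic treatment models of the two-timepoint setting by
#' maximum likelihood:
#' \itemize{
#'   \item denominator, time 0: \eqn{\mathrm{logit} P(A_0 = 1 \mid X_0)};
#'   \item numerator, time 0: the same design (the lagged treatment
#'     \eqn{a_{-1} \equiv 0} drops out), so the time-0 factors cancel exactly
#'     in the stabilized weight;
#'   \item denominator, time 1:
#'     \eqn{\mathrm{logit} P(A_1 = 1 \mid A_0, X_0, X_1)};
#'   \item numerator, time 1: \eqn{\mathrm{logit} P(A_1 = 1 \mid A_0, X_0)}.
#' }
#' The numerator design is a strict subset of the denominator design: lagged
#' treatment and baseline covariate only, versus the full covariate history.
#'
#' @param cohort A cohort with columns `x0, a0, x1, a1`.
#' @return An object of class `"treatment_models"`: a list of named
#'   coefficient vectors `den0`, `num0`, `den1`, `num1`.
#' @details Quasi-separation arising from structural zeroes (e.g. randomized
#'   designs where nobody untreated at baseline starts treatment, so fitted
#'   follow-up probabilities for those subjects approach 0) is tolerated; the
#'   fitted probabilities are clipped when weights are formed. Complete
#'   separation, where the model perfectly classifies every observation, is an
#'   error, as is a timepoint with no variation in treatment.
#' @export
fit_treatment_models <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("x0", "a0", "x1", "a1") %in% names(cohort)))
  for (v in c("a0", "a1"))
    if (length(unique(cohort[[v]])) < 2L)
      stop(sprintf(
        "'%s' has no variation: all subjects %streated at that timepoint",
        v, if (any(cohort[[v]] == 1)) "" else "un"))
  n <- nrow(cohort)
  one <- rep(1, n)
  den0 <- fit_logit(cbind(`(Intercept)` = one, x0 = cohort$x0), cohort$a0)
  den1 <- fit_logit(cbind(`(Intercept)` = one, a0 = cohort$a0,
                          x0 = cohort$x0, x1 = cohort$x1), cohort$a1)
  num1 <- fit_logit(cbind(`(Intercept)` = one, a0 = cohort$a0,
                          x0 = cohort$x0), cohort$a1)
  structure(list(den0 = den0, num0 = den0, den1 = den1, num1 = num1),
            class = "treatment_models")
}

#' @export
print.treatment_models <- function(x, ...) {
  cat("Treatment-assignment models (logistic, maximum likelihood)\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: ", nm))
    cat(paste(sprintf("%s=%.4f", names(x[[nm]]), x[[nm]]), collapse = ", "))
    cat("\n")
  }
  invisible(x)
}

# Plain logistic ML fit on a numeric design matrix, with complete-separation
# detection. Returns the named coefficient vector.
fit_logit <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 50, epsilon = 1e-10)))
  p <- fit$fitted.values
  eps <- 1e-8
  if (all(p[y == 1] > 1 - eps) && all(p[y == 0] < eps))
    stop("complete separation in a treatment model: refusing to return ",
         "divergent coefficients")
  structure(fit$coefficients, names = colnames(X))
}

lp_from <- function(coefs, X) drop(X %*% coefs[colnames(X)])

#' Compute stabilized inverse-probability-of-treatment weights
#'
#' For each subject the stabilized weight is
#' \deqn{sw_i = \prod_k \hat p^{*a_{ki}}_{ki} (1 - \hat p^*_{ki})^{1 - a_{ki}}
#'   \; / \; \prod_k \hat p^{a_{ki}}_{ki} (1 - \hat p_{ki})^{1 - a_{ki}},}
#' the ratio of the numerator-model to denominator-model probability of the
#' subject's own observed treatment history. Fitted probabilities are clipped
#' to `[clip, 1 - clip]` before the ratio is formed, which bounds the weights
#' without touching well-behaved fits; subjects whose unclipped probability of
#' their observed treatment is numerically 0 are counted in the `n_clipped`
#' diagnostic. Weights are untruncated by default; `truncate` optionally
#' winsorizes at the given lower/upper quantiles.
#'
#' @param cohort The cohort the models were fitted on (or one with the same
#'   design).
#' @param models A [fit_treatment_models()] result.
#' @param clip Probability clipping bound.
#' @param truncate `NULL` (default, no truncation) or a length-2 vector of
#'   quantiles such as `c(0.01, 0.99)`.
#' @return A numeric vector of class `"stabilized_weights"` with per-timepoint
#'   factors in attributes.
#' @export
compute_stabilized_weights <- function(cohort, models, clip = 1e-6,
                                       truncate = NULL) {
  stopifnot(inherits(models, "treatment_models"))
  n <- nrow(cohort)
  one <- rep(1, n)
  X0 <- cbind(`(Intercept)` = one, x0 = cohort$x0)
  X1d <- cbind(`(Intercept)` = one, a0 = cohort$a0, x0 = cohort$x0,
               x1 = cohort$x1)
  X1n <- cbind(`(Intercept)` = one, a0 = cohort$a0, x0 = cohort$x0)
  p_den0 <- stats::plogis(lp_from(models$den0, X0))
  p_num0 <- stats::plogis(lp_from(models$num0, X0))
  p_den1 <- stats::plogis(lp_from(models$den1, X1d))
  p_num1 <- stats::plogis(lp_from(models$num1, X1n))
  obs_prob <- function(p, a) ifelse(a == 1, p, 1 - p)
  raw <- cbind(obs_prob(p_den0, cohort$a0), obs_prob(p_den1, cohort$a1))
  n_clipped <- sum(raw < clip | raw > 1 - clip)
  cl <- function(p) pmin(pmax(p, clip), 1 - clip)
  f0 <- obs_prob(cl(p_num0), cohort$a0) / obs_prob(cl(p_den0), cohort$a0)
  f1 <- obs_prob(cl(p_num1), cohort$a1) / obs_prob(cl(p_den1), cohort$a1)
  sw <- f0 * f1
  if (!is.null(truncate)) {
    stopifnot(length(truncate) == 2L, truncate[1] < truncate[2])
    q <- stats::quantile(sw, truncate, names = FALSE)
    sw <- pmin(pmax(sw, q[1]), q[2])
  }
  structure(sw, factor0 = f0, factor1 = f1, n_clipped = n_clipped,
            class = "stabilized_weights")
}

#' @export
print.stabilized_weights <- function(x, ...) {
  cat(sprintf("Stabilized weights for %d subjects\n", length(x)))
  print(weight_diagnostics(x))
  invisible(x)
}

#' @export
summary.stabilized_weights <- function(object, ...) weight_diagnostics(object)

#' Stabilized-weight diagnostics
#'
#' Summary statistics for a weight vector: min, max, mean (which should sit
#' within Monte-Carlo error of 1 for correctly stabilized weights), standard
#' deviation, tail quantiles, and the number of clipped probability factors.
#'
#' @param sw A [compute_stabilized_weights()] result (any numeric vector
#'   works).
#' @param path Optional path; if given, the diagnostics are also written as
#'   JSON.
#' @return A named list of diagnostics, invisibly written to `path` if given.
#' @export
weight_diagnostics <- function(sw, path = NULL) {
  q <- stats::quantile(as.numeric(sw), c(0.01, 0.05, 0.95, 0.99),
                       names = FALSE)
  out <- list(n = length(sw), min = min(sw), max = max(sw),
              mean = mean(sw), sd = stats::sd(sw),
              q01 = q[1], q05 = q[2], q95 = q[3], q99 = q[4],
              n_clipped = attr(sw, "n_clipped") %||% NA_integer_)
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Append stabilized weights to a cohort
#'
#' @param cohort A cohort data frame.
#' @param sw Weights aligned to the cohort rows.
#' @return The cohort with an `sw` column.
#' @export
append_weights <- function(cohort, sw) {
  stopifnot(length(sw) == nrow(cohort))
  cohort$sw <- as.numeric(sw)
  cohort
}
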