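#' Weighted maximum-likelihood logistic regression
#'
#' Maximizes the weight-multiplied Bernoulli log-likelihood
#' \deqn{\ell(\beta) = \sum_i sw_i \left[ y_i \log \pi_i + (1 - y_i)
#'   \log(1 - \pi_i) \right], \quad \pi_i = \mathrm{expit}(x_i^\top \beta),}
#' by iteratively reweighted least squares (Newton-Raphson on the weighted
#' score) with step-halving. This is the estimator behind the marginal
#' structural model: with stabilized weights it solves the weighted score
#' equations of the pseudo-population in which treatment is unconfounded by
#' covariate history. With unit weights it reduces to the ordinary logistic
#' MLE.
#'
#' Convergence is declared when the log-likelihood change is below `1e-8` or
#' the score sup-norm is below `1e-6`.
#'
#' @param X Numeric design matrix (include the intercept column yourself);
#'   must have full column rank.
#' @param y Binary response vector.
#' @param weights Strictly positive weights, one per row.
#' @param offset Optional fixed addition to the linear predictor (used e.g.
#'   for recalibration models that pin the slope at 1).
#' @param max_iter Iteration cap.
#' @return A list with `coefficients` (named by `colnames(X)`), `loglik`,
#'   `iterations`, and `converged`.
#' @examples
#' X <- cbind(1, c(0, 0, 1, 1))
#' weighted_logistic_mle(X, c(0, 1, 0, 1), rep(1, 4))$coefficients  # ~ (0, 0)
#' @export
weighted_logistic_mle <- function(X, y, weights, offset = NULL,
                                  max_iter = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("b", seq_len(ncol(X) - 1L)))[
      seq_len(ncol(X))]
  y <- as.numeric(y)
  w <- as.numeric(weights)
  stopifnot(nrow(X) == length(y), length(w) == length(y))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("'weights' must be strictly positive and finite")
  if (!all(y %in% c(0, 1))) stop("'y' must be binary")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  off <- if (is.null(offset)) 0 else as.numeric(offset)
  beta <- numeric(ncol(X))
  ll <- function(b) {
    # sum w * (y*eta - log(1 + e^eta)), with the log-sum-exp written stably
    eta <- drop(X %*% b) + off
    sum(w * (y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))))
  }
  ll_old <- ll(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p <- stats::plogis(drop(X %*% beta) + off)
    score <- drop(crossprod(X, w * (y - p)))
    if (max(abs(score)) < 1e-6) { converged <- TRUE; break }
    irls_w <- pmax(w * p * (1 - p), 1e-12)
    delta <- tryCatch(
      solve(crossprod(X, X * irls_w), score),
      error = function(e) stop("singular information matrix at iteration ",
                               iter, ": ", conditionMessage(e)))
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- ll(cand)
      if (ll_new >= ll_old - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- cand
    if (abs(ll_new - ll_old) < 1e-8) {
      ll_old <- ll_new
      converged <- TRUE
      break
    }
    ll_old <- ll_new
  }
  p <- stats::plogis(drop(X %*% beta) + off)
  info <- crossprod(X, X * pmax(w * p * (1 - p), 1e-12))
  list(coefficients = structure(as.numeric(beta), names = colnames(X)),
       vcov = structure(solve(info),
                        dimnames = list(colnames(X), colnames(X))),
       loglik = ll_old, iterations = iter, converged = converged)
}

#' Fit a clinical prediction model under one of four treatment strategies
#'
#' The four competing ways of handling treatment when modelling the log-odds
#' of the outcome from the baseline risk factor \eqn{x_0}:
#' \describe{
#'   \item{`"ignore"`}{\eqn{\beta_0' + \beta_{X0}' x_0} fitted on all
#'     subjects, disregarding treatment entirely.}
#'   \item{`"naive"`}{the same design fitted only on subjects untreated at
#'     baseline (the treatment-naive cohort).}
#'   \item{`"baseline"`}{adds the baseline treatment term
#'     \eqn{\beta_{A0}' a_0}, fitted on all subjects.}
#'   \item{`"msm"`}{the marginal structural model
#'     \eqn{\beta_0' + \beta_{X0}' x_0 + \beta_{A0}' a_0 + \beta_{A1}' a_1},
#'     fitted by [weighted_logistic_mle()] with the stabilized weights.}
#' }
#' Only the MSM admits prediction under arbitrary joint regimens of current
#' and future treatment; its weighted fit is what removes the covariate-driven
#' treatment drop-in from the coefficients.
#'
#' @param cohort A cohort with columns `x0, a0, x1, a1, y`.
#' @param strategy One of `"ignore"`, `"naive"`, `"baseline"`, `"msm"`.
#' @param weights Stabilized weights, required iff `strategy = "msm"` (see
#'   [compute_stabilized_weights()]).
#' @param interactions If `TRUE`, treatment-by-\eqn{x_0} interaction terms are
#'   added for each treatment term in the design (off by default).
#' @return An object of class `"cpm"` with components `strategy`,
#'   `coefficients`, `converged`, `n_used`, `weighted`, `loglik`.
#' @seealso [predict.cpm()], [evaluate_cpm()]
#' @export
cpm <- function(cohort, strategy = c("ignore", "naive", "baseline", "msm"),
                weights = NULL, interactions = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(cohort),
            all(c("x0", "y") %in% names(cohort)))
  if (strategy == "msm" && is.null(weights))
    stop("the MSM strategy requires stabilized weights")
  if (strategy != "msm" && !is.null(weights))
    stop("weights are only used by the MSM strategy")
  data <- cohort
  if (strategy == "naive") {
    data <- subset_nbt(cohort)
    if (nrow(data) == 0L)
      stop("no untreated-at-baseline subjects: cannot fit the naive strategy")
  }
  n <- nrow(data)
  X <- cbind(`(Intercept)` = rep(1, n), x0 = data$x0)
  # constant treatment columns are dropped: strategies coincide on such data
  if (strategy %in% c("baseline", "msm") && !constant_col(data$a0))
    X <- cbind(X, a0 = data$a0)
  if (strategy == "msm" && !constant_col(data$a1))
    X <- cbind(X, a1 = data$a1)
  if (interactions) {
    for (trt in intersect(colnames(X), c("a0", "a1"))) {
      Xint <- X[, trt] * data$x0
      X <- cbind(X, Xint)
      colnames(X)[ncol(X)] <- paste0(trt, ":x0")
    }
  }
  w <- if (strategy == "msm") as.numeric(weights) else rep(1, n)
  if (length(w) != n) stop("weights must align with the (subset) cohort rows")
  fit <- weighted_logistic_mle(X, data$y, w)
  structure(
    list(strategy = strategy, coefficients = fit$coefficients,
         vcov = fit$vcov, converged = fit$converged, n_used = n,
         weighted = strategy == "msm", loglik = fit$loglik,
         interactions = interactions, call = match.call()),
    class = "cpm")
}

constant_col <- function(v) length(unique(v)) < 2L

#' Specify a treatment regime for prediction
#'
#' Each timepoint's treatment is either held at a value (0 or 1) or left at
#' the subject's observed value. The estimand-relevant regimes are: both
#' observed (performance in the development-like population), both 0
#' (treatment-naive risk: no intervention now or later), `a0 = 1` with `a1`
#' observed or set (intervene now / sustained intervention).
#'
#' @param a0,a1 Either `"observed"` or 0/1.
#' @return An object of class `"cpm_regime"`.
#' @export
regime <- function(a0 = "observed", a1 = "observed") {
  chk <- function(v, nm) {
    if (identical(v, "observed")) return(v)
    if (is.numeric(v) && length(v) == 1L && v %in% c(0, 1)) return(as.integer(v))
    stop(sprintf("'%s' must be \"observed\", 0 or 1", nm))
  }
  structure(list(a0 = chk(a0, "a0"), a1 = chk(a1, "a1")),
            class = "cpm_regime")
}

resolve_regime <- function(r) {
  if (inherits(r, "cpm_regime")) return(r)
  if (is.character(r) && length(r) == 1L)
    return(switch(r,
                  observed = regime("observed", "observed"),
                  none = regime(0, 0),
                  all = regime(1, 1),
                  stop("unknown regime shortcut: ", r)))
  stop("'regime' must be a cpm_regime object or one of ",
       "\"observed\", \"none\", \"all\"")
}

#' Predict risk from a fitted prediction model under a treatment regime
#'
#' Evaluates the model's linear predictor with treatment indicators fixed
#' according to the regime and returns `expit` of it (or the linear predictor
#' itself with `type = "link"`). Strategies without a treatment term (ignore,
#' naive) use their linear predictor unchanged under any regime that does not
#' demand treatment: setting an absent term to 0 or leaving it observed is
#' vacuous, but setting it to 1 is an error because the model cannot express
#' it.
#'
#' @param object A fitted [cpm()].
#' @param newdata Data frame with `x0` and, where the regime leaves a term
#'   observed and the model carries it, `a0`/`a1`.
#' @param regime A [regime()] or one of the shortcuts `"observed"` (as-is
#'   evaluation), `"none"` (no treatment now or later) or `"all"` (sustained
#'   treatment).
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @param ... Unused.
#' @return Numeric vector, one value per row of `newdata`.
#' @export
predict.cpm <- function(object, newdata, regime = "observed",
                        type = c("response", "link"), ...) {
  type <- match.arg(type)
  r <- resolve_regime(regime)
  if (!isTRUE(object$converged))
    stop("model did not converge; refusing to predict")
  cf <- object$coefficients
  lp <- cf[["(Intercept)"]] + cf[["x0"]] * newdata$x0
  for (trt in c("a0", "a1")) {
    set <- r[[trt]]
    has_term <- trt %in% names(cf)
    if (!has_term) {
      if (is.numeric(set) && set == 1L)
        stop(sprintf(
          "regime sets %s = 1 but the '%s' model carries no %s term",
          trt, object$strategy, trt))
      next
    }
    val <- if (identical(set, "observed")) {
      if (!trt %in% names(newdata))
        stop(sprintf("regime leaves %s observed but 'newdata' lacks it", trt))
      newdata[[trt]]
    } else set
    lp <- lp + cf[[trt]] * val
    if (isTRUE(object$interactions) && paste0(trt, ":x0") %in% names(cf))
      lp <- lp + cf[[paste0(trt, ":x0")]] * val * newdata$x0
  }
  lp <- unname(lp)
  if (type == "link") lp else stats::plogis(lp)
}

#' @export
print.cpm <- function(x, ...) {
  cat(sprintf("Prediction model, strategy '%s'%s (n = %d%s)\n",
              x$strategy, if (x$weighted) " [weighted MLE]" else "",
              x$n_used, if (x$converged) "" else ", NOT converged"))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.cpm <- function(object, ...) object$coefficients

#' @export
vcov.cpm <- function(object, ...) object$vcov

#' @export
summary.cpm <- function(object, ...) {
  structure(list(strategy = object$strategy,
                 coefficients = object$coefficients,
                 n_used = object$n_used, weighted = object$weighted,
                 converged = object$converged, loglik = object$loglik),
            class = "summary.cpm")
}

#' @export
print.summary.cpm <- function(x, ...) {
  cat(sprintf("Strategy: %s%s\n", x$strategy,
              if (x$weighted) " (stabilized-weighted likelihood)" else ""))
  cat(sprintf("Observations used: %d\n", x$n_used))
  cat(sprintf("Log-likelihood: %.4f (converged: %s)\n", x$loglik,
              x$converged))
  cat("Coefficients:\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Serialize a fitted prediction model to JSON
#'
#' @param model A fitted [cpm()].
#' @param path File path.
#' @return `read_cpm()` returns the model; `write_cpm()` returns `path`
#'   invisibly.
#' @export
write_cpm <- function(model, path) {
  stopifnot(inherits(model, "cpm"))
  jsonlite::write_json(
    list(strategy = model$strategy,
         coefficients = as.list(model$coefficients),
         converged = model$converged, n_used = model$n_used,
         weighted = model$weighted, loglik = model$loglik,
         interactions = model$interactions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cpm
#' @export
read_cpm <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(strategy = raw$strategy,
         coefficients = unlist(raw$coefficients),
         converged = raw$converged, n_used = raw$n_used,
         weighted = raw$weighted, loglik = raw$loglik,
         interactions = isTRUE(raw$interactions), call = NULL),
    class = "cpm")
}
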