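#' Calibration-in-the-large
#'
#' Intercept of a logistic recalibration of the outcome on the model's linear
#' predictor held as a fixed offset (slope pinned at 1). Zero means the
#' observed event rate agrees with the predicted one on the log-odds scale;
#' positive values mean the model under-predicts.
#'
#' @param y Binary outcome vector.
#' @param linear_predictor Model linear predictor (log-odds scale).
#' @return Calibration-in-the-large (log-odds).
#' @export
calibration_in_the_large <- function(y, linear_predictor) {
  check_binary_both(y)
  fit <- weighted_logistic_mle(matrix(1, length(y)), y, rep(1, length(y)),
                               offset = linear_predictor)
  unname(fit$coefficients)
}

#' Calibration slope
#'
#' Slope of a univariate logistic regression of the outcome on the model's
#' linear predictor; 1 for a perfectly calibrated model, above 1 when the
#' linear predictor is under-dispersed (coefficients too small), below 1 when
#' over-fitted.
#'
#' @inheritParams calibration_in_the_large
#' @return The slope coefficient.
#' @export
calibration_slope <- function(y, linear_predictor) {
  check_binary_both(y)
  if (stats::var(linear_predictor) == 0)
    stop("constant linear predictor: calibration slope is undefined")
  X <- cbind(1, linear_predictor)
  fit <- weighted_logistic_mle(X, y, rep(1, length(y)))
  unname(fit$coefficients[2])
}

#' Area under the ROC curve
#'
#' The exact Mann-Whitney statistic: the probability that a randomly drawn
#' event has a higher predicted risk than a randomly drawn non-event, counting
#' ties as one half. Computed from midranks, so it is deterministic, tie-safe,
#' and invariant to any strictly monotone transform of the risks.
#'
#' @param y Binary outcome vector (both classes must be present).
#' @param risk Predicted risks (any monotone score works).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(y, risk) {
  check_binary_both(y)
  stopifnot(length(y) == length(risk))
  n1 <- sum(y == 1)
  n0 <- length(y) - n1
  r <- rank(risk, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted risk and outcome; 0 for perfect
#' predictions, 0.25 for a constant 0.5.
#'
#' @inheritParams auc
#' @return The Brier score.
#' @export
brier <- function(y, risk) {
  stopifnot(length(y) == length(risk))
  mean((risk - y)^2)
}

#' Treatment-allocation curve
#'
#' For each treatment threshold, the proportion of subjects whose predicted
#' treatment-naive risk exceeds it — the fraction who would have treatment
#' initiated if the model were used with that decision threshold.
#'
#' @param e3_risk Predicted risks under no treatment now or later.
#' @param thresholds Strictly increasing thresholds inside (0, 1); the default
#'   spans 5% to 70% in 5-point steps.
#' @return Named vector of proportions, non-increasing in the threshold.
#' @export
treatment_allocation <- function(e3_risk,
                                 thresholds = seq(0.05, 0.70, by = 0.05)) {
  if (length(e3_risk) == 0L) stop("empty risk vector")
  stopifnot(all(thresholds > 0 & thresholds < 1),
            !is.unsorted(thresholds, strictly = TRUE))
  structure(vapply(thresholds, function(t) mean(e3_risk > t), numeric(1)),
            names = format(thresholds, trim = TRUE))
}

check_binary_both <- function(y) {
  if (!all(y %in% c(0, 1))) stop("'y' must be binary")
  if (length(unique(y)) < 2L)
    stop("need at least one event and one non-event")
  invisible(NULL)
}

#' Evaluate a fitted prediction model in one performance setting
#'
#' The three performance settings probe different estimands:
#' \describe{
#'   \item{`"MT"` (mix of treatment)}{observed-regime predictions on the
#'     development-like test cohort — internal-validation performance.}
#'   \item{`"NBT"` (no baseline treatment)}{observed-regime predictions on the
#'     untreated-at-baseline subset of the same cohort — risk given no
#'     intervention now.}
#'   \item{`"NTT"` (no treatment throughout)}{no-treatment-regime predictions
#'     on the cohort in which treatment was withheld from everyone — the
#'     treatment-naive risk that drives treatment-initiation decisions. The
#'     treatment-allocation curve is computed only here.}
#' }
#'
#' @param model A fitted [cpm()].
#' @param setting `"MT"`, `"NBT"` or `"NTT"`.
#' @param test_mt Mix-of-treatment test cohort ([generate_test_mt()]);
#'   required for MT and NBT.
#' @param test_ntt No-treatment test cohort ([generate_test_ntt()]); required
#'   for NTT.
#' @param thresholds Treatment thresholds for the allocation curve.
#' @return An object of class `"performance_report"`: a list with `setting`,
#'   `strategy`, `citl`, `cal_slope`, `auc`, `brier`, `n_eval`, and (NTT only)
#'   `allocation`.
#' @export
evaluate_cpm <- function(model, setting = c("MT", "NBT", "NTT"),
                         test_mt = NULL, test_ntt = NULL,
                         thresholds = seq(0.05, 0.70, by = 0.05)) {
  setting <- match.arg(setting)
  stopifnot(inherits(model, "cpm"))
  if (setting %in% c("MT", "NBT") && is.null(test_mt))
    stop("setting ", setting, " needs the mix-of-treatment test cohort")
  if (setting == "NTT" && is.null(test_ntt))
    stop("setting NTT needs the no-treatment test cohort")
  data <- switch(setting,
                 MT = test_mt,
                 NBT = subset_nbt(test_mt),
                 NTT = test_ntt)
  reg <- if (setting == "NTT") "none" else "observed"
  lp <- predict(model, data, regime = reg, type = "link")
  risk <- stats::plogis(lp)
  out <- list(setting = setting, strategy = model$strategy,
              citl = calibration_in_the_large(data$y, lp),
              cal_slope = calibration_slope(data$y, lp),
              auc = auc(data$y, risk),
              brier = brier(data$y, risk),
              n_eval = nrow(data))
  if (setting == "NTT")
    out$allocation <- treatment_allocation(risk, thresholds)
  structure(out, class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance of '%s' in setting %s (n = %d)\n",
              x$strategy, x$setting, x$n_eval))
  cat(sprintf("  CITL %.4f | slope %.4f | AUC %.4f | Brier %.4f\n",
              x$citl, x$cal_slope, x$auc, x$brier))
  if (!is.null(x$allocation)) {
    cat("  allocation (risk > threshold):\n")
    print(round(x$allocation, 4))
  }
  invisible(x)
}

#' Flatten a performance report to a long-format data frame
#'
#' @param report A [evaluate_cpm()] result.
#' @return Data frame with columns `strategy`, `setting`, `metric`, `value`;
#'   allocation entries appear as metrics named `alloc_<threshold>`.
#' @export
report_to_long <- function(report) {
  stopifnot(inherits(report, "performance_report"))
  metrics <- c(citl = report$citl, cal_slope = report$cal_slope,
               auc = report$auc, brier = report$brier)
  if (!is.null(report$allocation)) {
    al <- report$allocation
    names(al) <- paste0("alloc_", names(al))
    metrics <- c(metrics, al)
  }
  data.frame(strategy = report$strategy, setting = report$setting,
             metric = names(metrics), value = unname(metrics),
             stringsAsFactors = FALSE)
}
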