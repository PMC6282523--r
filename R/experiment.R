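#' Define a simulation experiment plan
#'
#' A plan is a grid of scenarios and covariate-lowering effects
#' (\eqn{\gamma}), each cell repeated over independent replicates. The default
#' \eqn{\gamma} grid spans `(-3, -2.5, -2, -1.5, -1, -0.5, 0)`; positive
#' values (treatment raising the risk factor) are not part of the study
#' conditions, though [scenario_config()] accepts any real `gamma`.
#'
#' @param scenarios Character vector of preset names (see [scenario_preset()])
#'   or a list of uncalibrated [scenario_config()] objects.
#' @param gamma_grid Values of gamma to sweep.
#' @param n_dev Development cohort size per replicate.
#' @param n_test Test cohort size (both test cohorts).
#' @param n_reps Replicates per cell.
#' @param root_seed Root seed; every cohort of every replicate draws from a
#'   stream derived from it with [child_seed()], so any cell can be re-run in
#'   isolation.
#' @param thresholds Treatment-allocation thresholds.
#' @return An object of class `"experiment_plan"`.
#' @export
experiment_plan <- function(scenarios = c("rct_10pct_dropout",
                                          "obs_50pct_treated",
                                          "obs_20pct_treated"),
                            gamma_grid = c(-3, -2.5, -2, -1.5, -1, -0.5, 0),
                            n_dev = 10000L, n_test = 100000L,
                            n_reps = 1000L, root_seed = 1L,
                            thresholds = seq(0.05, 0.70, by = 0.05)) {
  stopifnot(n_reps >= 1L, length(gamma_grid) >= 1L)
  if (is.character(scenarios)) scenarios <- as.list(scenarios)
  structure(list(scenarios = scenarios, gamma_grid = gamma_grid,
                 n_dev = as.integer(n_dev), n_test = as.integer(n_test),
                 n_reps = as.integer(n_reps),
                 root_seed = as.integer(root_seed), thresholds = thresholds),
            class = "experiment_plan")
}

#' Run one simulation replicate
#'
#' One full pass of the study pipeline: generate a development cohort, fit the
#' treatment models and stabilized weights, fit the four modelling strategies,
#' generate the two test cohorts, and evaluate every strategy in every
#' performance setting. Cohort seeds are derived from `seed` with
#' [child_seed()] (streams 1-3), so a replicate is reproducible in isolation.
#'
#' @param config A calibrated [scenario_config()] (its `gamma` is the cell's
#'   gamma).
#' @param seed Replicate seed.
#' @param n_dev,n_test Cohort sizes; default to the scenario's.
#' @param thresholds Allocation thresholds.
#' @return Long-format data frame of metrics (strategy x setting x metric)
#'   with the fitted models attached as attribute `"models"`.
#' @export
run_replicate <- function(config, seed, n_dev = config$n_dev,
                          n_test = config$n_test,
                          thresholds = seq(0.05, 0.70, by = 0.05)) {
  stopifnot(inherits(config, "scenario_config"))
  dev <- generate_development(config, n_dev, child_seed(seed, 1L))
  tmods <- fit_treatment_models(dev)
  sw <- compute_stabilized_weights(dev, tmods)
  fits <- list(
    ignore = cpm(dev, "ignore"),
    naive = cpm(dev, "naive"),
    baseline = cpm(dev, "baseline"),
    msm = cpm(dev, "msm", weights = sw))
  test_mt <- generate_test_mt(config, n_test, child_seed(seed, 2L))
  test_ntt <- generate_test_ntt(config, n_test, child_seed(seed, 3L))
  rows <- list()
  for (nm in names(fits))
    for (setting in c("MT", "NBT", "NTT"))
      rows[[paste(nm, setting)]] <- report_to_long(
        evaluate_cpm(fits[[nm]], setting, test_mt = test_mt,
                     test_ntt = test_ntt, thresholds = thresholds))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "models") <- fits
  attr(out, "weights_mean") <- mean(sw)
  out
}

#' Run a full simulation experiment
#'
#' For every scenario and every gamma, calibrates the scenario intercepts
#' once, runs `n_reps` independent replicates, and aggregates each metric to
#' its mean and empirical standard error (SD across replicates divided by
#' \eqn{\sqrt{n_{reps}}}). Replicate seeds follow a counter-based derivation
#' from `root_seed`, so cells can be run in any order (or subset) with
#' identical results.
#'
#' @param plan An [experiment_plan()].
#' @param keep_replicates Keep the per-replicate long table (needed e.g. to
#'   compare allocation curves replicate by replicate).
#' @param verbose Print per-cell progress.
#' @return An object of class `"msm_experiment"`: list with `results` (the
#'   aggregated long table: scenario, gamma, strategy, setting, metric, mean,
#'   se, n_reps, n_failed) and optionally `replicates`.
#' @export
run_experiment <- function(plan, keep_replicates = FALSE, verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  agg <- list()
  reps_out <- list()
  cell <- 0L
  for (sc in plan$scenarios) {
    for (g in plan$gamma_grid) {
      cell <- cell + 1L
      config <- if (is.character(sc)) scenario_preset(sc, gamma = g) else {
        sc$gamma <- g; sc
      }
      config$n_dev <- plan$n_dev
      config$n_test <- plan$n_test
      config <- calibrate_scenario(config)
      if (verbose)
        message(sprintf("cell %d: %s, gamma = %.2f", cell, config$name, g))
      rep_tabs <- vector("list", plan$n_reps)
      failed <- 0L
      for (r in seq_len(plan$n_reps)) {
        rep_seed <- child_seed(plan$root_seed, cell * 100000L + r)
        tab <- tryCatch(
          run_replicate(config, rep_seed, thresholds = plan$thresholds),
          error = function(e) {
            warning(sprintf("replicate %d of cell %d failed: %s", r, cell,
                            conditionMessage(e)), call. = FALSE)
            NULL
          })
        if (is.null(tab)) { failed <- failed + 1L; next }
        tab$replicate <- r
        attr(tab, "models") <- NULL
        rep_tabs[[r]] <- tab
      }
      reps <- do.call(rbind, c(rep_tabs, list(make.row.names = FALSE)))
      if (is.null(reps)) next
      reps$scenario <- config$name
      reps$gamma <- g
      a <- aggregate_replicates(reps)
      a$n_failed <- failed
      if (failed > 0.05 * plan$n_reps) a$unreliable <- TRUE
      agg[[cell]] <- a
      if (keep_replicates) reps_out[[cell]] <- reps
    }
  }
  out <- list(plan = plan,
              results = do.call(rbind, c(agg, list(make.row.names = FALSE))))
  if (keep_replicates)
    out$replicates <- do.call(rbind, c(reps_out,
                                       list(make.row.names = FALSE)))
  structure(out, class = "msm_experiment")
}

# Mean and empirical SE per (scenario, gamma, strategy, setting, metric).
aggregate_replicates <- function(reps) {
  key <- interaction(reps$scenario, reps$gamma, reps$strategy, reps$setting,
                     reps$metric, drop = TRUE)
  split_idx <- split(seq_len(nrow(reps)), key)
  rows <- lapply(split_idx, function(ix) {
    v <- reps$value[ix]
    first <- ix[1]
    data.frame(scenario = reps$scenario[first], gamma = reps$gamma[first],
               strategy = reps$strategy[first], setting = reps$setting[first],
               metric = reps$metric[first], mean = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               n_reps = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$scenario, out$gamma, out$strategy, out$setting, out$metric), ,
      drop = FALSE]
}

#' @export
print.msm_experiment <- function(x, ...) {
  res <- x$results
  cat(sprintf(
    "Simulation experiment: %d scenario(s) x %d gamma value(s), %d replicates\n",
    length(unique(res$scenario)), length(unique(res$gamma)),
    x$plan$n_reps))
  core <- res[res$metric %in% c("citl", "auc"), , drop = FALSE]
  cat("Calibration-in-the-large and AUC (mean over replicates):\n")
  print(utils::head(core[, c("scenario", "gamma", "strategy", "setting",
                             "metric", "mean", "se")], 24), row.names = FALSE)
  if (nrow(core) > 24) cat(sprintf("... (%d rows total)\n", nrow(res)))
  invisible(x)
}

#' Write aggregated experiment results as delimited text
#'
#' @param experiment A [run_experiment()] result.
#' @param path File path for the long-format results table.
#' @return `path`, invisibly.
#' @export
write_results <- function(experiment, path) {
  stopifnot(inherits(experiment, "msm_experiment"))
  utils::write.csv(experiment$results, path, row.names = FALSE)
  invisible(path)
}
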