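test_that("person-period tables satisfy the risk-set accounting invariants", {
  lc <- longitudinal_config()
  pp <- generate_longitudinal(lc, 3000, K = 10, seed = 401)
  expect_identical(pp, generate_longitudinal(lc, 3000, K = 10, seed = 401))
  by_id <- split(pp, pp$id)
  for (sub in by_id[1:200]) {
    expect_equal(sub$k, seq_len(nrow(sub)) - 1L)   # contiguous from 0
    expect_true(all(diff(sub$a) >= 0))             # absorbing treatment
    expect_lte(sum(sub$y), 1L)
    if (sum(sub$y) == 1L) expect_equal(which(sub$y == 1L), nrow(sub))
    if (sum(sub$c) == 1L) expect_equal(which(sub$c == 1L), nrow(sub))
    expect_lte(sum(sub$y) + sum(sub$c), 1L)
  }
  # total person-periods match per-subject termination bookkeeping
  last <- vapply(by_id, nrow, integer(1))
  expect_equal(nrow(pp), sum(last))
  expect_true(all(last <= 10))
})

test_that("switching off hazards removes the corresponding processes", {
  lc_noc <- longitudinal_config(alpha_cens = -30)
  pp <- generate_longitudinal(lc_noc, 2000, K = 6, seed = 411)
  expect_equal(sum(pp$c), 0L)
  lc_not <- longitudinal_config(alpha_treat = -30)
  expect_warning(pp2 <- generate_longitudinal(lc_not, 2000, K = 6,
                                              seed = 412),
                 "degenerate")
  expect_equal(sum(pp2$a), 0L)
})

test_that("with no drop-in and no censoring the MSM equals the naive fit", {
  lc <- longitudinal_config(alpha_treat = -30, alpha_cens = -30)
  pp <- suppressWarnings(generate_longitudinal(lc, 5000, K = 8, seed = 421))
  w <- fit_longitudinal_weights(pp)
  expect_equal(w$sw, rep(1, nrow(pp)))
  msm <- fit_pooled_msm(pp, weights = w)          # treatment column constant
  naive <- fit_pooled_msm(pp, treatment = "none")
  expect_equal(coef(msm), coef(naive), tolerance = 1e-8)
})

test_that("cumulative incidence matches the product-of-hazards closed form", {
  lc <- longitudinal_config(alpha_treat = -30, alpha_cens = -30)
  pp <- suppressWarnings(generate_longitudinal(lc, 1e5, K = 10, seed = 431))
  realized <- mean(tapply(pp$y, pp$id, max))
  set.seed(4310)
  x0 <- rnorm(5e5); z <- rbinom(5e5, 1, lc$p_z)
  h <- vapply(0:9, function(k)
    plogis(lc$alpha_event + lc$event_trend * k + lc$event_x0 * x0 +
             lc$event_z * z), numeric(5e5))
  oracle <- mean(1 - apply(1 - h, 1, prod))
  expect_lt(abs(realized - oracle), 0.005)
})

test_that("restricted cubic spline basis has the right dimension and tails", {
  b3 <- rcs_basis(0:9, n_knots = 3)
  expect_equal(ncol(b3$basis), 2L)
  b4 <- rcs_basis(0:9, n_knots = 4)
  expect_equal(ncol(b4$basis), 3L)
  # linear beyond the last knot: second differences vanish there
  xs <- seq(max(b4$knots) + 0.5, max(b4$knots) + 6, by = 0.5)
  tail_vals <- msmcpm:::rcs_eval(xs, b4$knots)
  for (j in seq_len(ncol(tail_vals)))
    expect_equal(max(abs(diff(diff(tail_vals[, j])))), 0, tolerance = 1e-9)
  # same below the first knot
  lo <- msmcpm:::rcs_eval(seq(-6, min(b4$knots) - 0.5, by = 0.5), b4$knots)
  for (j in seq_len(ncol(lo)))
    expect_equal(max(abs(diff(diff(lo[, j])))), 0, tolerance = 1e-9)
  expect_error(rcs_basis(c(0, 1), n_knots = 4), "fewer distinct periods")
})

test_that("a flat hazard is recovered as a flat fitted time profile", {
  lc <- longitudinal_config(alpha_treat = -30, alpha_cens = -30,
                            event_trend = 0, event_x0 = 0, event_z = 0,
                            alpha_event = qlogis(0.05))
  pp <- suppressWarnings(generate_longitudinal(lc, 3e4, K = 10, seed = 441))
  fit <- fit_pooled_msm(pp, treatment = "none")
  h <- msmcpm:::hazard_matrix(fit, data.frame(x0 = 0, z = 0), K = 10)
  expect_lt(max(h) - min(h), 0.01)
  expect_lt(abs(mean(h) - 0.05), 0.005)
})

test_that("longitudinal weights stabilize and honor the absorbing state", {
  lc <- longitudinal_config()
  pp <- generate_longitudinal(lc, 2e4, K = 10, seed = 451)
  w <- fit_longitudinal_weights(pp)
  expect_true(all(w$sw > 0))
  expect_lt(abs(mean(w$sw) - 1), 0.05)
  # per-period means stay near one as well
  per_k <- tapply(w$sw, pp$k, mean)
  expect_lt(max(abs(per_k - 1)), 0.1)
  # once treated, the treatment factor contributes nothing further
  treated_rows <- which(pp$a == 1 &
                          c(FALSE, pp$a[-nrow(pp)] == 1 &
                              pp$id[-1] == pp$id[-nrow(pp)]))
  expect_equal(w$factor_treat[treated_rows],
               rep(1, length(treated_rows)))
})

test_that("the two-period mapping reproduces the two-timepoint engine exactly", {
  cfg <- cached_config("obs_50pct_treated", gamma = -1)
  dev <- generate_development(cfg, 4000, seed = 461)
  sw_wide <- compute_stabilized_weights(dev, fit_treatment_models(dev))
  pp <- as_person_period(dev)
  lw <- fit_longitudinal_weights(pp, pool_periods = FALSE, absorbing = FALSE)
  expect_equal(lw$sw[pp$k == 1], as.numeric(sw_wide), tolerance = 1e-8)
  # the outcome stage agrees too once the mapped rows carry their history
  sub <- pp[pp$k == 1, ]
  sub$a_lag <- dev$a0
  pooled <- fit_pooled_msm(sub, weights = lw$sw[pp$k == 1], time = "none",
                           treatment = "both")
  wide <- cpm(dev, "msm", weights = sw_wide)
  expect_equal(unname(coef(pooled)[c("(Intercept)", "x0", "a_lag", "a")]),
               unname(coef(wide)), tolerance = 1e-8)
})

test_that("the pooled MSM recovers the generating hazard coefficients", {
  lc <- longitudinal_config()
  pp <- generate_longitudinal(lc, 6e4, K = 10, seed = 471)
  w <- fit_longitudinal_weights(pp)
  fit <- fit_pooled_msm(pp, weights = w)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)["x0"] - lc$event_x0), 3 * se["x0"])
  expect_lt(abs(coef(fit)["z"] - lc$event_z), 3 * se["z"])
  expect_lt(abs(coef(fit)["a"] - lc$event_a), 3 * se["a"])
  expect_lt(coef(fit)["a"], 0)  # protective treatment
})

test_that("cumulative risk follows its closed forms and is monotone", {
  lc <- longitudinal_config()
  pp <- generate_longitudinal(lc, 5000, K = 10, seed = 481)
  fit <- fit_pooled_msm(pp, weights = fit_longitudinal_weights(pp))
  nd <- data.frame(x0 = c(-1, 0, 1, 2), z = c(0, 1, 0, 1))
  risks <- vapply(1:10, function(K) predict_cumulative_risk(fit, nd, K),
                  numeric(4))
  expect_true(all(diff(t(risks)) >= 0))          # non-decreasing in horizon
  expect_true(all(risks > 0 & risks < 1))
  expect_error(predict_cumulative_risk(fit, nd, K = 11), "extrapolate")
  # hand evaluation: risk = 1 - prod(1 - h_k)
  h <- msmcpm:::hazard_matrix(fit, nd, K = 10)
  expect_equal(predict_cumulative_risk(fit, nd, 10),
               1 - apply(1 - h, 1, prod))
  # degenerate hazard checks on a hand-built constant-hazard model
  flat <- fit
  flat$coefficients[] <- 0
  flat$coefficients["(Intercept)"] <- qlogis(0.1)
  flat$time <- "none"
  expect_equal(predict_cumulative_risk(flat, nd, 5),
               rep(1 - (1 - 0.1)^5, 4), tolerance = 1e-12)
})

test_that("drop-in biases the naive longitudinal model but not the MSM", {
  # strong drop-in to make the contrast visible at desk scale
  lc <- longitudinal_config(alpha_treat = -2.2, event_a = log(0.4))
  pp <- generate_longitudinal(lc, 3e4, K = 10, seed = 491)
  msm <- fit_pooled_msm(pp, weights = fit_longitudinal_weights(pp))
  naive <- fit_pooled_msm(pp, treatment = "none")
  # evaluate on an independent fully observed cohort with treatment withheld
  lc0 <- longitudinal_config(alpha_treat = -30, alpha_cens = -30,
                             event_a = log(0.4))
  test <- suppressWarnings(generate_longitudinal(lc0, 3e4, K = 10,
                                                 seed = 492))
  y10 <- tapply(test$y, test$id, max)
  nd <- test[test$k == 0, c("x0", "z")]
  lp_msm <- qlogis(predict_cumulative_risk(msm, nd, 10))
  lp_naive <- qlogis(predict_cumulative_risk(naive, nd, 10))
  citl_msm <- calibration_in_the_large(y10, lp_msm)
  citl_naive <- calibration_in_the_large(y10, lp_naive)
  expect_gt(citl_naive, 0.05)            # naive under-predicts
  expect_lt(abs(citl_msm), 0.05)         # MSM close to calibrated
  expect_gt(citl_naive, citl_msm)
  # and the naive model allocates fewer patients at a fixed threshold
  thr <- stats::quantile(plogis(lp_msm), 0.8)
  expect_lt(mean(plogis(lp_naive) > thr), mean(plogis(lp_msm) > thr))
})

test_that("person-period tables round-trip through delimited text", {
  lc <- longitudinal_config()
  pp <- generate_longitudinal(lc, 300, K = 5, seed = 499)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_person_period(pp, path)
  back <- read_person_period(path)
  expect_equal(back$x, pp$x, tolerance = 1e-12)
  expect_identical(back$a, pp$a)
  expect_equal(attr(back, "K"), 5L)
})
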