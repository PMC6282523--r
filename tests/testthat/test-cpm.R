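test_that("unit-weight fits equal the ordinary logistic MLE", {
  set.seed(141)
  n <- 2000
  x <- rnorm(n); a <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x - 0.5 * a))
  X <- cbind(`(Intercept)` = 1, x = x, a = a)
  ours <- weighted_logistic_mle(X, y, rep(1, n))
  ref <- glm(y ~ x + a, family = binomial)
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_true(ours$converged)
  # model-based covariance agrees too
  expect_equal(unname(diag(ours$vcov)), unname(diag(vcov(ref))),
               tolerance = 1e-4)
})

test_that("the symmetric four-point configuration has a flat fit", {
  X <- cbind(`(Intercept)` = 1, x = c(0, 0, 1, 1))
  fit <- weighted_logistic_mle(X, c(0, 1, 0, 1), rep(1, 4))
  expect_equal(unname(fit$coefficients), c(0, 0), tolerance = 1e-6)
})

test_that("integer weights are equivalent to row expansion", {
  set.seed(151)
  n <- 300
  x <- rnorm(n); y <- rbinom(n, 1, plogis(x))
  w <- sample(1:4, n, replace = TRUE)
  X <- cbind(`(Intercept)` = 1, x = x)
  weighted <- weighted_logistic_mle(X, y, w)$coefficients
  idx <- rep(seq_len(n), w)
  expanded <- weighted_logistic_mle(X[idx, ], y[idx],
                                    rep(1, length(idx)))$coefficients
  expect_equal(unname(weighted), unname(expanded), tolerance = 1e-6)
})

test_that("rank deficiency and invalid weights are rejected informatively", {
  X <- cbind(`(Intercept)` = 1, x = 1:10, x2 = 2 * (1:10))
  y <- rep(0:1, 5)
  expect_error(weighted_logistic_mle(X, y, rep(1, 10)), "x2")
  expect_error(weighted_logistic_mle(X[, 1:2], y, c(rep(1, 9), 0)),
               "strictly positive")
  expect_error(weighted_logistic_mle(X[, 1:2], c(y[-1], 2), rep(1, 10)),
               "binary")
})

test_that("the four strategies use their prescribed designs", {
  cfg <- cached_config("obs_50pct_treated")
  dev <- generate_development(cfg, 8000, seed = 161)
  sw <- compute_stabilized_weights(dev, fit_treatment_models(dev))
  ignore <- cpm(dev, "ignore")
  naive <- cpm(dev, "naive")
  baseline <- cpm(dev, "baseline")
  msm <- cpm(dev, "msm", weights = sw)
  expect_named(coef(ignore), c("(Intercept)", "x0"))
  expect_named(coef(naive), c("(Intercept)", "x0"))
  expect_equal(naive$n_used, sum(dev$a0 == 0))
  expect_named(coef(baseline), c("(Intercept)", "x0", "a0"))
  expect_named(coef(msm), c("(Intercept)", "x0", "a0", "a1"))
  expect_true(msm$weighted && !baseline$weighted)
  expect_error(cpm(dev, "msm"), "weights")
  expect_error(cpm(dev, "ignore", weights = sw), "only used")
})

test_that("strategies coincide when nobody is treated", {
  cfg <- cached_config("obs_50pct_treated")
  ntt <- generate_test_ntt(cfg, 3000, seed = 171)
  fits <- list(cpm(ntt, "ignore"), cpm(ntt, "naive"), cpm(ntt, "baseline"),
               cpm(ntt, "msm", weights = rep(1, 3000)))
  base <- coef(fits[[1]])
  for (f in fits[-1])
    expect_equal(unname(coef(f)), unname(base), tolerance = 1e-6)
})

test_that("fitted treatment effects are protective at scale", {
  cfgr <- cached_config("rct_10pct_dropout")
  devr <- generate_development(cfgr, 5e4, seed = 181)
  expect_lt(coef(cpm(devr, "baseline"))["a0"], 0)
  cfg <- cached_config("obs_50pct_treated")
  dev <- generate_development(cfg, 1e5, seed = 182)
  sw <- compute_stabilized_weights(dev, fit_treatment_models(dev))
  msm <- cpm(dev, "msm", weights = sw)
  expect_lt(coef(msm)["a0"], 0)
  expect_lt(coef(msm)["a1"], 0)
})

test_that("fit equivalences across strategies hold", {
  cfg <- cached_config("obs_50pct_treated")
  dev <- generate_development(cfg, 5000, seed = 191)
  # baseline fit on an all-untreated-at-baseline cohort == naive on the full
  nbt <- subset_nbt(dev)
  expect_equal(unname(coef(cpm(nbt, "baseline"))),
               unname(coef(cpm(dev, "naive"))), tolerance = 1e-6)
  # unit weights with the follow-up treatment held constant == baseline fit
  flat <- dev; flat$a1 <- 0L
  expect_equal(unname(coef(cpm(flat, "msm", weights = rep(1, 5000)))),
               unname(coef(cpm(flat, "baseline"))), tolerance = 1e-6)
})

test_that("predictions evaluate closed forms under explicit regimes", {
  msm <- make_cpm("msm", c("(Intercept)" = 0, x0 = 1, a0 = log(0.5),
                           a1 = log(0.5)))
  nd <- data.frame(x0 = 0)
  expect_equal(predict(msm, nd, regime = "none"), 0.5)
  expect_equal(predict(msm, nd, regime = "all"), plogis(2 * log(0.5)))
  expect_equal(predict(msm, nd, regime = "all"), 0.2, tolerance = 1e-12)
  expect_equal(predict(msm, data.frame(x0 = 1), regime = "none",
                       type = "link"), 1)
  # mixed regime: treat now, never again
  expect_equal(predict(msm, nd, regime = regime(a0 = 1, a1 = 0)),
               plogis(log(0.5)))
})

test_that("no-treatment risk dominates sustained-treatment risk for protective models", {
  set.seed(201)
  for (i in 1:20) {
    m <- make_cpm("msm", c("(Intercept)" = rnorm(1), x0 = rnorm(1),
                           a0 = -abs(rnorm(1)), a1 = -abs(rnorm(1))))
    nd <- data.frame(x0 = rnorm(15))
    expect_true(all(predict(m, nd, regime = "none") >=
                      predict(m, nd, regime = "all")))
  }
})

test_that("regimes demanding absent treatment terms are rejected", {
  ign <- make_cpm("ignore", c("(Intercept)" = 0, x0 = 1))
  nd <- data.frame(x0 = c(-1, 0, 1))
  # setting an absent term to zero (or leaving it observed) is vacuous
  expect_equal(predict(ign, nd, regime = "none"), plogis(nd$x0))
  expect_error(predict(ign, nd, regime = "all"), "no a0 term")
  bas <- make_cpm("baseline", c("(Intercept)" = 0, x0 = 1, a0 = -0.5))
  expect_error(predict(bas, nd, regime = "all"), "no a1 term")
  expect_equal(predict(bas, nd, regime = regime(a0 = 1, a1 = 0),
                       type = "link"), nd$x0 - 0.5)
})

test_that("predictions are probabilities and order-invariant", {
  cfg <- cached_config("rct_10pct_dropout")
  dev <- generate_development(cfg, 3000, seed = 211)
  fit <- cpm(dev, "baseline")
  p <- predict(fit, dev, regime = "observed")
  expect_true(all(p > 0 & p < 1))
  perm <- sample(3000)
  expect_equal(predict(fit, dev[perm, ], regime = "observed"), p[perm])
})

test_that("model objects print, summarize and serialize", {
  cfg <- cached_config("rct_10pct_dropout")
  dev <- generate_development(cfg, 2000, seed = 221)
  fit <- cpm(dev, "baseline")
  expect_output(print(fit), "baseline")
  s <- summary(fit)
  expect_output(print(s), "Log-likelihood")
  expect_equal(coef(fit), fit$coefficients)
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_cpm(fit, path)
  back <- read_cpm(path)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  expect_equal(predict(back, dev[1:5, ], regime = "observed"),
               predict(fit, dev[1:5, ], regime = "observed"))
})
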