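#' Configure the longitudinal (person-period) generator
#'
#' Parameters of a discrete-time cohort with annual covariate review,
#' treatment drop-in, right censoring and a terminal event, emulating the
#' structure of a primary-care statin/cardiovascular-disease cohort at desk
#' scale. All hazards are logit-linear in the stated covariates, so every
#' weight model and the pooled outcome model fitted by this module are
#' correctly specified by construction.
#'
#' Subjects carry a continuous baseline risk factor \eqn{x_0 \sim N(0,1)} and
#' a binary baseline covariate \eqn{z}. Within interval `k` (annual), in
#' order: the time-updated covariate is reviewed
#' (\eqn{x_k = x_{k-1} + \gamma_L a_{k-1} + N(0, \sigma_x^2)}); the subject
#' may be censored (hazard depending on \eqn{x_k} and treatment status); the
#' event may occur (hazard depending on \eqn{k}, \eqn{x_0}, \eqn{z} and
#' treatment status, with a protective treatment effect); finally an untreated
#' survivor may initiate treatment (hazard depending on \eqn{x_k}), which
#' takes effect from the next interval. Treatment is absorbing — no
#' discontinuation — and the one-interval lag between initiation and effect
#' means an event is never attributed a same-interval initiation.
#'
#' @param gamma_l Covariate shift per interval of in-force treatment
#'   (protective treatment lowers the risk factor; default -0.5).
#' @param sd_x Standard deviation of the annual covariate innovation.
#' @param alpha_treat,phi_treat Initiation hazard intercept and log-odds per
#'   unit of the current covariate.
#' @param alpha_cens,cens_x,cens_a Censoring hazard intercept and log-odds for
#'   the current covariate and treatment status.
#' @param alpha_event,event_trend Event hazard intercept and linear
#'   per-interval trend (log-odds scale).
#' @param event_x0,event_z,event_a Event log-odds per unit baseline covariate,
#'   for the binary covariate, and for in-force treatment.
#' @param p_z Prevalence of the binary baseline covariate.
#' @return An object of class `"longitudinal_config"`.
#' @export
longitudinal_config <- function(gamma_l = -0.5, sd_x = 0.5,
                                alpha_treat = -4.6, phi_treat = log(2),
                                alpha_cens = -2.5, cens_x = 0.1,
                                cens_a = -0.3,
                                alpha_event = -4.9, event_trend = 0.05,
                                event_x0 = log(1.5), event_z = log(1.3),
                                event_a = log(0.5), p_z = 0.5) {
  structure(as.list(environment()), class = "longitudinal_config")
}

#' Generate a longitudinal person-period cohort
#'
#' Draws `n` subjects followed for up to `K` annual intervals under the
#' mechanism described in [longitudinal_config()]. Each subject contributes
#' one row per interval up to and including the first of event, censoring, or
#' the end of follow-up.
#'
#' @param config A [longitudinal_config()].
#' @param n Number of subjects.
#' @param K Number of annual intervals (>= 2).
#' @param seed Integer seed.
#' @return A data frame of class `"person_period"` with columns `id`, `k`
#'   (interval index, 0-based), `x0`, `z`, `x` (current covariate), `a`
#'   (treatment in force during the interval; non-decreasing), `c` (censored
#'   during the interval), `y` (event during the interval).
#' @export
generate_longitudinal <- function(config, n, K = 10L, seed = 1L) {
  stopifnot(inherits(config, "longitudinal_config"), n >= 1, K >= 2)
  state <- local_rng(seed)
  on.exit(restore_rng(state))
  x0 <- stats::rnorm(n)
  z <- stats::rbinom(n, 1L, config$p_z)
  active <- rep(TRUE, n)
  x_prev <- x0
  a_prev <- rep(0L, n)   # status in force during the previous interval
  s <- rep(0L, n)        # status in force during the current interval
  rows <- vector("list", K)
  for (k in seq_len(K) - 1L) {
    idx <- which(active)
    if (length(idx) == 0L) break
    m <- length(idx)
    x_k <- if (k == 0L) x0[idx] else
      x_prev[idx] + config$gamma_l * a_prev[idx] +
        stats::rnorm(m, sd = config$sd_x)
    s_k <- s[idx]
    c_k <- stats::rbinom(m, 1L, stats::plogis(
      config$alpha_cens + config$cens_x * x_k + config$cens_a * s_k))
    h_y <- stats::plogis(
      config$alpha_event + config$event_trend * k +
        config$event_x0 * x0[idx] + config$event_z * z[idx] +
        config$event_a * s_k)
    y_k <- ifelse(c_k == 1L, 0L, stats::rbinom(m, 1L, h_y))
    rows[[k + 1L]] <- data.frame(
      id = idx, k = k, x0 = x0[idx], z = z[idx], x = x_k,
      a = s_k, c = c_k, y = y_k)
    ended <- c_k == 1L | y_k == 1L
    active[idx[ended]] <- FALSE
    cont <- idx[!ended]
    if (length(cont) > 0L && k < K - 1L) {
      at_risk <- s[cont] == 0L
      init <- integer(length(cont))
      if (any(at_risk)) {
        x_cont <- x_k[!ended][at_risk]
        init[at_risk] <- stats::rbinom(
          sum(at_risk), 1L,
          stats::plogis(config$alpha_treat + config$phi_treat * x_cont))
      }
      s_next <- pmax(s[cont], init)
      x_prev[cont] <- x_k[!ended]
      a_prev[cont] <- s[cont]
      s[cont] <- s_next
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$id, out$k), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("person_period", "data.frame")
  attr(out, "K") <- as.integer(K)
  attr(out, "config") <- config
  if (sum(out$y) == 0L || !any(out$a == 1L))
    warning("degenerate cohort: no events or no treatment drop-in generated")
  out
}

#' Map a two-timepoint cohort to a two-period person-period table
#'
#' Each subject becomes two rows: interval 0 carries the baseline covariate
#' and baseline treatment, interval 1 the follow-up covariate, follow-up
#' treatment, and the outcome. No censoring. Note the mapped `a` column is the
#' raw per-timepoint treatment of the wide cohort, which need not be
#' non-decreasing (e.g. randomized designs with treatment dropout); the
#' fitting functions accept such tables when `absorbing = FALSE`.
#'
#' @param cohort A two-timepoint cohort (`x0, a0, x1, a1, y`).
#' @return A `person_period` data frame.
#' @export
as_person_period <- function(cohort) {
  stopifnot(all(c("x0", "a0", "x1", "a1", "y") %in% names(cohort)))
  n <- nrow(cohort)
  out <- data.frame(
    id = rep(seq_len(n), each = 2L),
    k = rep(c(0L, 1L), n),
    x0 = rep(cohort$x0, each = 2L),
    x = as.vector(rbind(cohort$x0, cohort$x1)),
    a = as.vector(rbind(cohort$a0, cohort$a1)),
    c = 0L,
    y = as.vector(rbind(0L, cohort$y)))
  class(out) <- c("person_period", "data.frame")
  attr(out, "K") <- 2L
  out
}

#' Restricted cubic spline basis for the period index
#'
#' Truncated-power restricted cubic spline: cubic between the boundary knots
#' and constrained to be linear beyond them, giving `n_knots - 1` basis
#' columns (one linear term plus `n_knots - 2` restricted cubic terms). Knots
#' default to conventional quantiles of the observed period distribution
#' (e.g. \{0.05, 0.35, 0.65, 0.95\} for four knots).
#'
#' @param periods Integer vector of observed period indices.
#' @param n_knots Number of knots (>= 3).
#' @param knots Optional explicit knot locations (overrides `n_knots`).
#' @return An object of class `"rcs_basis"`: list with `knots` and `basis`
#'   (the evaluated matrix, one row per element of `periods`).
#' @export
rcs_basis <- function(periods, n_knots = 4L, knots = NULL) {
  if (is.null(knots)) {
    if (n_knots < 3L) stop("'n_knots' must be >= 3")
    probs <- switch(as.character(n_knots),
                    "3" = c(0.10, 0.50, 0.90),
                    "4" = c(0.05, 0.35, 0.65, 0.95),
                    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
                    "7" = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167,
                            0.975),
                    seq(0.05, 0.95, length.out = n_knots))
    knots <- unique(stats::quantile(periods, probs, names = FALSE, type = 7))
  }
  knots <- sort(knots)
  if (length(unique(periods)) < length(knots))
    stop("fewer distinct periods than knots")
  if (length(knots) < 3L)
    stop("knot placement collapsed below 3 distinct knots")
  structure(list(knots = knots, basis = rcs_eval(periods, knots)),
            class = "rcs_basis")
}

# Harrell-parametrized RCS evaluation: m knots -> m-1 columns.
rcs_eval <- function(x, knots) {
  m <- length(knots)
  t1 <- knots[1]; tm1 <- knots[m - 1]; tm <- knots[m]
  scale2 <- (tm - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), m - 1L)
  out[, 1] <- x
  for (j in seq_len(m - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
                        pos3(x - tm1) * (tm - tj) / (tm - tm1) +
                        pos3(x - tm) * (tm1 - tj) / (tm - tm1)) / scale2
  }
  colnames(out) <- c("k", paste0("k'", seq_len(m - 2L)))
  out
}

# Time-intercept columns for pooled models: RCS when the period range
# supports it, plain period dummies otherwise, or nothing.
time_columns <- function(k, n_knots, time = c("rcs", "factor", "none")) {
  time <- match.arg(time)
  if (time == "none") return(list(X = NULL, knots = NULL, time = time))
  if (time == "rcs" && length(unique(k)) > n_knots) {
    b <- rcs_basis(k, n_knots)
    return(list(X = b$basis, knots = b$knots, time = "rcs"))
  }
  lev <- sort(unique(k))
  if (length(lev) < 2L) return(list(X = NULL, knots = NULL, time = "none"))
  X <- vapply(lev[-1], function(l) as.numeric(k == l), numeric(length(k)))
  colnames(X) <- paste0("k", lev[-1])
  list(X = X, knots = lev, time = "factor")
}

# Keep a maximal linearly independent set of columns (constant or duplicated
# covariates arise e.g. at the baseline period, where x == x0).
drop_collinear <- function(X) {
  q <- qr(X)
  if (q$rank == ncol(X)) return(X)
  X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
}

lag_within <- function(v, id) {
  out <- c(0, v[-length(v)])
  out[c(TRUE, id[-1] != id[-length(id)])] <- 0
  out
}

baseline_cols <- function(tab) {
  cols <- list(x0 = tab$x0)
  if ("z" %in% names(tab)) cols$z <- tab$z
  cols
}

#' Stabilized treatment and censoring weights for person-period data
#'
#' Builds, for every person-period, the cumulative stabilized weight
#' (treatment factors times censoring factors) used by the pooled marginal
#' structural model. All component models are pooled logistic regressions with
#' a restricted-cubic-spline period intercept. Numerator models condition on
#' the baseline covariates (and prior treatment); denominator models add the
#' time-updated covariate.
#'
#' With `absorbing = TRUE` (the generator's convention) treatment is an
#' absorbing state: initiation models are fitted only on person-periods still
#' at risk of initiation (untreated, record continuing), the modelled
#' transition is the next interval's in-force status, and a subject's
#' treatment factors are 1 from initiation onwards. With `absorbing = FALSE`
#' the current treatment column is modelled directly at every period given
#' lagged treatment and covariates, which accommodates tables with
#' discontinuation such as [as_person_period()] mappings of two-timepoint
#' cohorts.
#'
#' @param table A `person_period` data frame.
#' @param n_knots Knots for the period spline in all component models.
#' @param pool_periods If `FALSE`, fit separate per-period models instead of
#'   pooled ones (no time term inside each).
#' @param absorbing See above.
#' @param clip Probability clipping bound, as in
#'   [compute_stabilized_weights()].
#' @return An object of class `"longitudinal_weights"`: list with `sw`
#'   (cumulative weight per table row), `sw_treat`, `sw_cens`, and the fitted
#'   component coefficient sets.
#' @export
fit_longitudinal_weights <- function(table, n_knots = 4L,
                                     pool_periods = TRUE, absorbing = TRUE,
                                     clip = 1e-6) {
  tab <- table[order(table$id, table$k), , drop = FALSE]
  n <- nrow(tab)
  cl <- function(p) pmin(pmax(p, clip), 1 - clip)
  obs_prob <- function(p, a) ifelse(a == 1, p, 1 - p)

  fit_pair <- function(rows, response, num_base, den_base) {
    # returns per-row numerator/denominator probabilities for the rows
    fit_one <- function(base) {
      if (pool_periods) {
        tc <- time_columns(rows$k, n_knots)
        X <- drop_collinear(
          do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(rows))),
                           if (!is.null(tc$X)) list(tc$X), base)))
        stats::plogis(drop(X %*% fit_logit(X, response)[colnames(X)]))
      } else {
        p <- numeric(nrow(rows))
        for (kk in sort(unique(rows$k))) {
          ix <- rows$k == kk
          base_k <- lapply(base, function(col) col[ix])
          X <- drop_collinear(
            do.call(cbind, c(list(`(Intercept)` = rep(1, sum(ix))),
                             base_k)))
          p[ix] <- stats::plogis(
            drop(X %*% fit_logit(X, response[ix])[colnames(X)]))
        }
        p
      }
    }
    list(num = fit_one(num_base), den = fit_one(den_base))
  }

  # --- treatment factors -------------------------------------------------
  f_treat <- rep(1, n)
  if (length(unique(tab$a)) < 2L) {
    treat_fit <- NULL  # no variation: factors stay 1
  } else if (absorbing) {
    nxt <- c(tab$a[-1], NA)
    nxt[c(tab$id[-1] != tab$id[-n], TRUE)] <- NA
    at_risk <- tab$a == 0L & !is.na(nxt)
    rows <- tab[at_risk, , drop = FALSE]
    resp <- nxt[at_risk]
    bc <- baseline_cols(rows)
    pr <- fit_pair(rows, resp, num_base = bc,
                   den_base = c(bc, list(x = rows$x)))
    # the transition decided at row j applies to the next interval; a
    # subject's factor stream is that per-decision ratio, carried forward
    ratio <- obs_prob(cl(pr$num), resp) / obs_prob(cl(pr$den), resp)
    f_dec <- rep(1, n)
    f_dec[at_risk] <- ratio
    # shift the decision factor onto the row it takes effect in (k+1)
    f_treat <- rep(1, n)
    same_subj <- c(FALSE, tab$id[-1] == tab$id[-n])
    f_treat[which(same_subj)] <- f_dec[which(same_subj) - 1L]
    treat_fit <- pr
  } else {
    a_lag <- lag_within(tab$a, tab$id)
    bc <- baseline_cols(tab)
    pr <- fit_pair(tab, tab$a,
                   num_base = c(list(a_lag = a_lag), bc),
                   den_base = c(list(a_lag = a_lag), bc, list(x = tab$x)))
    f_treat <- obs_prob(cl(pr$num), tab$a) / obs_prob(cl(pr$den), tab$a)
    treat_fit <- pr
  }

  # --- censoring factors -------------------------------------------------
  if (any(tab$c == 1L)) {
    bc <- baseline_cols(tab)
    pr <- fit_pair(tab, tab$c,
                   num_base = c(bc, list(a = tab$a)),
                   den_base = c(bc, list(a = tab$a, x = tab$x)))
    f_cens <- (1 - cl(pr$num)) / (1 - cl(pr$den))
    cens_fit <- pr
  } else {
    f_cens <- rep(1, n)
    cens_fit <- NULL
  }

  cumprod_within <- function(f, id) {
    out <- numeric(length(f))
    start <- c(TRUE, id[-1] != id[-length(id)])
    acc <- 1
    for (i in seq_along(f)) {
      if (start[i]) acc <- 1
      acc <- acc * f[i]
      out[i] <- acc
    }
    out
  }
  sw_treat <- cumprod_within(f_treat, tab$id)
  sw_cens <- cumprod_within(f_cens, tab$id)
  sw <- sw_treat * sw_cens
  # map back to the caller's row order
  ord <- order(order(table$id, table$k))
  structure(list(sw = sw[ord], sw_treat = sw_treat[ord],
                 sw_cens = sw_cens[ord],
                 factor_treat = f_treat[ord], factor_cens = f_cens[ord]),
            class = "longitudinal_weights")
}

#' @export
print.longitudinal_weights <- function(x, ...) {
  cat(sprintf("Cumulative stabilized weights for %d person-periods\n",
              length(x$sw)))
  cat(sprintf("  mean %.4f, sd %.4f, range [%.4f, %.4f]\n",
              mean(x$sw), stats::sd(x$sw), min(x$sw), max(x$sw)))
  invisible(x)
}

#' Fit a pooled logistic hazard model on person-period data
#'
#' The marginal structural model of the longitudinal setting: a weighted
#' pooled logistic regression of the per-interval event indicator on a
#' restricted-cubic-spline period intercept, the baseline covariates, and the
#' in-force treatment indicator, fitted on uncensored person-periods with the
#' cumulative stabilized weights. Fitting it unweighted without the treatment
#' term (`treatment = "none"`, `weights = NULL`) gives the treatment-naive
#' comparator.
#'
#' @param table A `person_period` data frame.
#' @param weights A [fit_longitudinal_weights()] result, a numeric vector
#'   aligned to the table rows, or `NULL` for unweighted maximum likelihood.
#' @param n_knots Knots for the period spline.
#' @param treatment `"current"` (in-force status, the default), `"none"`
#'   (treatment-naive), or `"both"` (adds lagged treatment; used e.g. when a
#'   two-timepoint cohort is mapped onto person-periods).
#' @param time `"rcs"` (default), `"factor"`, or `"none"`.
#' @return An object of class `"pooled_cpm"` with coefficients, the spline
#'   definition, and the fitted period support.
#' @export
fit_pooled_msm <- function(table, weights = NULL, n_knots = 4L,
                           treatment = c("current", "none", "both"),
                           time = c("rcs", "factor", "none")) {
  treatment <- match.arg(treatment)
  time <- match.arg(time)
  tab <- table[table$c == 0L, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(table)) else if
    (inherits(weights, "longitudinal_weights")) weights$sw else
      as.numeric(weights)
  if (length(w) != nrow(table))
    stop("weights must align with the person-period rows")
  w <- w[table$c == 0L]
  tc <- time_columns(tab$k, n_knots, time)
  base <- baseline_cols(tab)
  trt <- switch(treatment,
                none = NULL,
                current = if (constant_col(tab$a)) NULL else list(a = tab$a),
                both = {
                  al <- if ("a_lag" %in% names(tab)) tab$a_lag else
                    lag_within(tab$a, tab$id)
                  cols <- list()
                  if (!constant_col(al)) cols$a_lag <- al
                  if (!constant_col(tab$a)) cols$a <- tab$a
                  cols
                })
  X <- do.call(cbind, c(list(`(Intercept)` = rep(1, nrow(tab))),
                        if (!is.null(tc$X)) list(tc$X), base, trt))
  fit <- weighted_logistic_mle(X, tab$y, w)
  structure(
    list(coefficients = fit$coefficients, vcov = fit$vcov,
         converged = fit$converged,
         loglik = fit$loglik, n_used = nrow(tab),
         weighted = !is.null(weights), treatment = treatment,
         time = tc$time, knots = tc$knots,
         K_fit = max(tab$k) + 1L, has_z = "z" %in% names(tab)),
    class = "pooled_cpm")
}

#' @export
print.pooled_cpm <- function(x, ...) {
  cat(sprintf(
    "Pooled logistic hazard model (%s, treatment term: %s, n = %d)\n",
    if (x$weighted) "stabilized-weighted" else "maximum likelihood",
    x$treatment, x$n_used))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.pooled_cpm <- function(object, ...) object$coefficients

#' @export
vcov.pooled_cpm <- function(object, ...) object$vcov

# Per-interval hazard under no treatment for one covariate profile per row.
hazard_matrix <- function(model, newdata, K) {
  ks <- seq_len(K) - 1L
  tc <- switch(model$time,
               rcs = rcs_eval(ks, model$knots),
               factor = {
                 lev <- model$knots
                 Xf <- vapply(lev[-1], function(l) as.numeric(ks == l),
                              numeric(length(ks)))
                 colnames(Xf) <- paste0("k", lev[-1])
                 Xf
               },
               none = NULL)
  cf <- model$coefficients
  eta_t <- rep(cf[["(Intercept)"]], K)
  if (!is.null(tc)) eta_t <- eta_t + drop(tc %*% cf[colnames(tc)])
  eta_i <- cf[["x0"]] * newdata$x0
  if (model$has_z) {
    if (!"z" %in% names(newdata)) stop("'newdata' lacks the z covariate")
    eta_i <- eta_i + cf[["z"]] * newdata$z
  }
  stats::plogis(outer(eta_i, eta_t, `+`))
}

#' Cumulative event risk under no treatment
#'
#' \eqn{1 - \prod_{k=0}^{K-1} (1 - h_k)}, with \eqn{h_k} the fitted
#' per-interval hazard holding treatment at zero throughout — the predicted
#' treatment-naive K-year risk.
#'
#' @param model A fitted [fit_pooled_msm()].
#' @param newdata Data frame of baseline covariates (`x0`, and `z` if the
#'   model has it).
#' @param K Horizon in intervals; must not exceed the fitted period support
#'   (no extrapolation beyond the spline's range).
#' @return Numeric vector of cumulative risks, one per row of `newdata`.
#' @export
predict_cumulative_risk <- function(model, newdata, K = model$K_fit) {
  stopifnot(inherits(model, "pooled_cpm"))
  if (!isTRUE(model$converged)) stop("model did not converge")
  if (K > model$K_fit)
    stop(sprintf("K = %d exceeds the fitted period support (%d): %s",
                 K, model$K_fit, "refusing to extrapolate the time spline"))
  h <- hazard_matrix(model, newdata, K)
  unname(1 - apply(1 - h, 1L, prod))
}

#' Read or write a person-period table as delimited text
#'
#' @param table A `person_period` data frame.
#' @param path File path.
#' @return `read_person_period()` returns the table; `write_person_period()`
#'   returns `path` invisibly.
#' @export
write_person_period <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_person_period
#' @export
read_person_period <- function(path) {
  raw <- utils::read.csv(path)
  need <- c("id", "k", "x0", "x", "a", "c", "y")
  if (!all(need %in% names(raw)))
    stop("person-period file must have columns ",
         paste(need, collapse = ", "))
  class(raw) <- c("person_period", "data.frame")
  attr(raw, "K") <- max(raw$k) + 1L
  raw
}
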