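---
title: "Adjusting clinical prediction models for treatment drop-in with marginal structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting clinical prediction models for treatment drop-in with marginal structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A clinical prediction model (CPM) that guides treatment initiation should
report the risk a patient faces *if no treatment is given* — not the risk
averaged over whatever treatment their look-alikes in the development data
happened to receive. Development cohorts drawn from routine care violate this
in two ways: some patients are already treated at baseline, and others start
treatment between baseline and the outcome ("treatment drop-in"). A
protective treatment taken up preferentially by high-risk patients drags
their observed event rates down, so a model fitted naively to such data
under-states untreated risk and, used with a decision threshold,
under-allocates treatment.

`msmcpm` implements and compares four ways of handling this in the simplest
setting that exhibits the full mechanism — one continuous risk factor and one
binary treatment, each measured at baseline (time 0) and once more before the
outcome (time 1):

* **ignore** — regress the outcome on the baseline risk factor $x_0$ only;
* **naive** — the same regression restricted to patients untreated at
  baseline;
* **baseline** — add a baseline-treatment term $a_0$;
* **msm** — a marginal structural model including the whole treatment path,
  $\operatorname{logit} P(Y\mid x_0,\bar a) = \beta_0 + \beta_X x_0 +
  \beta_{A0} a_0 + \beta_{A1} a_1$, fitted by weighted maximum likelihood.

The estimand hierarchy behind the comparison: risk disregarding treatment
(what "ignore" estimates); risk given no treatment *now*; risk given no
treatment *now or later* — the treatment-naive risk a deployment needs; and
the corresponding intervene-now / sustain-treatment quantities. Only a model
that carries the full treatment path can be asked the third question, by
setting $a_0 = a_1 = 0$ in the linear predictor (`predict(fit, newdata,
regime = "none")`).

## Stabilized weights and the weighted likelihood

The MSM removes the covariate-driven part of treatment assignment by
reweighting. For each subject the stabilized weight is

$$ sw_i \;=\; \frac{\prod_k \hat p^{*\,a_{ki}}_{ki}\,(1-\hat p^*_{ki})^{1-a_{ki}}}
               {\prod_k \hat p^{\,a_{ki}}_{ki}\,(1-\hat p_{ki})^{1-a_{ki}}}, $$

where the denominator models condition on the lagged treatment and the full
covariate history ($a_{k-1}, x_0, \dots, x_k$) and the numerator models only
on lagged treatment and the baseline covariate. Because the CPM must predict
within strata of everything known at baseline, the numerator *keeps* $x_0$
even though it is merely prognostic — its time-0 factor then cancels exactly
against the denominator's, so in this two-timepoint design the weights are
driven entirely by how much the updated covariate $x_1$ explains the second
treatment decision. The outcome model is then fitted by maximizing
$\sum_i sw_i [y_i \log \pi_i + (1-y_i)\log(1-\pi_i)]$
(`weighted_logistic_mle()`, Newton–Raphson/IRLS with step-halving,
convergence at $|\Delta\ell| < 10^{-8}$ or score sup-norm $< 10^{-6}$).

Numerical choices, made once:

* fitted assignment probabilities are clipped to $[10^{-6}, 1-10^{-6}]$
  before the ratio is formed. Structural zeroes are legitimate (in a
  randomized design nobody untreated at baseline starts treatment, so that
  stratum's fitted follow-up probability is 0); clipping bounds the weights
  there while leaving regular scenarios untouched;
* weights are *not* truncated by default — the stabilized form already has
  mean $\approx 1$ — but `compute_stabilized_weights(..., truncate =
  c(0.01, 0.99))` winsorizes on request;
* treatment-by-covariate interaction terms exist behind
  `cpm(..., interactions = TRUE)` but default off: the simulated mechanism
  has no effect modification, and the default mirrors the additive design;
* complete separation in a treatment model is an error (no divergent
  coefficients are ever returned); quasi-separation from structural zeroes is
  tolerated and handled by the clipping rule.

## The synthetic cohort generator

The generator is the package's definition of the study conditions, not a
tuning knob. A cohort of size $n$ is drawn as
$x_0 \sim N(0,1)$;
$a_0 \sim \text{Bern}(\text{expit}(\alpha_0 + \phi x_0))$;
$x_1 \sim N(x_0 + \gamma a_0, 1)$;
$a_1 \sim \text{Bern}(\theta a_0)$ in the randomized design or
$\text{Bern}(\text{expit}(\alpha_1 + \phi x_1 + \theta a_0))$ in the
observational one; and
$y \sim \text{Bern}(\text{expit}(\alpha_Y + \beta_{X0} x_0 + \beta_{X1} x_1 +
\beta_{A0} a_0 + \beta_{A1} a_1))$.

Three presets span the designs of interest, all with
$\beta_{X0}=\beta_{X1}=\log 1.5$ (the risk factor raises risk),
$\beta_{A0}=\beta_{A1}=\log 0.5$ (treatment halves the odds), and a 20%
marginal event rate:

| preset | design | $\phi$ | $\theta$ | treated |
|---|---|---|---|---|
| `rct_10pct_dropout` | randomized | 0 | 0.9 (retention prob.) | 50% |
| `obs_50pct_treated` | observational | $\log 2$ | $\log 2$ (log-odds carry-over) | 50% |
| `obs_20pct_treated` | observational | $\log 2$ | $\log 2$ | 20% |

$\gamma \le 0$ is the treatment's lowering effect on the follow-up risk
factor, swept over $(-3, -2.5, -2, -1.5, -1, -0.5, 0)$ by default; positive
values (treatment worsening the risk factor it is meant to control) are
outside the study conditions, though the configuration type accepts them.

The intercepts are defined only implicitly, by the marginal rates they must
achieve. `calibrate_scenario()` resolves them by bracketed root-finding
(`uniroot`) on a fixed-seed Monte-Carlo estimate of each marginal
($2 \times 10^5$ draws, tolerance $10^{-3}$ on the probability scale),
sequentially in the order the mechanism unfolds: $\alpha_0$ on draws of
$x_0$; then $a_0$ and $x_1$ are drawn and $\alpha_1$ solved against the
marginal follow-up treatment rate; then $a_1$ is drawn and $\alpha_Y$ solved.
Monte-Carlo calibration was chosen over closed-form integration because the
$\alpha_1$ and $\alpha_Y$ marginals depend on the induced joint distribution
of $(x_1, a_0, a_1)$, for which no convenient closed form exists; the
fixed internal seed makes calibration deterministic. Because the calibration
draws are shared across candidate intercepts, the bracketed function is
smooth and strictly monotone, and the solver is exact to far below the
Monte-Carlo tolerance. An open choice the package had to make: in
observational designs $\alpha_1$ is calibrated to the *marginal* follow-up
treatment rate (not a within-stratum rate), which is the reading consistent
with "x% of the population have treatment".

Randomness follows one root seed per experiment. `child_seed()` derives a
stream per cohort (development / mixed test / no-treatment test) and per
replicate with a counter-based rule, so any cell of a sweep is reproducible
in isolation and cells can run in any order.

## Evaluation

Each fitted strategy is evaluated in three settings: on a fresh cohort from
the development process (internal-validation performance), on its
untreated-at-baseline subset, and on a cohort in which treatment is withheld
from everyone (the treatment-naive question; predictions use the all-zero
regime there). Metrics are calibration-in-the-large (the intercept of a
logistic recalibration with the linear predictor as a fixed offset — the
standard CPM-literature definition, on the log-odds scale, positive when the
model under-predicts), the calibration slope, the exact midrank Mann–Whitney
AUC (deterministic and tie-safe, unlike a trapezoidal ROC), the Brier score,
and — in the no-treatment setting only — the treatment-allocation curve: the
fraction of patients whose predicted treatment-naive risk exceeds each
threshold on a 5%–70% grid in 5-point steps (the step is the package's
choice; only the endpoints are inherent to the question).

`run_experiment()` repeats this over scenario × $\gamma$ × replicate and
reports each metric's mean and empirical standard error, defined as the
across-replicate standard deviation divided by $\sqrt{n_{\text{reps}}}$ (the
standard error of the reported mean; error-bar multipliers are left to the
consumer). Replicates draw independent development data; no common random
numbers are shared across $\gamma$ values.

```{r, eval = FALSE}
library(msmcpm)
plan <- experiment_plan(scenarios = "obs_50pct_treated", gamma_grid = 0,
                        n_dev = 10000, n_test = 50000, n_reps = 200,
                        root_seed = 1)
run <- run_experiment(plan)
subset(run$results, metric == "alloc_0.40" & setting == "NTT")
```

## Problem sizes

The package's tests and the reproduction script run at desk scale, chosen
once: the allocation study uses 200 replicates with development cohorts of
10,000 and test cohorts of 50,000; the scenario-by-$\gamma$ calibration grid
uses 200 replicates, $\gamma \in \{-3, -1.5, 0\}$ and test cohorts of
20,000. Development-cohort size is part of the study conditions (the
finite-sample behaviour of a model fitted to 10,000 patients is the object
of study); test-cohort and replicate counts only set Monte-Carlo resolution,
and the reported empirical standard errors quantify exactly what that
resolution is.

## The discrete-time longitudinal extension

The same ideas scale to a K-year risk model fitted on person-period data:
one row per patient per year at risk, a pooled logistic model for the annual
event hazard with a restricted-cubic-spline year intercept, and cumulative
stabilized weights that now also carry an inverse-probability-of-censoring
component — censoring is treated as a second time-varying "treatment" whose
weight models are symmetric with the initiation models (numerator: baseline
covariates and prior treatment; denominator: plus the time-updated
covariate; both include the year spline — the package includes the spline on
both sides since nothing pins this down externally). The predicted K-year
treatment-naive risk is $1 - \prod_{k<K} (1 - \hat h_k)$ with the hazard
evaluated at zero treatment; the spline is never extrapolated beyond the
fitted year range.

The synthetic longitudinal generator emulates the *structure* of a
primary-care statin/cardiovascular cohort — annual covariate review,
covariate-driven treatment drop-in, right censoring, a terminal event, about
a 9% ten-year event rate, roughly half the cohort censored before ten years,
and single-digit-percent drop-in under the defaults — at desk scale. Its
design choices:

* **treatment is absorbing** (no discontinuation is modelled), and
  initiation during year $k$ takes effect from year $k+1$: the `a` column is
  the status *in force* during an interval. An event can therefore never be
  attributed a same-year initiation, reproducing the one-year lag between
  prescription and modelled exposure without calendar dates;
* **every model is correctly specified by construction**: the event hazard
  is logit-linear in the year, the baseline covariates and the in-force
  treatment; initiation and censoring hazards are logit-linear in the
  current covariate and treatment. This is deliberate — the module's tests
  separate estimator correctness from approximation error. Two consequences
  should be kept in mind when interpreting green tests. First, because the
  event hazard depends on time-updated covariates only through baseline, the
  unweighted treatment-adjusted fit would also be consistent here; the
  weights are exercised and must be *harmless* (and are required for the
  censoring adjustment), but this generator cannot demonstrate that
  weighting is *necessary*. Second, real cohorts add everything the
  generator omits: residual confounding, informative observation times,
  missing covariate data (the imputation machinery of real analyses is
  intentionally out of scope), measurement error, and non-logit-linear
  hazards;
* **spline knots** default to 4, at the conventional
  $\{0.05, 0.35, 0.65, 0.95\}$ quantiles of the observed year distribution
  (3–7 knots use the standard quantile sequences); the basis is the
  truncated-power restricted cubic form, $m$ knots giving $m-1$ columns and
  exact linearity outside the boundary knots;
* default hazard parameters: initiation intercept $-4.6$ with $\log 2$ per
  unit of the current covariate; censoring intercept $-2.5$ (about 8% per
  year, matching the heavy administrative censoring of routine-care
  registries) with mild covariate and treatment dependence; event intercept
  $-4.9$ with a $+0.05$/year trend, $\log 1.5$ per unit baseline covariate,
  $\log 1.3$ for the binary covariate and $\log 0.5$ for treatment.

A deliberately generalized corner: the weight-fitting functions accept
`absorbing = FALSE` and `pool_periods = FALSE`, in which case the current
treatment column is modelled directly given its lag with separate per-period
models. On a two-period mapping of a two-timepoint cohort
(`as_person_period()`) this reproduces the two-timepoint weight engine and
MSM *exactly*, which is how the package cross-checks the two code paths
against each other. The absorbing convention itself cannot coincide exactly
with the two-timepoint engine, whose lagged-treatment coefficient only stays
finite when some patients discontinue.

## Known limitations

* The two-timepoint MSM is, after marginalizing the follow-up risk factor,
  only approximately logit-linear; its treatment-naive predictions carry a
  small model-approximation and finite-sample offset (of the order of a few
  hundredths on the log-odds scale for development cohorts of 10,000, and
  vanishing as the development cohort grows). The package reports
  calibration-in-the-large with empirical standard errors so this is visible
  rather than hidden.
* In the mixed-treatment evaluation setting the strategies' predictions use
  the subjects' observed treatments; models that carry treatment terms
  genuinely discriminate better there (treatment has a direct protective
  effect at every $\gamma$), so the four AUCs narrow as $\gamma \to 0$
  without meeting.
* One treatment, one (summary) continuous covariate per timepoint in the
  two-timepoint engine; no competing risks, no time-varying treatment
  effects, no doubly robust or covariate-balancing estimators.
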