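# msmcpm

Marginal structural models for clinical prediction under treatment drop-in.

## The problem

Clinical prediction models (CPMs) that guide treatment initiation should
report the risk a patient faces **if no treatment is given** — formally
`E[Y(ā = 0̄) | X₀]`, the treatment-naive risk. But development cohorts from
routine care contain patients who are treated at baseline and patients who
start treatment after baseline but before the outcome ("treatment drop-in").
If a protective treatment is taken up preferentially by high-risk patients,
a model fitted to such data absorbs the treatment effect into its covariate
coefficients, under-states untreated risk, and — used with a decision
threshold — under-allocates treatment.

`msmcpm` is for biostatisticians and prediction-model developers who want to
quantify that bias and correct it. It fits and compares four strategies on
two-timepoint cohorts (risk factor `x0, x1`; binary treatment `a0, a1`;
binary outcome `y`):

| strategy | outcome model | fitted on |
|---|---|---|
| `ignore` | `logit P(Y) = β₀ + β_X x₀` | everyone |
| `naive` | `β₀ + β_X x₀` | untreated at baseline |
| `baseline` | `β₀ + β_X x₀ + β_A0 a₀` | everyone |
| `msm` | `β₀ + β_X x₀ + β_A0 a₀ + β_A1 a₁` | everyone, weighted |

The MSM is fitted by maximizing the weighted log-likelihood
`Σᵢ swᵢ [yᵢ log πᵢ + (1−yᵢ) log(1−πᵢ)]` with stabilized
inverse-probability-of-treatment weights

```
swᵢ = Π_k p̂*ₖᵢ^aₖᵢ (1−p̂*ₖᵢ)^(1−aₖᵢ)  /  Π_k p̂ₖᵢ^aₖᵢ (1−p̂ₖᵢ)^(1−aₖᵢ)
```

where the denominator models `logit P(Aₖ=1 | A_{k−1}, X̄ₖ)` condition on the
full covariate history and the numerator models `logit P(Aₖ=1 | A_{k−1},
X₀)` only on baseline. Because the MSM carries the whole treatment path, its
predictions can be evaluated under explicit regimens — in particular
`a₀ = a₁ = 0`, the quantity a treatment-initiation decision needs.

The package also ships, as first-class tested components:

* a synthetic-cohort generator for three study designs (a randomized trial
  with treatment dropout; observational designs with 50% / 20% treated),
  with Monte-Carlo calibration of all intercepts to target marginal rates;
* calibration (CITL, slope), discrimination (exact Mann–Whitney AUC), Brier
  score, and treatment-allocation curves, evaluated under
  mix-of-treatment / no-baseline-treatment / no-treatment-throughout
  settings;
* a simulation harness over scenario × covariate-effect (γ) × replicate with
  empirical standard errors and counter-based reproducible seeding;
* a discrete-time longitudinal extension: person-period cohorts with annual
  review, treatment drop-in, right censoring; pooled logistic hazard models
  with restricted-cubic-spline year intercepts; combined treatment and
  censoring stabilized weights; K-year treatment-naive risk prediction.

## Worked example

```r
library(msmcpm)

cfg <- calibrate_scenario(scenario_preset("obs_50pct_treated", gamma = -1))
cfg
#> Two-timepoint scenario 'obs_50pct_treated' (observational design, calibrated)
#>   phi = 0.6931, theta = 0.6931, gamma = -1
#>   targets: P(A0=1) = 0.5, P(A1=1) = 0.5, P(Y=1) = 0.2
#>   intercepts: alpha0 = 0.0008, alpha1 = 0.0011, alphaY = -0.6949

dev <- generate_development(cfg, 10000, seed = child_seed(42, 1))
sw  <- compute_stabilized_weights(dev, fit_treatment_models(dev))
msm <- cpm(dev, "msm", weights = sw)
msm
#> Prediction model, strategy 'msm' [weighted MLE] (n = 10000)
#> (Intercept)          x0          a0          a1
#>    -0.64150     0.77915    -1.06677    -0.67243

ntt <- generate_test_ntt(cfg, 50000, seed = child_seed(42, 3))
evaluate_cpm(msm, "NTT", test_ntt = ntt, thresholds = c(0.2, 0.4))
#> Performance of 'msm' in setting NTT (n = 50000)
#>   CITL -0.0367 | slope 1.0030 | AUC 0.6988 | Brier 0.2033
#>   allocation (risk > threshold):
#>    0.2    0.4
#> 0.8311 0.3826

evaluate_cpm(cpm(dev, "naive"), "NTT", test_ntt = ntt, thresholds = c(0.2, 0.4))
#> Performance of 'naive' in setting NTT (n = 50000)
#>   CITL 0.3053 | slope 1.1286 | AUC 0.6988 | Brier 0.2077
#>   allocation (risk > threshold):
#>    0.2    0.4
#> 0.7290 0.2084
```

Reading the output: both treatment coefficients of the MSM are negative
(treatment roughly halves the odds at each timepoint; here γ = −1 also makes
baseline treatment lower the follow-up risk factor, which the `a0`
coefficient absorbs as the total effect of the baseline decision). On a test
population where treatment is withheld from everyone, the MSM is essentially
calibrated (calibration-in-the-large −0.04, slope 1.00), while the
treatment-naive model under-predicts (CITL +0.31, i.e. observed untreated
risk is higher than it claims): at a 40% treatment threshold it would treat
21% of patients where the MSM treats 38%. Discrimination is identical — both
predictions are monotone in `x0` — the entire difference is calibration,
which is exactly what threshold-based allocation feels.

The full simulation study (scenarios × γ grid × replicates, with empirical
standard errors) runs through `experiment_plan()` / `run_experiment()`; the
longitudinal pipeline through `generate_longitudinal()`,
`fit_longitudinal_weights()`, `fit_pooled_msm()` and
`predict_cumulative_risk()`. See the vignette
(`vignettes/treatment-dropin-msm.Rmd`) for the models, parameter meanings
and design choices.

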