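# Calibrated scenario configurations are deterministic, so cache them across
# test files instead of re-running the Monte-Carlo calibration.
.config_cache <- new.env(parent = emptyenv())

cached_config <- function(preset, gamma = 0) {
  key <- paste(preset, gamma, sep = "@")
  if (is.null(.config_cache[[key]]))
    .config_cache[[key]] <- calibrate_scenario(scenario_preset(preset, gamma))
  .config_cache[[key]]
}

# Hand-built model sets and fitted-model stubs for closed-form checks.
make_treatment_models <- function(den0, num0, den1, num1) {
  structure(list(den0 = den0, num0 = num0, den1 = den1, num1 = num1),
            class = "treatment_models")
}

make_cpm <- function(strategy, coefficients) {
  structure(list(strategy = strategy, coefficients = coefficients,
                 converged = TRUE, n_used = NA_integer_,
                 weighted = strategy == "msm", interactions = FALSE),
            class = "cpm")
}
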