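# Shared helpers: hand-built trials and independent fitting oracles.

# Construct a trial_dataset directly from vectors (bypasses the
# generator so exact toy examples can be fitted).
make_trial <- function(group, baseline, outcome,
                       spec = scenario_spec(0, 0, 0, max(2L, sum(group == 1)))) {
  structure(
    list(group = as.numeric(group), baseline = as.numeric(baseline),
         outcome = as.numeric(outcome),
         change = as.numeric(outcome) - as.numeric(baseline),
         spec = spec),
    class = "trial_dataset"
  )
}

# Generic OLS oracle via lm(): returns group coefficient, its
# model-based SE, residual df and two-sided p-value.
lm_oracle <- function(formula, data) {
  fit <- lm(formula, data = data)
  cf <- summary(fit)$coefficients
  list(beta = cf["group", "Estimate"], se = cf["group", "Std. Error"],
       df = fit$df.residual, p_value = cf["group", "Pr(>|t|)"],
       coef = coef(fit))
}

# A batch of trials spanning the factor space, for property tests.
random_trials <- function(n_trials = 20, seed_base = 900) {
  lapply(seq_len(n_trials), function(i) {
    effects <- c(0, 0.2, 0.5, 0.8)
    rhos <- c(0, 0.1, 0.5, 0.9)
    devs <- c(-1.96, 0, 1.28)
    ns <- c(10L, 26L, 64L)
    spec <- scenario_spec(effects[1 + i %% 4], rhos[1 + (i %/% 4) %% 4],
                          devs[1 + i %% 3], ns[1 + i %% 3])
    generate_trial(spec, seed = seed_base + i)
  })
}

observed_imbalance <- function(trial) {
  mean(trial$baseline[trial$group == 1]) -
    mean(trial$baseline[trial$group == 0])
}
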