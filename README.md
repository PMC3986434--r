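# ancovasim

Baseline imbalance happens by chance in randomized trials, and what you
do about it at analysis time changes the answer. For a two-arm trial
with a continuous outcome measured at baseline (*Z*) and follow-up
(*Y*), three analyses are in routine use:

- **ANOVA** — regress *Y* on the group indicator (equivalently, the
  pooled two-sample t-test on follow-up scores); ignores baseline.
- **CSA** (change-score analysis) — regress *Y − Z* on group; subtracts
  the observed baseline imbalance in full.
- **ANCOVA** — regress *Y* on group and *Z* with a common slope;
  subtracts the imbalance in proportion to the estimated
  baseline-outcome slope.

`ancovasim` is a simulation laboratory for comparing these three
estimators head-to-head. It generates trials from a bivariate-normal
model with controlled baseline-outcome correlation ρ, standardized
treatment effect *y′* ∈ {0.2, 0.5, 0.8} (with the per-group sample
sizes 394/64/26 that give each effect 80% nominal power), and
standardized baseline imbalance *z*·√(2/n) for deviates
*z* ∈ {0, ±1.28, ±1.64, ±1.96}; fits all three models to each of 1000
replicates per scenario across the 7 × 6 × 3 = 126-scenario factorial;
and summarizes

- **bias** — mean paired differences β̂~ANCOVA~ − β̂~ANOVA~ and
  β̂~ANCOVA~ − β̂~CSA~, with closed forms −ρ·Δz and (1 − ρ)·Δz where
  Δz = z·√(2/n);
- **precision** — design effects (ratios of mean model-based standard
  errors), with closed forms SE~ANCOVA~/SE~ANOVA~ = √(1 − ρ²),
  SE~CSA~/SE~ANOVA~ = √(2(1 − ρ)), SE~ANCOVA~/SE~CSA~ = √((1 + ρ)/2);
- **conditional power** — the fraction of two-sided rejections at
  α = 0.05, relative to the 80% nominal level.

The OLS fits are closed-form (group means and the pooled within-group
slope), exactly matching `lm()` to 10⁻¹⁰ but fast enough for the
378 000 fits of a full run in under half a minute; `lm()`, the pooled
t-test and `power.t.test()` serve as independent oracles in the test
suite only.

## Worked example

```r
library(ancovasim)

# a trial scenario: small effect, moderate correlation, extreme
# negative baseline imbalance, the 80%-power sample size
spec <- scenario_spec(effect = 0.2, rho = 0.5, deviate = -1.96,
                      n_per_group = 394)
s <- run_scenario(spec, n_reps = 1000, master_seed = 20140409)
round(s[, c("bias_anova", "de_ancova_anova", "de_csa_anova",
            "power_anova", "power_csa", "power_ancova")], 3)
#>   bias_anova de_ancova_anova de_csa_anova power_anova power_csa power_ancova
#> 1      0.072           0.869        0.999       0.779     0.997        0.994
```

Read: with the control arm 0.14 SD better off at baseline, unadjusted
ANOVA underestimates the treatment effect by 0.07 SD relative to
ANCOVA (the closed form says ρ·Δz = 0.5 × 1.96 × √(2/394) = 0.0698).
ANCOVA's standard error is 0.87 of ANOVA's (√(1 − 0.5²) = 0.866), CSA's
equals ANOVA's exactly at ρ = 0.5, and while ANOVA sits at its nominal
80% power, CSA and ANCOVA — which correct the unfavourable imbalance —
reject far more often.

The full study is four scripts:

```sh
Rscript analysis/01_sample_sizes.R   # 394/64/26 by noncentral-t search
Rscript analysis/02_run_grid.R       # 126 scenarios x 1000 replicates
Rscript analysis/03_tables.R         # bias / design-effect / power tables
Rscript analysis/04_theory_check.R   # simulation vs closed-form algebra
```

Stage 2 writes `results/scenario_summaries.csv` (126 rows, full
precision) and the three wide tables `bias.csv`, `design_effect.csv`,
`power_increment.csv` (rows: comparison × deviate; columns:
`effect{e}_rho{r}`). Stage 3 prints headline cells, e.g.:

```
 bias(ANCOVA-ANOVA) @ effect .2, rho .5, dev -1.96: +0.07 SD
 CSA power @ effect .2, rho .1, dev +1.96: 9.0%
 ANOVA power, same cell: 80.5%
 CSA precision gain over ANOVA @ rho .9: 55.3%
 ANCOVA/ANOVA SE ratio @ rho .9, balanced, effect .2: 0.44
```

The 9% cell is the cautionary tale: change-score analysis under a
favourable-looking baseline imbalance at low correlation has almost no
power to detect a real effect, because it over-corrects — regression to
the mean means only a fraction ρ of the baseline difference carries
forward to follow-up.

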