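# ccmisim

Simulation tools for comparing missing-data strategies in **case-cohort
studies with a binary endpoint**.

In a case-cohort design, an expensive exposure (here: vitamin D
insufficiency at birth, in a birth cohort studying food allergy) is
measured only in a random subcohort plus all cases, so the exposure is
*missing by design* outside that subset. Real studies additionally suffer
ordinary nonresponse (*unintended* missingness) in the exposure and
confounders. Standard practice handles the by-design part with inverse
probability weighting (IPW) and the nonresponse part with multiple
imputation (MI) — but MI could also handle both. This package implements
the full simulation apparatus for comparing five strategies:

| approach | unintended | intended | analysis sample |
|---|---|---|---|
| `CCA` | delete incomplete records | sampling weights | complete subset |
| `IPW-only` | response-probability weights | sampling weights | complete subset |
| `MI-IPW-Sub` | MI (subset sample) | sampling weights | subset |
| `MI-IPW-Int` | MI (full cohort) | sampling weights | subset |
| `MI-only` | MI (full cohort) | MI | full cohort |

The estimand is an adjusted risk ratio, $\exp(\theta_1)$ from the
log-link model

$$\log \Pr(Y=1) = \theta_0 + \theta_1\,\mathrm{VDI} + \theta_2\,\mathrm{Eth}
+ \theta_3\,\mathrm{FamHx} + \theta_4\,\mathrm{PetOwn} +
\theta_5\,\mathrm{AnteVD} + \theta_6 I[\mathrm{NSib}{=}1] + \theta_7
I[\mathrm{NSib}{=}2],$$

fitted by modified Poisson regression (log link, robust sandwich
variance, optionally weighted), with Rubin's-rules pooling across
imputations. The package provides the synthetic cohort generator,
calibrated independent and outcome-dependent missingness mechanisms,
subcohort selection, weight construction, a fully conditional
specification (FCS) MI engine with proper posterior draws, the estimator
and pooling, Monte-Carlo performance evaluation with Monte Carlo standard
errors, the 26-scenario study grid, and a synthetic case-study fixture.

## Worked example

One replication of a large-sample scenario — generate a 10,000-record
cohort, induce calibrated outcome-dependent missingness, select a 10%
subcohort, and compare approaches:

```r
library(ccmisim)

params <- default_generation_params("observed")   # RR = 1.16
config <- calibrate_intercepts(params, missingness_config("dependent", "low"))

cohort <- generate_cohort(params, 10000, seed = 21)
cohort <- induce_unintended(cohort, config, seed = 22)
cohort <- select_subset(cohort, design_config(10000, 0.1), seed = 23)
print(cohort)
#> <cc_cohort> 10000 records, 790 cases, subset 1690
#>   missing: VDI=8513, PetOwn=998, AnteVD=1256

spec <- imputation_spec(m = 10, cycles = 10, seed = 99)
for (a in c("complete-data", "CCA", "IPW-only", "MI-IPW-Sub", "MI-IPW-Int", "MI-only")) {
  td <- tidy_estimate(run_approach(cohort, a, spec = spec))
  cat(sprintf("%-13s logRR %.4f  (robust SE %.4f)\n", a, td$estimate, td$se))
}
#> complete-data logRR 0.1463  (robust SE 0.0686)
#> CCA           logRR 0.2627  (robust SE 0.1129)
#> IPW-only      logRR 0.2556  (robust SE 0.1118)
#> MI-IPW-Sub    logRR 0.1895  (robust SE 0.0986)
#> MI-IPW-Int    logRR 0.2008  (robust SE 0.0970)
#> MI-only       logRR 0.1873  (robust SE 0.0829)
```

The generating value is `log(1.16) = 0.1484`. In this single replication
the complete-data benchmark is close to the truth, the MI-based
approaches are closer than the weighted-only ones and have smaller
standard errors — the pattern the simulation study quantifies over
hundreds of replications via `run_scenario()` / `run_grid()`, which
report relative bias, empirical and model-based SE, and 95% CI coverage,
each with its Monte Carlo standard error.

## Analysis workflow

The numbered scripts under `analysis/` drive the study end to end,
writing tables under `results/`:

1. `01_calibrate_missingness.R` — calibrate all missingness mechanisms
   (targets: 20% any-confounder, 10% exposure, 25% any-incomplete at the
   low level; components doubled at high) and record achieved proportions.
2. `02_simulation.R` — a desk-scale slice of the 26-scenario grid with
   all six approaches; performance summaries to `results/performance.csv`.
3. `03_interaction_true_value.R` — the estimand under analysis-model
   misspecification, by averaging the main-effects fit over many large
   populations generated with an exposure-by-ethnicity interaction.
4. `04_case_study.R` — the synthetic case-study fixture (margins of the
   motivating cohort reproduced exactly), its descriptive table, and all
   five approaches with the known design weight `(0.30)^-1` and `m = 50`.

The methods vignette (`vignettes/methods.Rmd`) documents the generation
models, the calibration procedure, the FCS engine's numerical choices,
and every place where the package had to fix a convention.

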