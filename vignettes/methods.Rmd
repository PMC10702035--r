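---
title: "Missing-data strategies in case-cohort studies: models, mechanisms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-data strategies in case-cohort studies: models, mechanisms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a case-cohort design an expensive exposure is measured only in a random
subcohort plus all cases of a binary outcome. Writing $S_i$ for membership
of that "subset" (subcohort $\cup$ cases), the exposure is *missing by
design* whenever $S_i = 0$ — we call this intended missingness. On top of
it, ordinary nonresponse produces *unintended* missingness in the exposure
and confounders among measured records. The package implements and
compares, by simulation, five ways of analysing such data when the
estimand is an adjusted risk ratio:

| approach | unintended missingness | intended missingness | imputation sample | analysis sample |
|---|---|---|---|---|
| CCA | listwise deletion | sampling weights | — | subset |
| IPW-only | response-probability weights | sampling weights | — | subset |
| MI-IPW-Sub | MI | sampling weights | subset | subset |
| MI-IPW-Int | MI | sampling weights | full cohort | subset |
| MI-only | MI | MI | full cohort | full cohort |

with the complete-data analysis (the fit before any masking) as the
generation benchmark.

## Target model and estimator

The analysis model is log-linear in the outcome probability,

$$\log \Pr(Y_i = 1) = \theta_0 + \theta_1 \mathrm{VDI}_i + \theta_2
\mathrm{Eth}_i + \theta_3 \mathrm{FamHx}_i + \theta_4 \mathrm{PetOwn}_i +
\theta_5 \mathrm{AnteVD}_i + \theta_6 I[\mathrm{NSib}_i = 1] + \theta_7
I[\mathrm{NSib}_i = 2],$$

so $\exp(\theta_1)$ is the adjusted risk ratio for the exposure. It is fit
by modified Poisson regression — a Poisson GLM with log link applied to
the binary outcome — because direct log-binomial fitting is notoriously
non-convergent; the price is that the Poisson likelihood is misspecified
for binary data, which is repaired by a robust (sandwich) variance.
`fit_modified_poisson()` maximizes the weighted Poisson likelihood and
computes an HC0 sandwich with weights treated as fixed: bread = inverse
weighted Fisher information $\left(\sum_i w_i \hat\mu_i x_i
x_i^\top\right)^{-1}$, meat = $\sum_i w_i^2 (y_i - \hat\mu_i)^2 x_i
x_i^\top$. An HC1 small-sample factor is available but not the default;
single-fit intervals are Wald on the log-RR scale.

Sampling weights (`sampling_weights()`) are $w_i = \Pr(S_i = 1 \mid
Y_i)^{-1}$: exactly 1 for cases and $(m_0/n_0)^{-1}$ for non-case
subcohort members, with $m_0$, $n_0$ the non-case counts in subcohort and
cohort. A known design probability can replace the ratio estimate (the
case study uses $1/0.30$). Combined weights (`combined_weights()`)
multiply $w_i$ by the inverse of an estimated complete-record probability
$\Pr(R_i = 1 \mid Y_i, Z_i)$ from a logistic model fit among subset
members, with $Z$ defaulting to the fully observed missingness predictors
(ethnicity and maternal age). The response model is fitted on the subset
because completeness is only at stake there; the predictor set and this
choice are configurable. When no subset record is incomplete the response
model is degenerate and the probabilities are taken as 1, which makes CCA
and IPW-only coincide exactly — a property the tests assert.

Across $m$ imputations, Rubin's rules (`pool_rubin()`) combine estimates:
$\bar\theta$ is the mean, total variance $T = W + (1 + 1/m)B$ with $W$
the mean robust variance and $B$ the between-imputation variance, and the
classic degrees of freedom $(m-1)\{1 + W/((1+1/m)B)\}^2$ (normal quantile
when $B = 0$; the Barnard–Rubin small-sample correction is deliberately
not used, keeping the pooling rule in its standard textbook form).

## The synthetic cohort

The generator (`generate_cohort()`) emulates the structure of a birth
cohort investigating vitamin D insufficiency (VDI) and food allergy:
variables are drawn sequentially — ethnicity (Bernoulli), maternal age
(linear in ethnicity, Gaussian error, raw scale in years), socioeconomic
tertile and number of siblings (multinomial logit), family history, pet
ownership, antenatal vitamin D use and VDI (logistic) — and finally the
outcome from the log-link model above. Because the link is a log
probability, a draw whose linear predictor implies $\Pr(Y=1) \ge 1$ is an
error, never a truncation: truncating would silently change the estimand.

The published source for this design reports its exact generation
coefficients only in supplementary material that is not part of this
package's inputs, so the default parameter sets are **calibrated
approximations, not reproductions**: slope coefficients are plausible
values chosen once on the raw covariate scale, and intercepts were
calibrated by large-sample simulation (2,000,000 records, sequential
one-dimensional root finding; alternating roots for the two multinomial
intercepts) so the marginal summaries match the motivating study's
descriptive table — outcome 7.8%, exposure 45.1%, ethnicity 73.2%, pet
ownership 77.4%, antenatal vitamin D 79.3%, family history 86.9%, sibling
distribution 40.7/35.8/23.5, socioeconomic tertiles 22.3/19.2/58.6,
maternal age 32.1 (SD 4.8) years. Two association settings are built in:

* `observed` — exposure-outcome RR 1.16, weak maternal-age slopes (0.01
  per year) in the three incomplete-variable models;
* `enhanced` — exposure-outcome RR exactly 2, and maternal-age slopes of
  $\log(10)/30 \approx 0.0768$ per year in the VDI, pet-ownership and
  antenatal-vitamin-D models, i.e. roughly a ten-fold change across a
  30-year age range, making maternal age a strong auxiliary.

The interaction variant adds $\theta_{\mathrm{int}} = \log 2$ on
VDI $\times$ ethnicity (intercept recalibrated to keep prevalence at
7.8%), chosen so the main-effects analysis model is misspecified by a
clearly detectable margin. All parameters live in one object
(`default_generation_params()`), round-trip through YAML (reference
copies of the defaults ship under `inst/extdata/`), and are fully
user-overridable.

## Missingness mechanisms and their calibration

Unintended missingness is induced in pet ownership, antenatal vitamin D
use and the exposure, *before* subcohort selection (the ordering matters:
a subset member's exposure can then be missing "by chance"). The stated
study conditions at the **low** level are: 20% of records with at least
one confounder missing, 10% with the exposure missing, and 25% with any
of the three missing; the **high** level doubles the component
percentages.

Under the **dependent** mechanism three sequential logistic models drive
the masks: the pet-ownership mask on outcome, ethnicity and maternal age;
the antenatal mask additionally on the pet mask; the exposure mask
additionally on the indicator that either confounder is masked. The
default "observed" slopes (+0.5 outcome, −0.3 ethnicity, −0.03 per year
of maternal age, on the logit scale) are this package's own plausible
choices; the "enhanced" setting doubles them. The five intercept-like
parameters are calibrated (`calibrate_intercepts()`) against a
200,000-record reference cohort using *exact per-record mask
probabilities* (expectations over the mask randomness, so no Monte Carlo
noise enters the root finding): the pet intercept matches its marginal;
the antenatal intercept and pet-dependence coefficient are solved by
nested root finding for the antenatal marginal and the confounder-mask
union; the exposure intercept and its dependence coefficient likewise for
the exposure marginal and the any-incomplete proportion. Achieved
proportions are stored in the config and checked against a tolerance
(default 0.005); infeasible target combinations (e.g. an any-incomplete
proportion below the exposure component) raise an error.

Under the **independent** mechanism the masks are independent of every
generated variable. One structural point deserves emphasis: the three
compound proportions above *cannot* be met by three mutually independent
per-variable masks — independence would force the any-incomplete
proportion to $1 - 0.8 \times 0.9 = 28\%$, not 25%. Since the study
conditions state all three proportions were achieved, the package gives
the exposure mask a rate that depends on the confounder-mask indicator
only (25% when a confounder is masked, 6.25% otherwise, in closed form),
which meets all three targets exactly while keeping the masks jointly
independent of the data. The component split of the confounder union
(pet 10%, antenatal 12.5% at low) is a package choice, made once.

At the high level only the doubled component targets are stated, so the
any-incomplete proportion is emergent: the dependent mechanism keeps the
exposure-mask dependence coefficient from the low calibration and
re-solves the marginals; the independent mechanism keeps the low-level
conditional-rate ratio.

## The FCS imputation engine

`impute()` implements fully conditional specification with proper
univariate draws. Per imputation: missing cells are initialized by draws
from each variable's observed values; then 10 sweeps (configurable; the
source design is silent on the count, so this is a package default) visit
the incomplete variables in ascending order of missingness count, ties
broken by column order. Each visit refits the variable's model to the
currently completed data — logistic for binary, ordinal logistic
(proportional odds) for ordered three-level, linear for continuous — and
draws parameters from the large-sample normal posterior around the MLE
(the linear model also draws its residual variance from the scaled
inverse-$\chi^2$), then draws the missing values from the model at those
parameters. Exact Bayesian logistic posteriors are deliberately out of
scope; the normal approximation is the standard proper-imputation device.

Every default predictor set contains the outcome. This is the
weight-compatibility device: sampling weights are constant within outcome
strata, so conditioning the (unweighted) imputation models on the outcome
is equivalent to conditioning on the analysis weights, which is what
makes the MI-IPW combinations approximately unbiased under the
outcome-dependent mechanism. The imputation models are main-effects only,
also in the interaction scenarios — that mirrors the misspecification
experiment, where both the analysis and imputation models omit the
generated interaction.

Numerical safeguards: univariate logistic fits use IRLS with
step-halving; on separation or collinearity a ridge penalty of 0.1
(intercept excluded) is applied, and in that penalized fallback the point
estimate is used *without* a posterior draw, because the normal posterior
is invalid in a separated direction — drawn coefficients would routinely
destroy a near-deterministic relationship that the data support. An
ordinal fit that fails (e.g. an absent category) falls back to marginal
draws from the observed values. A variable that is 100% missing is an
error, as is a missing outcome.

The `scope` of imputation implements the approach taxonomy: `"subset"`
exposes only subset records, so design-missing exposure values never
enter the imputation problem; `"full"` exposes the whole cohort, so the
exposure carries intended plus unintended missingness (MI-IPW-Int then
discards non-subset records at analysis; MI-only analyses everyone,
unweighted).

## Performance evaluation and the study grid

`summarize_performance()` computes relative bias (% of the true
$\theta_1$), empirical SE (SD of estimates), model-based SE (root mean
squared reported SE), relative SE error, and 95% CI coverage — each with
its Monte Carlo standard error. Replications with non-converged fits are
excluded and counted (the source design is silent on this; exclusion with
reporting is the package's choice). In the interaction scenarios the true
value is the large-sample limit of the misspecified fit, estimated by
`true_value_misspecified()`; the package default is 50 populations of
200,000 (the full-scale choice of 1,000 × 1,000,000 is configurable) with
the MCSE reported so the user can judge adequacy.

The grid (`scenario_grid()`) crosses three designs — (1,000, 0.3),
(10,000, 0.1), (10,000, 0.2) — with both association settings, both
missingness levels and both mechanisms (24 scenarios), plus two
interaction scenarios (observed association, dependent/low, one per
sample-size design — the source does not specify these conditions, so
they are fixed here once). Replication seeds derive deterministically
from (master seed, scenario id, replication index) via a small integer
hash, so any slice of the grid reproduces identically in any execution
order, and checkpointed runs resume exactly.

### Problem sizes used by the shipped analyses and tests

The full study (26 scenarios × 2,000 replications × $m = 50$) is a
cluster-scale computation. The shipped drivers and tests use desk-scale
slices chosen so that each claim is still decided by a comfortable
Monte-Carlo margin: the large-sample bias/coverage experiment uses 500
replications of $n = 10{,}000$ at selection 0.1 with $m = 10$ (bias MCSE
≈ 3% of the true log-RR; coverage MCSE ≈ 1%); the outcome-dependent bias
pattern uses 150 replications under the enhanced/high setting, where the
complete-case bias is an order of magnitude larger than its MCSE; margin
and calibration checks use single cohorts of 100,000–200,000; the
generation benchmark fits one population of 1,000,000.

## The synthetic case-study fixture

`make_fixture()` constructs a 786-record cohort reproducing the
motivating study's descriptive table margins exactly where counts are
printed: 61 cases, subset 325, exposure observed for 246 subset records
(79 missing by chance) and 47 non-subset records (reconciling the printed
414/786 intended-missingness figure with the subset size), plus
per-variable present/missing counts in both strata and maternal-age
moments. Values are shuffled within the subset and non-subset strata, so
the *joint* distribution is synthetic — only margins, the missingness
structure and the design are real. Consequently the case-study risk
ratios are not estimates of the real association; what transfers is the
structural comparison (every MI-based interval narrower than the CCA and
IPW-only intervals). Two printed percentage cells (antenatal subset
missingness 21.9, high-tertile share 58.6) are internally inconsistent
with the printed counts under any one rounding convention; the tabulator
(`summarize_table1()`, half-up rounding to one decimal, percentages among
observed values) stays faithful to the counts and reports 21.8 and 58.5.

`run_case_study()` applies all five approaches with the known design
weight $(0.30)^{-1}$, imputing every incomplete variable with its
type-appropriate model — including the socioeconomic tertile as *ordered*
(ordinal logistic) even though generation treats it as unordered
multinomial, mirroring the asymmetry of the original implementation. The
response model for IPW-only uses the outcome and maternal age (ethnicity,
the other designated missingness predictor, is itself incomplete in the
fixture and so cannot enter).

## Known limitations

* The generation parameters approximate published margins, not the real
  joint distribution; agreement of simulation results with the published
  figures is therefore expected only for robust qualitative patterns and
  bounded quantities, not cell-by-cell.
* Substantive-model-compatible FCS, weighted imputation models,
  weights-as-covariate imputation, missing outcome data, and time-to-event
  analogues are all out of scope by design.
* The sandwich variance treats weights as fixed; no stabilization,
  trimming or calibration of weights is provided.
* Parallel execution is a seed contract (replications are independent
  given derived seeds), not a scheduler: `run_grid()` itself is serial.
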