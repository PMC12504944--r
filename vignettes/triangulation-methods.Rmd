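---
title: "Triangulating causal effect estimators: models, assumptions and design choices"
author: "causaltri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating causal effect estimators: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causaltri)
```

## The problem

Comparative-effectiveness questions with observational data — for example,
whether one second-line diabetes drug causes more genital infections than
another — cannot rely on randomization to balance treatment groups. Every
standard answer rests on an identification assumption that the data cannot
verify: outcome regression assumes no unmeasured confounding (NUC),
instrumental-variable (IV) methods assume the instrument affects the outcome
only through treatment (the exclusion restriction), and two-period
difference-in-difference (DiD) regression assumes the prior-period outcome
does not itself drive the treatment decision and that unmeasured confounding
is stable over time. `causaltri` fits all of these estimators — plus
prior-outcome-augmented (POA) IV variants that remain valid when both the
exclusion restriction and the prior-outcome assumption fail — on the same
risk-difference scale, and provides a heterogeneity statistic to judge
whether their answers are statistically dissimilar once their correlation is
taken into account.

The estimand throughout is the average causal risk difference

$$\beta = E[Y_1(X{=}1)] - E[Y_1(X{=}0)],$$

for a binary treatment $X$ and binary study-period outcome $Y_1$. The risk
difference is collapsible, so estimators with different adjustment sets
target the same quantity — a prerequisite for comparing them at all.

## The data world and its generator

`simulate_dataset()` generates the two-period world the estimators are
designed for: patients nested in provider clusters; a binary cluster-level
instrument $Z$ (provider preference, prevalence 0.5); correlated continuous
measured confounders $W_0, W_1$ per period ($\rho = 0.5$, unit variance); a
standard-normal unmeasured confounder $U$; binary outcomes $Y_0$ (prior
period) and $Y_1$ (study period); and both potential study outcomes.
Treatment follows a logistic model in $Z$, $W_1$ and — depending on the
scenario's violation flags — $Y_0$, $U$ and the interaction $Y_0 Z$. Both
outcome models are **linear on the probability scale** with the treatment
effect added as $+\beta x$ and probabilities clamped to
$[\varepsilon, 1-\varepsilon]$ ($\varepsilon = 0.01$). This choice makes the
ground-truth estimand exactly the configured $\beta$ (default 0.1) rather
than a derived quantity of log-odds parameters; the cost is a small
shrinkage of the truth when clamping occurs, which is why `true_effect()`
computes the realized Monte-Carlo truth (about 0.099 under the defaults) and
why the generator treats clamping of more than 1% of patients as a hard
calibration error.

Eleven named scenarios switch the assumption-violating paths on and off:
`base1`–`base8` cross the NUC, DiD1 ($Y_0 \to X$) and IV2 ($Z \to Y_1$)
violations (with $U \to Y_0$ active whenever NUC is violated, so that
unmeasured confounding is present in both periods), and `poa1`–`poa3` add
the $Y_0 Z \to X$ relevance path for the augmented instrument. In `poa1` and
`poa2` the prior outcome is deliberately left unconfounded — the validity
condition of the POA estimators — while `poa3` repeats the
everything-violated world with a confounded prior outcome, where the POA
estimators are themselves mildly biased but far less so than any comparator.

**Coefficients are calibrated, not transcribed.** The numeric defaults in
`default_dgp_coefficients()` were fixed once, against three requirements:
a strong preference instrument (first-stage F far above the conventional
threshold of 10 at $n = 5000$), event prevalence in the low-double-digit
range, and violation magnitudes large enough that each broken estimator is
unambiguously biased at 500 Monte-Carlo replicates (DiD bias near $-0.2$
under a DiD1 violation, IV/CF bias near $+0.15$ under an IV2 violation, CaT
bias near $+0.03$ under unmeasured confounding). The `poa*` scenarios
override three entries (`y0_int = 0.25`, `x_y0 = 0.5`, `x_y0z = 1.8`):
the augmented instrument $Y_0 Z$ only carries information through patients
with $Y_0 = 1$, so its strength requires a more prevalent prior outcome and
treatment probabilities away from saturation. With these values the
interaction F-statistic is comfortably large and the weak-instrument
pathologies (heavy-tailed sampling distributions, undercoverage) that appear
below F ≈ 30 are avoided. What the generator does **not** emulate: unequal
cluster sizes, provider random effects beyond the preference instrument,
time-varying unmeasured confounding, treatment-effect heterogeneity, and
time-to-event outcomes. Passing tests therefore demonstrate internal
validity of the estimators under this world, not performance on any real
cohort.

## The estimators

All estimators report an average marginal effect (AME): the difference in
average predicted outcome probability with the treatment term fixed at 1
versus 0, averaged over the observed covariate distribution. Standard
errors are delta-method, propagated through the final-stage coefficient
covariance.

- **CaT** (`fit_cat`): logistic $Y_1 \sim X + W_1$; AME of $X$. With
  `include_z` / `include_y0` the instrument or prior outcome join the
  adjustment set.
- **PSM** (`fit_psm`): logistic propensity model, greedy 1–1
  nearest-neighbour matching without replacement (seeded random order over
  treated patients, distance ties to the lowest patient id, no caliper by
  default), then the CaT fit on the matched subset. Diagnostics carry the
  matched fraction and pre/post standardized mean differences.
- **IV** (`fit_iv`): first stage logistic $X \sim Z + W_1$; the fitted
  probability $\hat X$ replaces $X$ in the second stage. The default second
  stage is **linear** with HC0 robust standard errors, so the $\hat X$
  coefficient is itself the risk difference; a logistic second stage (AME of
  $\hat X$ moved 0 to 1) is available via `second_stage`. The linear default
  was chosen because the second-stage conditional mean
  $E[Y_1 \mid \hat X, W_1]$ is exactly linear under the probability-scale
  outcome model, whereas the logistic AME requires extrapolating $\hat X$ to
  the endpoints of its support.
- **CF** (`fit_cf`): same first stage; the residual
  $\hat\Delta = X - \hat X$ and its interaction with $Z$ enter a logistic
  outcome model alongside the observed $X$ — the residual absorbs the
  unmeasured-confounding signal; AME of $X$.
- **DiD** (`fit_did`): single logistic regression on the 2n-row stacked data,
  $Y^* \sim P^* + X^* + P^{*}X^* + W^* + W^{*}P^*$ (+$Z$ + $ZP^*$ on
  request). Because the interaction coefficient of a logistic model is not a
  risk difference, the reported effect is the difference-in-AME: the
  study-period treatment contrast in average predicted probability minus the
  prior-period contrast, each patient evaluated with its period-appropriate
  confounder. In the linear family this reduces exactly to the classical
  four-mean plug-in.
- **POA-IV / POA-CF** (`fit_poa_iv`, `fit_poa_cf`): the first stage adds
  $Y_0$ and $Y_0 Z$, with the interaction serving as the instrument; the
  second stage controls $Z$ and $Y_0$ directly, so direct effects of either
  on $Y_1$ are permitted. Diagnostics carry the F-statistics of both $Z$
  and $Y_0 Z$; F below 10 for the operative instrument triggers a
  weak-instrument warning, not an error.

Two-stage standard errors deliberately ignore first-stage estimation noise,
matching the common margins-based workflow; the patient-level bootstrap
(`bootstrap_covariance`) is the supported alternative and is what the
dissimilarity machinery uses anyway. A package-level property test confirms
the two agree within 15% where both are valid.

## The dissimilarity statistic

For a set $e$ of estimates with bootstrap covariance $\hat\Sigma_e$,

$$Q_e = (\hat\beta_e - \hat\beta_{IVW,e})\, \hat\Sigma_e^{-1}
        (\hat\beta_e - \hat\beta_{IVW,e})^\top,$$

with the inverse-variance-weighted pool built from the diagonal of
$\hat\Sigma_e$ (one covariance object drives both the weights and the
quadratic form, keeping the statistic internally consistent). Under the
null that all estimates target the same quantity, $Q_e$ is asymptotically
chi-square with $|e| - 1$ degrees of freedom; no small-sample correction is
applied. Correlation matters in both directions: strongly correlated
estimators (CaT and PSM, say) can be declared dissimilar even when their
values nearly coincide, because their null spread is tiny.

Numerical policy: the covariance must be symmetric with positive diagonal
and condition number below $10^{10}$; beyond that the statistic is unstable
and the function errors rather than silently substituting a pseudo-inverse
(the typical trigger is including two near-duplicate methods — drop one
instead). Bootstrap resamples on which any estimator fails to converge are
dropped and counted, with a hard error above 10% failures; resampling is by
patient by default, with a provider-level cluster bootstrap available since
the instrument is cluster-constant.

## Monte-Carlo studies

`run_simulation_study()` aggregates bias, empirical SE, MSE, coverage and
type-1-error with the standard Monte-Carlo standard errors (bias MCSE
$= \widehat{SE}_{emp}/\sqrt{R}$, empirical-SE MCSE
$= \widehat{SE}_{emp}/\sqrt{2(R-1)}$, proportion MCSE
$= \sqrt{p(1-p)/R}$), so every summary cell satisfies
$MSE = bias^2 + \widehat{SE}_{emp}^2 (R-1)/R$ identically. Type-1-error
runs re-simulate with $\beta = 0$ rather than recycling the effect-present
draws. Scenario-driven adjustment is automatic: when a scenario violates
the exclusion restriction, $Z$ joins the CaT and DiD models (as main effect
and period interaction respectively); when the prior outcome affects the
study outcome, $Y_0$ joins every outcome model (`auto_adjust = FALSE`
disables both for ablation). Seeds follow a documented block scheme: one
master seed yields per-replicate sub-seeds drawn in a single block, so any
replicate is individually reproducible and the whole study is
byte-reproducible.

Problem sizes used by the package's own operating-characteristic tests —
chosen so the Monte-Carlo error of each asserted band is small relative to
the band — are: 1000 replicates for the all-assumptions-hold coverage and
size checks, 500 replicates for the bias-pattern matrices, and 100
replicates × 200 bootstrap resamples at $n = 2000$ for the rejection-rate
studies of $Q_e$.

## The preference instrument

`build_preference_iv()` encodes the classic proxy for provider preference:
each patient's instrument is the same provider's most recent previous
prescription choice, with the first patient of every provider excluded for
lack of history. A `window` argument generalizes to the majority of the
last $k$ prescriptions (ties resolve to the most recent); the default
window of 1 is the exact most-recent-prescription rule.

## Degenerate inputs and numerical choices

Logistic fits use a Newton IRLS (deviance tolerance $10^{-8}$, 100
iterations, step-halving) with a `glm.fit` fallback; coefficients beyond
±15 on the logit scale are reported as suspected separation with the
offending term named. A DiD period in which all outcomes are identical is a
hard error, as is a propensity-matched set that comes out empty, an
estimator arm with fewer than two patients, or a simulated scenario whose
probability models clamp more than 1% of patients. Validation errors carry
a dedicated condition class, which the command-line interface maps to exit
status 2.

## Known limitations

The linear-probability outcome models mean the logistic estimators are
technically misspecified; the induced AME bias is far below the Monte-Carlo
resolution of the shipped studies but would matter for extreme prevalence.
The generator's coefficients are a calibrated design rather than estimates
from any real cohort, so the magnitudes of bias under assumption violations
characterize this simulated world; only their signs and ordering should be
read as general.
The framework assumes treatment-effect homogeneity across instrument
levels, two periods only, and equal-size clusters; time-to-event outcomes
and hierarchical multi-set testing with family-wise error control are out
of scope.
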