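---
title: "Census-calibrated multiple imputation for partially recorded ethnicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Census-calibrated multiple imputation for partially recorded ethnicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmi)
```

## The problem

Primary-care electronic health records are an attractive source for
estimating how the prevalence of type 2 diabetes differs between ethnic
groups: they are large, population-based and routinely collected. Their
weakness is that ethnicity is recorded opportunistically, so a substantial
fraction of individuals — roughly a quarter in the London cohort this
package's defaults emulate — have no usable ethnicity record, and the
*chance of being recorded differs by ethnic group itself*. Complete records
over-represent the White group relative to the census population. Because
the missingness probability depends on the unobserved value even after
conditioning on everything observed, this is missing not at random (MNAR),
and neither complete-record analysis nor standard (MAR) multiple imputation
can recover the population distribution of ethnicity from the data alone.

The way out is external information: the UK census publishes the
population-level distribution of ethnicity for the catchment area. The
calibrated-δ adjustment method anchors the imputation model to that
distribution.

## The model

The cross-sectional analysis model is an ordinary logistic regression for
the prevalent type 2 diabetes indicator \(Y\):

\[
\operatorname{logit} \Pr(Y_i = 1) =
  \alpha + \beta_{e(i)} + \gamma_{s(i)} + \eta_{a(i)} + \zeta_{d(i)},
\]

with categorical contrasts for ethnicity (reference White), sex (reference
men), 10-year age group (reference 40–49) and Townsend deprivation quintile
(reference quintile 1, least deprived). Exponentiated coefficients are
adjusted odds ratios.

Missing ethnicity is imputed from a multinomial logistic model fitted on
complete records, with the outcome and all analysis covariates as
predictors (the congenial minimum for imputation):

\[
\Pr(E_i = k \mid y_i, x_i) =
  \frac{\exp(x_i^\top \beta_k)}{\sum_l \exp(x_i^\top \beta_l)},
  \qquad \beta_{\text{ref}} \equiv 0 .
\]

A MAR imputation drawn from this model reproduces the complete-record
ethnicity distribution, which is exactly what we do not want. The
calibrated-δ adjustment adds a category-specific offset \(\delta_k\)
(reference fixed at 0) to every linear predictor and solves, for each
category \(k\),

\[
\frac{n^{\text{obs}}_k + \sum_{i \in \text{missing}} p_{ik}(\beta, \delta)}{N}
  = \pi_k ,
\]

where \(\pi_k\) is the census proportion. The solution makes the *expected*
combined (observed + imputed) distribution equal the census distribution.
The left-hand side is strictly increasing in \(\delta_k\) and the equations
sum to an identity, so the \(K-1\) free offsets have a unique solution on
the feasible set. `calibrate_delta()` solves them by Newton–Raphson with
the analytic Jacobian, starting at \(\delta = 0\), with step-halving on
overshoot; convergence is declared when the max-norm residual on the
proportion scale falls below `1e-8` (at most 100 iterations). Feasibility —
\(n^{\text{obs}}_k < N\pi_k < n^{\text{obs}}_k + n^{\text{mis}}\) for every
category, with a `1e-9` margin — is checked before solving and a violation
reports the achievable interval per category.

Imputation is *proper*: for each of the \(M\) imputations a parameter
vector is drawn from the asymptotic normal approximation to the posterior
(MLE and inverse observed information; a bootstrap is a possible extension
but the normal approximation is standard and cheap), the offsets are
re-solved for that draw, and missing entries are sampled from the resulting
categorical distributions. Re-calibrating per draw rather than once at the
MLE keeps every imputed dataset census-consistent in expectation; the two
choices coincide asymptotically, and per-draw calibration is the
conservative one, so it is the package default.

Completed-data fits are pooled with Rubin's rules:
\(\bar Q = M^{-1}\sum_m \hat Q_m\),
\(T = W + (1 + 1/M)B\), with the Barnard–Rubin small-sample degrees of
freedom; when the between-imputation variance is exactly zero (fully
observed stratifiers, or identical fits) the complete-data degrees of
freedom are used. Crude prevalences are pooled on the logit scale with the
proportion clamped to \([0.5/n,\, 1-0.5/n]\) before transforming, which
guards empty and saturated margins; for fully observed stratifiers this
reduces to the direct sample proportion exactly.

## Case ascertainment

Coded event streams are reduced to a prevalent-case indicator by a
two-of-three rule: an individual is ascertained as diabetic when records of
at least two **distinct** types are present among (i) a diagnostic code,
(ii) supporting evidence such as retinopathy screening, and (iii) a
prescribed treatment. Two records of the same type do not qualify — the
rule demands corroborating evidence, and we read "at least two records" as
two distinct kinds; this is a deliberate reading, recorded here because the
alternative (any two records) is defensible too. The diagnosis date is the
earliest record of any of the three types, even when that earliest record
belongs to a type observed only once. A case is *prevalent* when its
diagnosis date falls on or before the index date, inclusive. Eligibility
uses deterministic calendar-month arithmetic: registered on or before the
index date minus twelve months, active at the index date, and complete on
age, sex and deprivation.

## What the generator emulates — and what it does not

`simulation_config()` defaults describe a synthetic London-like cohort:

* **Demographic marginals** follow the published THIN London 2013
  cross-section: sex 49/51, nine 10-year age bands peaking at 30–49, and
  Townsend quintiles skewed towards deprivation (see
  `thin_london_2013_counts()`).
* **Census targets** default to 60% White, 18% Asian, 13% Black, 9%
  Mixed/Other. These are *illustrative* of an ethnically diverse UK urban
  population — the official census figures for a real catchment must be
  supplied for any real analysis.
* **Outcome effects** default to the published adjusted odds ratios
  (e.g. Asian vs White 2.36, Black vs White 1.65, women vs men 0.77, a
  steep age gradient, deprivation quintile 5 vs 1 of 1.86), with the
  intercept root-found so the overall prevalence is 5.5%.
* **Missingness** is MNAR on ethnicity: missingness log-odds are
  `base + offset[k]`, the non-White offsets default to +1, and the base is
  root-found so overall missingness is 23.4%. This makes complete records
  over-represent the White group, the qualitative pattern observed in
  primary-care data.
* Covariates are sampled independently of each other and (by default) of
  ethnicity, because the published tables report marginals only; an
  association knob (`ethnicity_dep_assoc`) can tilt ethnicity across
  deprivation quintiles if a joint structure is wanted.

The generator does *not* emulate: practice-level clustering, Read-code
detail or free text, the 16-level ONS ethnicity classification,
undiagnosed diabetes, or missingness in anything other than ethnicity.
Passing tests on this generator therefore demonstrate the estimator's
internal correctness under its stated assumptions, not robustness to the
many further complications of real records.

One property of the default scenario deserves emphasis. Because the
default missingness depends *only on ethnicity itself* — a covariate of
the analysis model — complete-record logistic regression remains
consistent for the odds ratios (selection on covariates does not bias a
correctly specified conditional model), although it is badly biased for
the ethnicity distribution and for any marginal quantity. The calibrated
method's advantage under this clean mechanism shows up in the
census-consistency of the imputed data and in marginal summaries, while
adjusted odds ratios from all reasonable strategies sit close together.
Larger separations between strategies, as seen in real data, require
recording processes that also depend on the outcome or on unmodelled
factors. We keep the clean mechanism as the default because it is the one
the method's assumptions describe exactly.

## Numerical choices

* Root-finding for the outcome intercept and the missingness base uses
  `uniroot` on generous brackets with tolerance far below the `1e-6`
  guarantee.
* The multinomial fit is `nnet::multinom`; its asymptotic covariance is
  computed analytically from the observed information (block form
  \(X^\top \mathrm{diag}(p_k(\delta_{kl}-p_l)) X\)), which is both faster
  and more accurate than a numeric Hessian. The agreement is tested.
* Softmax evaluations subtract the row maximum before exponentiating, so
  arbitrarily large offsets (e.g. the δ → ∞ limit used in tests) cannot
  overflow.
* Zero-case covariate cells: at a few tens of thousands of individuals the
  youngest age groups (adjusted OR 0.01 at 5.5% overall prevalence) are
  regularly empty of cases, and their contrasts diverge. Model fits
  therefore accept an optional ridge penalty (`ridge`; weight decay for
  the multinomial fit, an unpenalised-intercept quadratic penalty for the
  logistic fit). Simulation studies in this package use `ridge = 0.1`,
  which shifts well-populated contrasts by well under 1% while pinning
  divergent ones; the default for data analysis remains the plain MLE,
  which errors loudly on separation rather than silently shrinking.
* Determinism: `simulate_cohort()` seeds once from the config seed, and
  every stochastic function accepts an explicit seed; identical
  configurations give byte-identical cohorts, and standard (uncalibrated)
  MI is the calibrated code path with offsets forced to zero, bit-for-bit
  under a shared seed.

## Study sizes used by the test-suite experiments

The packaged experiments run at sizes chosen to make Monte-Carlo error
small relative to the effects being measured while staying comfortable on
a single CPU: the census-calibration property is checked on one cohort of
100,000; parameter recovery on one cohort of 50,000 with \(M = 10\); and
the strategy comparison on 200 replicates of 20,000 with \(M = 5\),
reporting mean bias, empirical coverage and the between-strategy gaps of
the ethnicity contrasts.

## Known limitations

* The method handles a single incomplete categorical variable; there is no
  chained-equations engine for multiple incomplete variables.
* Calibration requires feasible targets: a census proportion below the
  observed share (or above observed-plus-missing) of a category cannot be
  reached by any offset, and the package refuses rather than approximates.
* The asymptotic-normal parameter draws understate uncertainty in tiny
  complete-record cells.
* Crude-prevalence intervals under MI use logit-scale Rubin pooling with a
  boundary clamp; other defensible interval constructions exist.

## A minimal session

```{r example, eval = FALSE}
cfg <- simulation_config(50000, seed = 1)
sim <- simulate_cohort(cfg)
eligible <- apply_eligibility(sim$cohort, eligibility_rule(cfg$index_date))
cases <- ascertain_cohort(sim$events, cfg$index_date, ids = eligible$id)
eligible$t2d <- as.integer(cases$is_prevalent_at_index)

mi <- run_mi(eligible, "calibrated", M = 10, targets = cfg$census)
fits <- lapply(seq_len(mi$M), function(m)
  fit_logistic(completed_cohort(eligible, mi, m), ridge = 0.1))
pool_rubin(fits)
crude_prevalence(mi, eligible)
```
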