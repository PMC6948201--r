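# calmi — census-calibrated multiple imputation for ethnicity in primary-care cohorts

Primary-care electronic health records are the natural place to estimate
how type 2 diabetes prevalence differs between ethnic groups, but
ethnicity is incompletely recorded and the chance of being recorded
differs *by ethnic group itself*: complete records over-represent the
White group relative to the census population. That is missing not at
random (MNAR), and neither complete-record analysis nor standard multiple
imputation can fix it from the data alone.

`calmi` implements the calibrated-δ adjustment: missing ethnicity is
imputed from a multinomial logistic model (fitted on complete records,
with the analysis outcome and covariates as predictors) whose linear
predictors receive category-specific offsets δ solved so that the
combined observed-plus-imputed distribution of ethnicity equals an
external census distribution,

```
(n_obs_k + Σ_{i∈missing} p_ik(β, δ)) / N = π_k ,   δ_reference = 0 ,
```

with `p_ik(β, δ) = exp(x_iᵀβ_k + δ_k) / Σ_l exp(x_iᵀβ_l + δ_l)`. The
offsets are re-solved for every posterior parameter draw (proper MI), each
completed dataset is analysed with an adjusted logistic regression of the
diabetes indicator on ethnicity, sex, 10-year age group and Townsend
deprivation quintile, and estimates are pooled with Rubin's rules
(Barnard–Rubin degrees of freedom).

The package also provides:

* a synthetic cohort generator with realistic demographic marginals,
  published adjusted odds ratios as generating effects, 5.5% outcome
  prevalence, and a tunable MNAR ethnicity-missingness mechanism;
* eligibility filtering (active at the index date, ≥ 12 months registered,
  complete age/sex/deprivation) and the two-of-three coded-record
  case-ascertainment rule with first-record diagnosis dating;
* crude prevalence tables pooled on the logit scale, a four-strategy
  comparison (calibrated MI, standard MI, single imputation with White,
  complete records), and a repeated-simulation study harness.

## Worked example

```r
library(calmi)
out <- run_pipeline(list(n_individuals = 30000, seed = 1), "demo",
                    m_imputations = 10, ridge = 0.1)
t2 <- read.csv(out$table2)
t2[t2$variable == "ethnicity", ]
```

The pipeline logs its stages,

```
simulate: n = 30000, seed = 1
eligibility: retained 30000 (excluded: not_active_at_index=0, registered_under_minimum=0, incomplete_covariates=0)
ascertain: 1629 prevalent cases (5.43%)
impute: calibrated-delta MI, M = 10
done: 8 files in demo
```

and the ethnicity block of the resulting prevalence/odds-ratio table reads

```
   variable       level     n prevalence conf.low conf.high adjusted_or or_conf.low or_conf.high
  ethnicity       White 18003       4.35     4.04      4.67        1.00          NA           NA
  ethnicity       Asian  5411       8.67     7.86      9.55        2.31       1.996         2.68
  ethnicity       Black  3893       6.48     5.65      7.41        1.66       1.400         1.96
  ethnicity Mixed/Other  2693       4.62     3.57      5.95        1.10       0.818         1.48
```

Each row shows the pooled crude prevalence (%) of ascertained type 2
diabetes within the ethnic group, its 95% CI, and the adjusted odds ratio
versus the White reference. The cohort was generated with true ORs of
2.36 (Asian), 1.65 (Black) and 1.17 (Mixed/Other), so the fitted values
sit comfortably inside their intervals; the column `n` is the average
group size across imputations, and the imputed ethnicity distribution in
every completed dataset matches the configured census targets (60/18/13/9%).

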