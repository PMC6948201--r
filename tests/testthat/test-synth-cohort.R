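test_that("generated covariate marginals match the configured proportions", {
  cfg <- simulation_config(100000, seed = 101)
  co <- generate_covariates(cfg, seed = 101)

  # chi-square goodness of fit against each configured marginal
  gof <- function(x, probs) {
    suppressWarnings(stats::chisq.test(table(x), p = probs)$p.value)
  }
  expect_gt(gof(co$sex, cfg$sex_marginal), 0.01)
  expect_gt(gof(co$age_group, cfg$age_marginal), 0.01)
  expect_gt(gof(co$deprivation, cfg$deprivation_marginal), 0.01)
  expect_gt(gof(co$ethnicity, cfg$census$proportions), 0.01)

  # at the published cohort size, the generated women count sits within
  # 3 binomial SDs of n * 0.51, just as the published count does within 2
  n_pub <- 404318L
  sd_w <- sqrt(n_pub * 0.49 * 0.51)
  expect_lt(abs(206017 - n_pub * 0.51), 2 * sd_w)
  co_big <- generate_covariates(simulation_config(n_pub, seed = 7), seed = 7)
  expect_lt(abs(sum(co_big$sex == "Women") - n_pub * 0.51), 3 * sd_w)
})

test_that("degenerate marginals concentrate all mass as configured", {
  age_point <- setNames(c(0, 0, 0, 0, 1, 0, 0, 0, 0),
                        names(calmi:::.default_age_marginal()))
  cfg <- simulation_config(500, age_marginal = age_point,
                           census = census_targets(c(White = 1, Asian = 0,
                                                     Black = 0, `Mixed/Other` = 0)),
                           missingness = mnar_mechanism(
                             c(White = 0.2, Asian = 0.2, Black = 0.2,
                               `Mixed/Other` = 0.2)),
                           seed = 5)
  co <- generate_covariates(cfg, seed = 5)
  expect_true(all(co$age_group == "40-49"))
  expect_true(all(co$ethnicity == "White"))
})

test_that("invalid configuration proportions are rejected by name", {
  expect_error(simulation_config(100, sex_marginal = c(Men = 0.6, Women = 0.5)),
               "sex_marginal")
  expect_error(simulation_config(100,
                                 age_marginal = setNames(rep(1 / 8, 9),
                                                         names(calmi:::.default_age_marginal()))),
               "age_marginal")
  expect_error(census_targets(c(A = 0.5, B = 0.6)), "sum to 1")
  expect_error(simulation_config(100, target_overall_prevalence = 1.2),
               "prevalence")
  expect_error(mnar_mechanism(c(White = -0.1, Asian = 0.2)), "\\[0, 1\\]")
})

test_that("simulation is deterministic given the config seed", {
  cfg <- simulation_config(2000, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$events, b$events)
  c2 <- simulate_cohort(simulation_config(2000, seed = 78))
  expect_false(identical(a$cohort$ethnicity, c2$cohort$ethnicity))
})

test_that("outcome intercept is root-found to hit the target prevalence", {
  null_effects <- lapply(default_true_log_odds(), function(x) x * 0)
  cfg <- simulation_config(200000, true_log_odds = null_effects,
                           target_overall_prevalence = 0.055, seed = 13)
  co <- assign_outcome(generate_covariates(cfg, seed = 13), cfg)
  # with all log-ORs zero the solved intercept is exactly logit(target)
  expect_equal(attr(co, "outcome_intercept"), qlogis(0.055), tolerance = 1e-7)
  p_hat <- mean(co$t2d)
  expect_lt(abs(p_hat - 0.055), 3 * sqrt(0.055 * 0.945 / nrow(co)))
})

test_that("unreachable target prevalence errors with the achievable range", {
  cfg <- simulation_config(100, seed = 1)
  expect_error(simulation_config(100, target_overall_prevalence = 0),
               "prevalence")
  co <- generate_covariates(cfg, seed = 1)
  cfg2 <- cfg
  cfg2$target_overall_prevalence <- 1e-30  # unreachable with finite intercept
  expect_error(assign_outcome(co, cfg2), "achievable range")
})

test_that("generating odds ratios are recovered by refitting the generating model", {
  cfg <- simulation_config(150000, seed = 313)
  co <- assign_outcome(generate_covariates(cfg, seed = 313), cfg)
  fit <- fit_logistic(co, ridge = 0.1)
  for (term_truth in list(c("ethnicityAsian", log(2.36)),
                          c("ethnicityBlack", log(1.65)),
                          c("sexWomen", log(0.77)),
                          c("deprivationQ5", log(1.86)))) {
    i <- match(term_truth[1], names(fit$coefficients))
    se <- sqrt(fit$vcov[i, i])
    expect_lt(abs(fit$coefficients[i] - as.numeric(term_truth[2])), 3 * se)
  }
})

test_that("MNAR missingness hits the configured fraction and tilts complete records White", {
  cfg <- simulation_config(100000, seed = 29)
  co <- assign_outcome(generate_covariates(cfg, seed = 29), cfg)
  com <- apply_mnar_missingness(co, cfg$missingness)
  frac <- mean(is.na(com$ethnicity))
  expect_lt(abs(frac - 0.234), 3 * sqrt(0.234 * 0.766 / nrow(com)) + 0.003)
  cr_white <- mean(com$ethnicity[!is.na(com$ethnicity)] == "White")
  expect_gt(cr_white, cfg$census$proportions[1])
  # the pre-missingness truth is preserved for bias evaluation
  expect_identical(com$ethnicity_true, co$ethnicity)
  expect_identical(com$ethnicity[!is.na(com$ethnicity)],
                   com$ethnicity_true[!is.na(com$ethnicity)])
})

test_that("edge missingness mechanisms behave as specified", {
  cfg <- simulation_config(5000, seed = 31)
  co <- assign_outcome(generate_covariates(cfg, seed = 31), cfg)
  none <- apply_mnar_missingness(co, mnar_mechanism(
    setNames(rep(0, 4), cfg$census$labels)))
  expect_identical(none$ethnicity, co$ethnicity)
  only_white <- apply_mnar_missingness(co, mnar_mechanism(
    c(White = 0, Asian = 1, Black = 1, `Mixed/Other` = 1)))
  kept <- only_white$ethnicity[!is.na(only_white$ethnicity)]
  expect_true(all(kept == "White"))
})

test_that("equal per-category probabilities reduce to MCAR", {
  cfg <- simulation_config(100000, seed = 41)
  co <- assign_outcome(generate_covariates(cfg, seed = 41), cfg)
  mcar <- apply_mnar_missingness(co, mnar_mechanism(
    setNames(rep(0.234, 4), cfg$census$labels)))
  cc <- mcar$ethnicity[!is.na(mcar$ethnicity)]
  p <- suppressWarnings(stats::chisq.test(table(cc),
                                          p = cfg$census$proportions)$p.value)
  expect_gt(p, 0.01)
})

test_that("event streams give every case two distinct types and decoys one", {
  cfg <- simulation_config(20000, seed = 53, decoy_fraction = 0.1)
  sim <- simulate_cohort(cfg)
  ev <- sim$events
  expect_true(all(ev$event_date <= cfg$index_date))
  ntypes <- tapply(ev$event_type, ev$individual_id,
                   function(x) length(unique(x)))
  pos_ids <- sim$cohort$id[sim$cohort$t2d == 1L]
  expect_true(all(ntypes[as.character(pos_ids)] >= 2L))
  decoy_ids <- setdiff(unique(ev$individual_id), pos_ids)
  expect_true(all(ntypes[as.character(decoy_ids)] == 1L))
  n_neg <- sum(sim$cohort$t2d == 0L)
  expect_lt(abs(length(decoy_ids) - 0.1 * n_neg),
            3 * sqrt(n_neg * 0.1 * 0.9))
  # the case finder ascertains exactly the outcome-positive individuals
  asc <- ascertain_cohort(ev, cfg$index_date, ids = sim$cohort$id)
  expect_identical(asc$is_prevalent_at_index, sim$cohort$t2d == 1L)
})

test_that("an empty cohort yields an empty event stream", {
  cfg <- simulation_config(10, seed = 3)
  co <- assign_outcome(generate_covariates(cfg, seed = 3), cfg)
  expect_identical(nrow(generate_event_stream(co[0, ], cfg)), 0L)
})
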