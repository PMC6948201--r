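test_that("multinomial fit reproduces observed category proportions through its intercept score equations", {
  co <- make_cohort(4000, seed = 61)
  mod <- fit_imputation_model(co)
  cc <- co[!is.na(co$ethnicity), ]
  X <- model.matrix(~ t2d + sex + age_group + deprivation, cc)
  eta <- cbind(0, X %*% t(mod$coef))
  P <- exp(eta - apply(eta, 1, max)); P <- P / rowSums(P)
  # at the MLE the expected per-category counts equal the observed counts
  expect_equal(unname(colSums(P)),
               unname(as.numeric(table(factor(cc$ethnicity,
                                              levels = mod$categories)))),
               tolerance = 1e-4)
})

test_that("imputation-model coefficients are recovered from data generated by a known multinomial model", {
  set.seed(71)
  n <- 100000
  y <- rbinom(n, 1, 0.3)
  x <- rbinom(n, 1, 0.5)
  # true multinomial logit over (White, Asian, Black) with known coefficients
  b_true <- rbind(Asian = c(-1.0, 0.6, -0.3), Black = c(-1.4, -0.4, 0.5))
  eta <- cbind(0, cbind(1, y, x) %*% t(b_true))
  P <- exp(eta) / rowSums(exp(eta))
  u <- runif(n)
  idx <- 1L + (u > P[, 1]) + (u > P[, 1] + P[, 2])
  co <- data.frame(
    ethnicity = factor(c("White", "Asian", "Black")[idx],
                       levels = c("White", "Asian", "Black")),
    t2d = y,
    sex = factor(ifelse(x == 1, "Women", "Men"), levels = c("Men", "Women")),
    age_group = factor("40-49", levels = "40-49"),
    deprivation = factor("Q1", levels = "Q1")
  )
  mod <- fit_imputation_model(co)
  est <- mod$coef[, c("(Intercept)", "t2d", "sexWomen")]
  se <- matrix(sqrt(diag(mod$vcov)), nrow = 2, byrow = TRUE)[, c(1, 2, 3)]
  expect_true(all(abs(est - b_true) < 3 * se))
})

test_that("the analytic covariance agrees with the numeric Hessian from nnet", {
  co <- make_cohort(3000, seed = 83)
  mod <- fit_imputation_model(co)
  cc <- co[!is.na(co$ethnicity), ]
  cc$ethnicity <- relevel(droplevels(factor(cc$ethnicity)), mod$reference)
  ref <- nnet::multinom(ethnicity ~ t2d + sex + age_group + deprivation,
                        data = cc, trace = FALSE, maxit = 500, Hessian = TRUE)
  v_ref <- vcov(ref)
  expect_equal(unname(mod$vcov[rownames(v_ref), colnames(v_ref)]),
               unname(v_ref), tolerance = 5e-3)
})

test_that("an ethnicity category with no complete records is an error", {
  co <- make_cohort(2000, seed = 97)
  co$ethnicity[co$ethnicity == "Black" & !is.na(co$ethnicity)] <- NA
  expect_error(fit_imputation_model(co), "Black")
})

test_that("posterior draws are centred at the MLE with the asymptotic covariance", {
  co <- make_cohort(5000, seed = 103)
  mod <- fit_imputation_model(co)
  mu <- as.vector(t(mod$coef))

  zero <- mod
  zero$vcov[] <- 0
  expect_equal(unname(draw_model_parameters(zero, seed = 1)), mu)

  expect_identical(draw_model_parameters(mod, seed = 5),
                   draw_model_parameters(mod, seed = 5))

  # Monte-Carlo moments on a small hand-built model
  small <- structure(list(
    coef = matrix(c(0.5, -0.2), 1, 2,
                  dimnames = list("B", c("(Intercept)", "x"))),
    vcov = matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2,
                  dimnames = list(c("B:(Intercept)", "B:x"),
                                  c("B:(Intercept)", "B:x"))),
    reference = "A", categories = c("A", "B"),
    predictors = c("(Intercept)", "x"), n_complete = 1000L
  ), class = "imputation_model")
  set.seed(100)
  draws <- t(replicate(10000, draw_model_parameters(small)))
  expect_lt(max(abs(colMeans(draws) - c(0.5, -0.2)) /
                  sqrt(diag(small$vcov) / 10000)), 5)
  expect_equal(unname(cov(draws)), unname(small$vcov), tolerance = 0.08)

  bad <- mod
  bad$vcov[1, 1] <- -1
  expect_error(draw_model_parameters(bad), "positive semi-definite")
})

test_that("the two-category calibration offset matches the 1-D grid-search oracle", {
  # 30 A and 10 B observed, 60 missing rows each with p_B = 0.25 at delta = 0;
  # the target (0.5, 0.5) forces 10 + 60 * plogis(logit(0.25) + delta_B) = 50
  X <- matrix(1, 60, 1, dimnames = list(NULL, "(Intercept)"))
  beta <- matrix(qlogis(0.25), 1, 1, dimnames = list("B", "(Intercept)"))
  targets <- census_targets(c(A = 0.5, B = 0.5))
  d <- calibrate_delta(beta, X, c(A = 30, B = 10), targets, reference = "A")
  oracle <- grid_delta_2cat(beta, X, c(30, 10), c(0.5, 0.5))
  expect_lt(abs(d[["B"]] - oracle), 1e-4)
  expect_equal(d[["B"]], log(6), tolerance = 1e-7)  # closed form
  expect_lt(attr(d, "residual"), 1e-8)
  expect_identical(d[["A"]], 0)
})

test_that("the Newton solver matches the coordinate-bisection oracle on random small instances", {
  set.seed(211)
  for (r in 1:12) {
    n_mis <- sample(10:50, 1)
    X <- cbind(1, matrix(rnorm(n_mis * 2), n_mis, 2))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    beta <- matrix(rnorm(6, sd = 0.7), 2, 3,
                   dimnames = list(c("B", "C"), colnames(X)))
    n_obs <- c(A = sample(20:60, 1), B = sample(10:40, 1), C = sample(10:40, 1))
    N <- sum(n_obs) + n_mis
    # draw a feasible target strictly inside the achievable box
    w <- runif(3, 0.25, 0.75)
    tgt <- (n_obs + w * n_mis * runif(3, 0.5, 1.5))
    tgt <- tgt / sum(tgt)
    feasible <- all(N * tgt > n_obs + 1e-6) & all(N * tgt < n_obs + n_mis - 1e-6)
    if (!feasible) next
    targets <- census_targets(setNames(tgt, c("A", "B", "C")))
    d <- calibrate_delta(beta, X, n_obs, targets, reference = "A")
    oracle <- bisect_delta_oracle(beta, X, n_obs, tgt)
    expect_lt(max(abs(as.numeric(d) - oracle)), 1e-4)
    expect_lt(attr(d, "residual"), 1e-8)
  }
})

test_that("calibration probabilities conserve mass and respond monotonically to their own offset", {
  set.seed(223)
  X <- cbind(1, rnorm(40))
  beta <- matrix(rnorm(4), 2, 2, dimnames = list(c("B", "C"), NULL))
  labels <- c("A", "B", "C")
  for (d_b in c(-5, -1, 0, 2, 8)) {
    P <- calmi:::.category_probs(X, beta, c(A = 0, B = d_b, C = 0.5),
                                 labels, "A")
    expect_equal(rowSums(P), rep(1, 40), tolerance = 1e-12)
  }
  exp_b <- vapply(c(-2, -1, 0, 1, 2), function(d_b)
    sum(calmi:::.category_probs(X, beta, c(A = 0, B = d_b, C = 0.5),
                                labels, "A")[, "B"]),
    numeric(1))
  expect_true(all(diff(exp_b) > 0))
})

test_that("infeasible census targets fail fast with the achievable interval", {
  X <- matrix(1, 5, 1)
  beta <- matrix(0, 1, 1, dimnames = list("B", NULL))
  expect_error(
    calibrate_delta(beta, X, c(A = 90, B = 5), census_targets(c(A = 0.5, B = 0.5)),
                    reference = "A"),
    "achievable interval")
  expect_error(
    calibrate_delta(beta, X[0, , drop = FALSE], c(A = 9, B = 5),
                    census_targets(c(A = 0.5, B = 0.5)), reference = "A"),
    "at least one incomplete row")
})

test_that("imputed datasets respect the solved calibration in expectation and realisation", {
  cfg <- simulation_config(20000, seed = 229)
  co <- simulate_cohort(cfg, events = FALSE)$cohort
  mod <- fit_imputation_model(co)
  miss <- which(is.na(co$ethnicity))
  X_mis <- model.matrix(~ t2d + sex + age_group + deprivation, co[miss, ])
  n_obs <- table(co$ethnicity)[mod$categories]
  targets <- census_targets(setNames(cfg$census$proportions,
                                     cfg$census$labels)[mod$categories])
  beta <- calmi:::.coef_vector(mod)
  d <- calibrate_delta(calmi:::.beta_matrix(beta, mod), X_mis, n_obs, targets,
                       reference = mod$reference)
  # expected combined counts equal N * pi at the solution
  P <- calmi:::.category_probs(X_mis, calmi:::.beta_matrix(beta, mod), d,
                               names(d), mod$reference)
  expect_equal(unname((as.numeric(n_obs) + colSums(P)) / nrow(co)),
               unname(targets$proportions), tolerance = 1e-8)
  # realised counts fall within 3 multinomial SDs over repeated draws
  sds <- sqrt(colSums(P * (1 - P)))
  set.seed(1)
  for (r in 1:5) {
    eth <- impute_dataset(co, calmi:::.beta_matrix(beta, mod), d,
                          x_missing = X_mis)
    realised <- as.numeric(table(eth)[names(d)]) - as.numeric(n_obs)
    expect_true(all(abs(realised - colSums(P)) <= 4 * sds))
  }
})

test_that("imputation leaves observed entries alone and honours limit offsets", {
  co <- make_cohort(3000, seed = 233)
  mod <- fit_imputation_model(co)
  beta <- calmi:::.beta_matrix(calmi:::.coef_vector(mod), mod)
  # no missing entries: output equals input
  cc <- co[!is.na(co$ethnicity), ]
  zero <- structure(setNames(rep(0, 4), mod$categories),
                    class = "delta_offsets", reference = mod$reference)
  expect_identical(impute_dataset(cc, beta, zero), cc$ethnicity)
  # a huge offset forces every missing entry into that category
  push <- structure(setNames(c(0, 50, 0, 0), mod$categories),
                    class = "delta_offsets", reference = mod$reference)
  eth <- impute_dataset(co, beta, push, seed = 2)
  expect_true(all(eth[is.na(co$ethnicity)] == mod$categories[2]))
  expect_identical(eth[!is.na(co$ethnicity)],
                   co$ethnicity[!is.na(co$ethnicity)])
})

test_that("standard MI is the calibrated code path with offsets forced to zero", {
  co <- make_cohort(4000, seed = 239)
  mod <- fit_imputation_model(co)
  mi <- run_mi(co, "standard", M = 3, seed = 41, model = mod)
  expect_true(all(mi$deltas == 0))
  # replay the calibrated loop by hand with zero offsets under the same seed
  set.seed(41)
  miss <- which(is.na(co$ethnicity))
  X_mis <- model.matrix(~ t2d + sex + age_group + deprivation, co[miss, ])
  zero <- structure(setNames(rep(0, 4), mod$categories),
                    class = "delta_offsets", reference = mod$reference)
  for (m in 1:3) {
    b <- draw_model_parameters(mod)
    eth <- impute_dataset(co, calmi:::.beta_matrix(b, mod), zero,
                          x_missing = X_mis)
    expect_identical(eth, mi$imputations[[m]])
    expect_identical(unname(b), unname(mi$betas[m, ]))
  }
})

test_that("every imputed dataset keeps observed entries fixed and fills all gaps", {
  co <- make_cohort(5000, seed = 241)
  cfg_targets <- default_census_targets()
  mi <- run_mi(co, "calibrated", M = 4, targets = cfg_targets, seed = 7)
  obs <- !is.na(co$ethnicity)
  for (m in 1:4) {
    expect_false(anyNA(mi$imputations[[m]]))
    expect_identical(mi$imputations[[m]][obs], co$ethnicity[obs])
  }
  expect_identical(dim(mi$deltas), c(4L, 4L))
  expect_identical(dim(mi$betas), c(4L, length(calmi:::.coef_vector(mi$model))))
})

test_that("single imputation with White converts exactly the missing count", {
  co <- make_cohort(3000, seed = 251)
  n_miss <- sum(is.na(co$ethnicity))
  mi <- run_mi(co, "single_white")
  eth <- mi$imputations[[1]]
  expect_identical(sum(is.na(eth)), 0L)
  expect_identical(sum(eth == "White"),
                   sum(co$ethnicity == "White", na.rm = TRUE) + n_miss)
  cr <- run_mi(co, "complete_records")
  expect_identical(nrow(cr), nrow(co) - n_miss)
  expect_false(anyNA(cr$ethnicity))
})

test_that("calibrated imputations reproduce the census distribution in each dataset", {
  cfg <- simulation_config(30000, seed = 257)
  co <- simulate_cohort(cfg, events = FALSE)$cohort
  mi <- run_mi(co, "calibrated", M = 5, targets = cfg$census, seed = 3)
  for (m in 1:5) {
    dist <- prop.table(table(mi$imputations[[m]]))
    expect_lt(max(abs(dist[cfg$census$labels] - cfg$census$proportions)), 0.01)
  }
})
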