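# Predictors of the imputation model: the analysis outcome plus the analysis
# covariates; factors that are constant (single level) carry no contrast and
# are dropped, matching fit_logistic().
.imp_rhs_vars <- function(data) {
  keep <- c("sex", "age_group", "deprivation")
  keep <- keep[vapply(keep, function(v) nlevels(factor(data[[v]])) >= 2L,
                      logical(1))]
  c("t2d", keep)
}

# Design matrix of the imputation model. Built from the factor levels carried
# by the data, so complete-record and missing-row matrices always align.
.imp_design <- function(data, rhs = .imp_rhs_vars(data)) {
  stats::model.matrix(stats::reformulate(rhs), data = data)
}

#' Fit the multinomial logistic imputation model
#'
#' Maximum-likelihood multinomial logistic regression of ethnicity on the
#' analysis outcome and the analysis covariates (sex, age group, deprivation
#' as indicator sets), using complete records only. Including the outcome
#' keeps the imputation model congenial with the analysis model. The
#' asymptotic parameter covariance is the inverse observed information,
#' evaluated analytically at the MLE.
#'
#' @param cohort data.frame with columns `ethnicity` (factor, possibly with
#'   `NA`s), `t2d`, `sex`, `age_group`, `deprivation`; predictors must be
#'   complete.
#' @param ridge optional non-negative ridge (weight-decay) penalty used as a
#'   fallback for separation or near-empty cells; 0 (the default) is the
#'   plain MLE.
#' @return an object of class `imputation_model`: coefficient matrix
#'   (`(K-1)` non-reference categories by `p` predictors), covariance of the
#'   vectorised coefficients (category-major order), reference category,
#'   category labels and the complete-record count.
#' @export
fit_imputation_model <- function(cohort, ridge = 0) {
  vars <- c("ethnicity", "t2d", "sex", "age_group", "deprivation")
  absent <- setdiff(vars, names(cohort))
  if (length(absent))
    stopf("fit_imputation_model: cohort lacks column(s): %s",
          paste(absent, collapse = ", "))
  cc <- cohort[!is.na(cohort$ethnicity), vars]
  if (!nrow(cc)) stopf("fit_imputation_model: no complete records")
  if (anyNA(cc))
    stopf("fit_imputation_model: imputation-model predictors must be complete (apply eligibility first)")
  lev <- levels(as.factor(cohort$ethnicity))  # full category set, incl. unused
  tab <- table(factor(cc$ethnicity, levels = lev))
  if (any(tab == 0L))
    stopf("fit_imputation_model: no complete records in category '%s'; merge sparse categories or revisit the classification (a ridge penalty cannot rescue an empty category)",
          paste(names(tab)[tab == 0L], collapse = "', '"))
  ref <- if ("White" %in% lev) "White" else lev[1L]
  cc$ethnicity <- stats::relevel(factor(cc$ethnicity, levels = lev), ref)
  rhs <- .imp_rhs_vars(cc)

  fit <- nnet::multinom(stats::reformulate(rhs, "ethnicity"), data = cc,
                        trace = FALSE, maxit = 500L, decay = ridge,
                        Hessian = FALSE)
  if (fit$convergence != 0L)
    stopf("fit_imputation_model: multinomial fit did not converge")
  B <- stats::coef(fit)
  if (is.null(dim(B)))  # K = 2: nnet returns a plain vector
    B <- matrix(B, nrow = 1L,
                dimnames = list(levels(cc$ethnicity)[2L], names(B)))
  if (ridge == 0 && max(abs(B)) > 15)
    stopf("fit_imputation_model: extreme coefficients suggest separation; refit with a small ridge penalty (ridge > 0) or merge sparse categories")

  X <- .imp_design(cc, rhs)
  if (!identical(colnames(X), colnames(B)))
    stopf("fit_imputation_model: internal design/coefficient mismatch")
  V <- .multinom_vcov(X, B, ridge)
  structure(list(
    coef = B,
    vcov = V,
    reference = ref,
    categories = levels(cc$ethnicity),
    predictors = colnames(B),
    rhs = rhs,
    n_complete = nrow(cc)
  ), class = "imputation_model")
}

# Inverse observed information of the multinomial logit, in category-major
# vectorised order; with weight decay the curvature gains 2*ridge on the
# diagonal (matching nnet's penalised criterion).
.multinom_vcov <- function(X, B, ridge = 0) {
  K1 <- nrow(B); p <- ncol(B)
  P <- softmax_rows(cbind(0, X %*% t(B)))
  Pnr <- P[, -1L, drop = FALSE]
  info <- matrix(0, K1 * p, K1 * p)
  for (k in seq_len(K1)) for (l in k:K1) {
    w <- if (k == l) Pnr[, k] * (1 - Pnr[, k]) else -Pnr[, k] * Pnr[, l]
    blk <- crossprod(X, X * w)
    rk <- (k - 1L) * p + seq_len(p); cl <- (l - 1L) * p + seq_len(p)
    info[rk, cl] <- blk
    if (l > k) info[cl, rk] <- t(blk)
  }
  if (ridge > 0) info <- info + 2 * ridge * diag(K1 * p)
  V <- tryCatch(solve(info), error = function(e)
    stopf("fit_imputation_model: singular information matrix (%s); consider a ridge penalty", conditionMessage(e)))
  V <- (V + t(V)) / 2
  nm <- as.vector(vapply(rownames(B),
                         function(k) paste(k, colnames(B), sep = ":"),
                         character(p)))
  dimnames(V) <- list(nm, nm)
  V
}

# Coefficients as one named vector in the covariance (category-major) order.
.coef_vector <- function(model) {
  stats::setNames(as.vector(t(model$coef)), rownames(model$vcov))
}

# Reshape a parameter vector back into the (K-1) x p coefficient matrix.
.beta_matrix <- function(beta, model) {
  if (!is.null(dim(beta))) return(beta)
  matrix(beta, nrow = nrow(model$coef), byrow = TRUE,
         dimnames = dimnames(model$coef))
}

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("Multinomial imputation model: %d categories (reference %s), %d predictors, fitted on %s complete records\n",
              length(x$categories), x$reference, length(x$predictors),
              format(x$n_complete, big.mark = ",")))
  invisible(x)
}

#' Draw imputation-model parameters from their approximate posterior
#'
#' Proper multiple imputation requires propagating parameter uncertainty:
#' each imputation uses one draw from the multivariate normal approximation
#' to the posterior, centred at the MLE with the asymptotic covariance.
#'
#' @param model an [fit_imputation_model()] result.
#' @param seed optional integer seed.
#' @return a named parameter vector (category-major order).
#' @export
draw_model_parameters <- function(model, seed = NULL) {
  stopifnot(inherits(model, "imputation_model"))
  V <- model$vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stopf("draw_model_parameters: parameter covariance is not positive semi-definite (min eigenvalue %.3g)",
          min(ev))
  if (!is.null(seed)) set.seed(seed)
  mu <- .coef_vector(model)
  draw <- MASS::mvrnorm(1L, mu = mu, Sigma = V)
  stats::setNames(as.numeric(draw), names(mu))
}

# Row-wise category probabilities at (beta, delta): columns follow `labels`,
# the reference category contributes linear predictor 0.
.category_probs <- function(X, beta_mat, delta, labels, reference) {
  K <- length(labels)
  eta <- matrix(0, nrow(X), K, dimnames = list(NULL, labels))
  nonref <- setdiff(labels, reference)
  bm <- beta_mat
  if (!is.null(rownames(bm))) bm <- bm[nonref, , drop = FALSE]
  eta[, nonref] <- X %*% t(bm)
  eta <- eta + matrix(delta[labels], nrow(X), K, byrow = TRUE)
  softmax_rows(eta)
}

#' Solve the census-calibration offsets
#'
#' Finds category-specific log-odds offsets `delta` (reference fixed at 0)
#' such that the expected combined distribution of ethnicity — observed
#' counts plus the model-implied expected imputed counts over the incomplete
#' rows — equals the census targets:
#' `(n_obs_k + sum_i p_ik(beta, delta)) / N = pi_k` for every category `k`,
#' where `p_ik` is the multinomial-logit probability with `delta_k` added to
#' the linear predictor. Solved by damped Newton-Raphson with the analytic
#' Jacobian, starting at `delta = 0`; the sum over categories of the
#' calibration equations is identically zero, so the `K - 1` non-reference
#' equations determine the solution, which is unique because each expected
#' count is strictly increasing in its own offset.
#'
#' @param beta parameter draw: either the `(K-1) x p` coefficient matrix or
#'   the vectorised (category-major) form.
#' @param x_missing design matrix of the incomplete rows (from the same
#'   formula as the fitted model).
#' @param observed_counts named per-category counts among complete records.
#' @param targets a [census_targets()] object; labels must match the model
#'   categories.
#' @param reference reference category (offset fixed at 0); defaults to the
#'   first target label.
#' @param tol convergence tolerance on the max-norm calibration residual
#'   (proportion scale), default 1e-8.
#' @param max_iter maximum Newton iterations (default 100).
#' @return an object of class `delta_offsets`: named numeric vector of
#'   length `K` with the reference at 0; attributes `residual`, `iterations`
#'   and `reference`.
#' @export
calibrate_delta <- function(beta, x_missing, observed_counts, targets,
                            reference = targets$labels[1L],
                            tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(targets, "census_targets"))
  labels <- targets$labels
  K <- length(labels)
  if (!reference %in% labels)
    stopf("calibrate_delta: reference '%s' is not a target category", reference)
  n_mis <- nrow(x_missing)
  if (is.null(n_mis) || n_mis < 1L)
    stopf("calibrate_delta: need at least one incomplete row")
  n_obs <- observed_counts
  if (!is.null(names(n_obs))) {
    if (!all(labels %in% names(n_obs)))
      stopf("calibrate_delta: observed_counts lacks categories: %s",
            paste(setdiff(labels, names(n_obs)), collapse = ", "))
    n_obs <- n_obs[labels]
  } else if (length(n_obs) != K) {
    stopf("calibrate_delta: observed_counts must have one entry per category")
  }
  n_obs <- as.numeric(n_obs)
  N <- sum(n_obs) + n_mis
  pi_k <- targets$proportions

  # feasibility: the target count must be attainable between "no missing row
  # imputed into k" and "every missing row imputed into k"
  margin <- 1e-9
  infeasible <- !(N * pi_k > n_obs + margin & N * pi_k < n_obs + n_mis - margin)
  if (any(infeasible)) {
    msg <- paste(sprintf("'%s': target %.6f outside achievable interval (%.6f, %.6f)",
                         labels[infeasible], pi_k[infeasible],
                         (n_obs / N)[infeasible],
                         ((n_obs + n_mis) / N)[infeasible]),
                 collapse = "; ")
    stopf("calibrate_delta: infeasible census targets — %s", msg)
  }

  beta_mat <- if (is.null(dim(beta)))
    matrix(beta, nrow = K - 1L, byrow = TRUE) else beta
  if (ncol(beta_mat) != ncol(x_missing))
    stopf("calibrate_delta: beta has %d predictors but x_missing has %d columns",
          ncol(beta_mat), ncol(x_missing))
  if (is.null(rownames(beta_mat)))
    rownames(beta_mat) <- setdiff(labels, reference)

  delta <- stats::setNames(rep(0, K), labels)
  free <- which(labels != reference)
  resid_of <- function(d) {
    P <- .category_probs(x_missing, beta_mat, d, labels, reference)
    f <- (n_obs + colSums(P)) / N - pi_k
    list(P = P, f = f, max = max(abs(f)))
  }
  cur <- resid_of(delta)
  iter <- 0L
  while (cur$max >= tol) {
    if (iter >= max_iter)
      stopf("calibrate_delta: no convergence within %d iterations (residual %.3g)",
            max_iter, cur$max)
    Pf <- cur$P[, free, drop = FALSE]
    J <- (diag(colSums(Pf), nrow = length(free)) - crossprod(Pf)) / N
    step <- tryCatch(solve(J, cur$f[free]), error = function(e)
      stopf("calibrate_delta: singular Jacobian (%s)", conditionMessage(e)))
    lam <- 1
    repeat {  # damped steps on overshoot
      cand <- delta
      cand[free] <- delta[free] - lam * step
      trial <- resid_of(cand)
      if (is.finite(trial$max) && trial$max < cur$max) break
      lam <- lam / 2
      if (lam < 1e-10)
        stopf("calibrate_delta: step damping failed (residual %.3g)", cur$max)
    }
    delta <- cand; cur <- trial; iter <- iter + 1L
  }
  structure(delta, class = "delta_offsets",
            residual = cur$max, iterations = iter, reference = reference)
}

#' @export
print.delta_offsets <- function(x, ...) {
  cat(sprintf("Calibration offsets (reference %s, residual %.2e, %d iterations):\n",
              attr(x, "reference"), attr(x, "residual"), attr(x, "iterations")))
  print(round(unclass(x)[seq_along(x)], 4))
  invisible(x)
}

#' Impute missing ethnicity for one completed dataset
#'
#' Draws each missing entry from the categorical distribution
#' `p_i(beta, delta)`; observed entries are untouched.
#'
#' @param cohort cohort data.frame with an `ethnicity` factor containing the
#'   missing entries (and the imputation-model predictors).
#' @param beta parameter draw (matrix or vectorised form).
#' @param delta a [calibrate_delta()] result (use all-zero offsets for
#'   uncalibrated imputation).
#' @param seed optional integer seed.
#' @param x_missing optional precomputed design matrix of the missing rows.
#' @return the completed ethnicity factor (full column).
#' @export
impute_dataset <- function(cohort, beta, delta, seed = NULL, x_missing = NULL) {
  eth <- cohort$ethnicity
  miss <- which(is.na(eth))
  if (!length(miss)) return(eth)
  labels <- names(delta)
  reference <- attr(delta, "reference") %||% labels[1L]
  if (!all(labels %in% levels(eth)))
    stopf("impute_dataset: offset categories [%s] are not ethnicity levels",
          paste(setdiff(labels, levels(eth)), collapse = ", "))
  X <- x_missing %||% .imp_design(cohort[miss, , drop = FALSE])
  beta_mat <- if (is.null(dim(beta)))
    matrix(beta, nrow = length(labels) - 1L, byrow = TRUE,
           dimnames = list(setdiff(labels, reference), NULL)) else beta
  P <- .category_probs(X, beta_mat, delta, labels, reference)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample_categories(P, stats::runif(length(miss)))
  eth[miss] <- factor(labels[idx], levels = levels(eth))
  eth
}

#' Run a missing-ethnicity handling strategy
#'
#' The primary strategy is `"calibrated"`: for each of `M` imputations a
#' parameter vector is drawn from the approximate posterior, the calibration
#' offsets are re-solved for that draw (keeping every imputed dataset
#' census-consistent in expectation), and missing entries are drawn.
#' `"standard"` is the identical pipeline with the offsets forced to zero
#' (uncalibrated MI). `"single_white"` sets every missing entry to White
#' (one dataset); `"complete_records"` drops incomplete rows.
#'
#' @param cohort cohort data.frame (eligible rows; complete predictors).
#' @param strategy one of `"calibrated"`, `"standard"`, `"single_white"`,
#'   `"complete_records"`.
#' @param M number of imputations (default 30; must be >= 2 for the MI
#'   strategies).
#' @param targets [census_targets()]; required for `"calibrated"`.
#' @param seed optional integer seed.
#' @param ridge optional ridge penalty passed to [fit_imputation_model()].
#' @param model optional pre-fitted [fit_imputation_model()] result (reused
#'   across strategies to save refitting).
#' @return for the MI strategies and `"single_white"`, an object of class
#'   `multiple_imputations` (completed columns plus per-imputation offsets
#'   and parameter draws, kept for audit); for `"complete_records"`, the
#'   filtered cohort.
#' @export
run_mi <- function(cohort,
                   strategy = c("calibrated", "standard", "single_white",
                                "complete_records"),
                   M = 30L, targets = NULL, seed = NULL, ridge = 0,
                   model = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(seed)
  miss <- which(is.na(cohort$ethnicity))

  if (strategy == "complete_records") {
    out <- if (length(miss)) cohort[-miss, , drop = FALSE] else cohort
    attr(out, "strategy") <- "complete_records"
    return(out)
  }
  if (strategy == "single_white") {
    if (!"White" %in% levels(cohort$ethnicity))
      stopf("run_mi: single_white requires a 'White' ethnicity level")
    eth <- cohort$ethnicity
    eth[miss] <- "White"
    return(structure(list(imputations = list(eth), deltas = NULL, betas = NULL,
                          strategy = "single_white", M = 1L, model = NULL,
                          missing_index = miss, n = nrow(cohort)),
                     class = "multiple_imputations"))
  }

  M <- as.integer(M)
  if (M < 2L) stopf("run_mi: multiple imputation needs M >= 2")
  if (strategy == "calibrated" && !inherits(targets, "census_targets"))
    stopf("run_mi: calibrated imputation requires census targets")
  model <- model %||% fit_imputation_model(cohort, ridge)
  if (!length(miss)) {
    # nothing to impute: M copies of the observed column
    return(structure(list(imputations = rep(list(cohort$ethnicity), M),
                          deltas = NULL, betas = NULL, strategy = strategy,
                          M = M, model = model, missing_index = miss,
                          n = nrow(cohort)),
                     class = "multiple_imputations"))
  }
  if (strategy == "calibrated") {
    if (!setequal(targets$labels, model$categories))
      stopf("run_mi: census labels [%s] do not match ethnicity categories [%s]",
            paste(targets$labels, collapse = ", "),
            paste(model$categories, collapse = ", "))
    # align target order to the model's category order (reference first)
    targets <- census_targets(
      stats::setNames(targets$proportions, targets$labels)[model$categories])
  }
  X_mis <- .imp_design(cohort[miss, , drop = FALSE], model$rhs)
  n_obs <- table(cohort$ethnicity)[model$categories]
  zero_delta <- structure(stats::setNames(rep(0, length(model$categories)),
                                          model$categories),
                          class = "delta_offsets", residual = NA_real_,
                          iterations = 0L, reference = model$reference)
  imputations <- vector("list", M)
  deltas <- matrix(NA_real_, M, length(model$categories),
                   dimnames = list(NULL, model$categories))
  betas <- matrix(NA_real_, M, length(.coef_vector(model)),
                  dimnames = list(NULL, names(.coef_vector(model))))
  residuals <- rep(NA_real_, M)
  for (m in seq_len(M)) {
    b <- draw_model_parameters(model)
    d <- if (strategy == "calibrated")
      calibrate_delta(.beta_matrix(b, model), X_mis, n_obs, targets,
                      reference = model$reference)
    else zero_delta
    imputations[[m]] <- impute_dataset(cohort, .beta_matrix(b, model), d,
                                       x_missing = X_mis)
    deltas[m, ] <- as.numeric(d)
    betas[m, ] <- b
    residuals[m] <- attr(d, "residual")
  }
  structure(list(imputations = imputations, deltas = deltas, betas = betas,
                 residuals = residuals, strategy = strategy, M = M,
                 model = model, missing_index = miss, n = nrow(cohort)),
            class = "multiple_imputations")
}

#' @export
print.multiple_imputations <- function(x, ...) {
  cat(sprintf("%s: M = %d completed dataset(s), %s of %s entries imputed\n",
              switch(x$strategy,
                     calibrated = "Calibrated-delta multiple imputation",
                     standard = "Standard (uncalibrated) multiple imputation",
                     single_white = "Single imputation with the White group",
                     x$strategy),
              x$M, format(length(x$missing_index), big.mark = ","),
              format(x$n, big.mark = ",")))
  invisible(x)
}

#' Completed cohort for one imputation
#'
#' @param cohort the cohort the imputations were generated from.
#' @param mi a [run_mi()] result.
#' @param m imputation index.
#' @return the cohort with `ethnicity` replaced by the m-th completed column.
#' @export
completed_cohort <- function(cohort, mi, m = 1L) {
  stopifnot(inherits(mi, "multiple_imputations"))
  if (m < 1L || m > mi$M) stopf("completed_cohort: m must be in 1..%d", mi$M)
  cohort$ethnicity <- mi$imputations[[m]]
  cohort
}
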