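.analysis_refs <- c(ethnicity = "White", sex = "Men",
                    age_group = "40-49", deprivation = "Q1")

.set_references <- function(data) {
  for (v in names(.analysis_refs)) {
    ref <- .analysis_refs[[v]]
    x <- droplevels(factor(data[[v]]))
    if (ref %in% levels(x)) x <- stats::relevel(x, ref)
    data[[v]] <- x
  }
  data
}

#' Fit the adjusted logistic regression on one completed dataset
#'
#' Maximum-likelihood logistic regression of the type 2 diabetes indicator on
#' ethnicity, sex, age group and deprivation quintile, each entering as
#' categorical contrasts against the references White, men, 40-49 and
#' quintile 1. Covariates that are constant in the supplied data carry no
#' contrast and are dropped from the design.
#'
#' @param data completed dataset (no missing values in the model variables).
#' @param ridge optional non-negative ridge penalty on the non-intercept
#'   coefficients, available as a separation fallback (default 0, plain MLE).
#' @param start optional starting coefficient vector (warm start; useful
#'   when refitting across many similar completed datasets).
#' @return an object of class `fit_result`: named `coefficients`, `vcov`,
#'   `n`, `df_residual`.
#' @export
fit_logistic <- function(data, ridge = 0, start = NULL) {
  vars <- c("t2d", "ethnicity", "sex", "age_group", "deprivation")
  absent <- setdiff(vars, names(data))
  if (length(absent))
    stopf("fit_logistic: data lacks column(s): %s", paste(absent, collapse = ", "))
  if (anyNA(data[vars]))
    stopf("fit_logistic: model variables contain missing values")
  data <- .set_references(data)
  # covariates constant in the data carry no contrast and are dropped
  rhs <- names(.analysis_refs)
  rhs <- rhs[vapply(rhs, function(v) nlevels(data[[v]]) >= 2L, logical(1))]
  X <- if (length(rhs)) stats::model.matrix(stats::reformulate(rhs), data)
       else stats::model.matrix(~ 1, data)
  y <- data$t2d
  p <- ncol(X)

  if (ridge > 0) {
    pen <- c(0, rep(ridge, p - 1L))  # intercept unpenalised
    beta <- if (!is.null(start)) unname(start) else rep(0, p)
    converged <- FALSE
    for (it in 1:100) {
      mu <- stats::plogis(drop(X %*% beta))
      w <- mu * (1 - mu)
      score <- drop(crossprod(X, y - mu)) - 2 * pen * beta
      H <- crossprod(X, X * w) + 2 * diag(pen, p)
      step <- solve(H, score)
      beta <- beta + step
      if (!all(is.finite(beta))) stopf("fit_logistic: penalised fit diverged")
      if (max(abs(step)) < 1e-10) { converged <- TRUE; break }
    }
    if (!converged) stopf("fit_logistic: penalised IRLS did not converge")
    V <- solve(H)
    coefs <- stats::setNames(beta, colnames(X))
  } else {
    fit <- stats::glm.fit(X, y, family = stats::binomial(), start = start)
    if (!fit$converged) stopf("fit_logistic: IRLS did not converge")
    if (fit$rank < p)
      stopf("fit_logistic: rank-deficient design (aliased contrasts)")
    coefs <- fit$coefficients
    if (any(abs(coefs) > 15))
      stopf("fit_logistic: extreme coefficients suggest separation; consider ridge > 0 or merging sparse levels")
    p1 <- seq_len(fit$rank)
    V <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    piv <- fit$qr$pivot[p1]
    dimnames(V) <- list(names(coefs)[piv], names(coefs)[piv])
    V <- V[names(coefs), names(coefs)]
  }
  dimnames(V) <- list(names(coefs), names(coefs))
  structure(list(coefficients = coefs, vcov = V, n = nrow(X),
                 df_residual = nrow(X) - p),
            class = "fit_result")
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Pooled point estimate is the mean of the per-imputation estimates; the
#' total variance combines the mean within-imputation variance `W` and the
#' between-imputation variance `B` as `T = W + (1 + 1/M) B`. Interval
#' estimates use the Barnard-Rubin small-sample degrees of freedom; when
#' `B = 0` the complete-data degrees of freedom are used.
#'
#' @param fits list of `M >= 2` [fit_logistic()] results with congruent
#'   coefficient labels.
#' @param conf confidence level (default 0.95).
#' @return a data.frame of class `pooled_estimate` with one row per
#'   coefficient: `term`, `estimate`, `se`, `within`, `between`, `total`,
#'   `df`, `conf.low`, `conf.high`, and the odds-ratio scale `or`,
#'   `or.low`, `or.high`.
#' @export
pool_rubin <- function(fits, conf = 0.95) {
  M <- length(fits)
  if (M < 2L) stopf("pool_rubin: need at least two imputations")
  labs <- names(fits[[1L]]$coefficients)
  for (f in fits)
    if (!identical(names(f$coefficients), labs))
      stopf("pool_rubin: coefficient labels differ across imputations")
  Q <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  U <- do.call(rbind, lapply(fits, function(f) diag(f$vcov)))
  qbar <- colMeans(Q)
  w <- colMeans(U)
  b <- apply(Q, 2L, stats::var)
  tot <- w + (1 + 1 / M) * b
  nu_com <- min(vapply(fits, `[[`, numeric(1), "df_residual"))
  df <- vapply(seq_along(labs), function(j) {
    if (b[j] <= 0) return(nu_com)
    df_old <- (M - 1) * (1 + w[j] / ((1 + 1 / M) * b[j]))^2
    gamma <- (1 + 1 / M) * b[j] / tot[j]
    nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - gamma)
    1 / (1 / df_old + 1 / nu_obs)
  }, numeric(1))
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  lo <- qbar - tcrit * sqrt(tot)
  hi <- qbar + tcrit * sqrt(tot)
  out <- data.frame(term = labs, estimate = unname(qbar),
                    se = unname(sqrt(tot)), within = unname(w),
                    between = unname(b), total = unname(tot),
                    df = df, conf.low = unname(lo), conf.high = unname(hi),
                    or = exp(unname(qbar)), or.low = exp(unname(lo)),
                    or.high = exp(unname(hi)), m = M)
  class(out) <- c("pooled_estimate", "data.frame")
  out
}

# Wald-style interval for a single (non-imputed) fit, in the same layout as
# pool_rubin so strategies can be tabulated side by side.
.single_fit_estimate <- function(fit, conf = 0.95) {
  q <- fit$coefficients
  v <- diag(fit$vcov)
  tcrit <- stats::qt(1 - (1 - conf) / 2, fit$df_residual)
  lo <- q - tcrit * sqrt(v); hi <- q + tcrit * sqrt(v)
  out <- data.frame(term = names(q), estimate = unname(q),
                    se = unname(sqrt(v)), within = unname(v), between = 0,
                    total = unname(v), df = fit$df_residual,
                    conf.low = unname(lo), conf.high = unname(hi),
                    or = exp(unname(q)), or.low = exp(unname(lo)),
                    or.high = exp(unname(hi)), m = 1L)
  class(out) <- c("pooled_estimate", "data.frame")
  out
}

#' @export
print.pooled_estimate <- function(x, digits = 2, ...) {
  if (!all(c("term", "or", "or.low", "or.high", "m") %in% names(x)))
    return(print.data.frame(x, ...))
  cat(sprintf("Pooled estimates (M = %d):\n", x$m[1L]))
  show <- data.frame(term = x$term,
                     OR = round(x$or, digits),
                     `95% CI` = sprintf("%.*f to %.*f", digits, x$or.low,
                                        digits, x$or.high),
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Forest-style plot of pooled odds ratios
#' @param x a `pooled_estimate`.
#' @param terms optional subset of term labels to display.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pooled_estimate <- function(x, terms = NULL, ...) {
  d <- if (is.null(terms)) x[x$term != "(Intercept)", ] else x[x$term %in% terms, ]
  k <- nrow(d)
  graphics::plot(d$or, seq_len(k), xlim = range(c(d$or.low, d$or.high, 1)),
                 ylim = c(0.5, k + 0.5), log = "x", pch = 16, yaxt = "n",
                 xlab = "Odds ratio (log scale)", ylab = "", ...)
  graphics::segments(d$or.low, seq_len(k), d$or.high, seq_len(k))
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(k), labels = d$term, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Crude prevalence by level, pooled across imputations
#'
#' Within each level of ethnicity, sex, age group and deprivation, computes
#' the unadjusted percentage prevalence of the outcome per imputation, pools
#' on the logit scale with Rubin's rules (Barnard-Rubin degrees of freedom)
#' and back-transforms. Fully observed stratifiers are identical across
#' imputations, so the between-imputation variance is zero and the pooled
#' value equals the direct sample proportion. Proportions are clamped to
#' `[0.5/n, 1 - 0.5/n]` before the logit transform to guard empty margins.
#'
#' @param mi a [run_mi()] result (MI or single-imputation).
#' @param cohort the cohort the imputations were generated from (supplies
#'   the outcome and the observed stratifiers).
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `variable`, `level`, `n`, `prevalence`
#'   (percent), `conf.low`, `conf.high`.
#' @export
crude_prevalence <- function(mi, cohort, conf = 0.95) {
  stopifnot(inherits(mi, "multiple_imputations"))
  y <- cohort$t2d
  if (is.null(y)) stopf("crude_prevalence: cohort lacks the t2d outcome")
  M <- mi$M
  alpha <- 1 - conf
  rows <- list()
  for (v in c("ethnicity", "sex", "age_group", "deprivation")) {
    if (is.null(cohort[[v]])) next
    levs <- levels(factor(cohort[[v]]))
    if (v == "ethnicity") levs <- levels(mi$imputations[[1L]])
    theta <- matrix(NA_real_, M, length(levs))
    vtheta <- matrix(NA_real_, M, length(levs))
    ns <- matrix(0L, M, length(levs))
    for (m in seq_len(M)) {
      strat <- if (v == "ethnicity") mi$imputations[[m]] else cohort[[v]]
      for (j in seq_along(levs)) {
        in_lev <- strat == levs[j]
        n_l <- sum(in_lev)
        ns[m, j] <- n_l
        if (n_l == 0L) next
        p <- sum(y[in_lev]) / n_l
        p <- min(max(p, 0.5 / n_l), 1 - 0.5 / n_l)
        theta[m, j] <- stats::qlogis(p)
        vtheta[m, j] <- 1 / (n_l * p * (1 - p))
      }
    }
    for (j in seq_along(levs)) {
      if (any(ns[, j] == 0L)) {
        warning(sprintf("crude_prevalence: level '%s' of %s has no individuals in at least one imputation",
                        levs[j], v))
        rows[[paste(v, j)]] <- data.frame(variable = v, level = levs[j], n = 0L,
                                          prevalence = NA_real_,
                                          conf.low = NA_real_,
                                          conf.high = NA_real_)
        next
      }
      qbar <- mean(theta[, j])
      if (M >= 2L) {
        w <- mean(vtheta[, j]); b <- stats::var(theta[, j])
        tot <- w + (1 + 1 / M) * b
        nu_com <- min(ns[, j]) - 1
        df <- if (b <= 0) nu_com else {
          df_old <- (M - 1) * (1 + w / ((1 + 1 / M) * b))^2
          gamma <- (1 + 1 / M) * b / tot
          nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - gamma)
          1 / (1 / df_old + 1 / nu_obs)
        }
      } else {
        tot <- vtheta[1L, j]; df <- ns[1L, j] - 1
      }
      tcrit <- stats::qt(1 - alpha / 2, df)
      rows[[paste(v, j)]] <- data.frame(
        variable = v, level = levs[j],
        n = as.integer(round(mean(ns[, j]))),
        prevalence = 100 * stats::plogis(qbar),
        conf.low = 100 * stats::plogis(qbar - tcrit * sqrt(tot)),
        conf.high = 100 * stats::plogis(qbar + tcrit * sqrt(tot))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare missing-ethnicity strategies side by side
#'
#' Runs the four strategies end to end on the same cohort — calibrated-delta
#' MI, standard (uncalibrated) MI, single imputation with the White group,
#' and complete-record analysis — and tabulates the adjusted odds ratios
#' with confidence intervals.
#'
#' @param cohort eligible cohort with missing ethnicity.
#' @param targets [census_targets()] for the calibrated strategy.
#' @param M number of imputations for the MI strategies (default 30).
#' @param seed optional integer seed.
#' @param ridge optional ridge penalty for the model fits.
#' @return a data.frame of class `strategy_comparison`: the
#'   [pool_rubin()] columns plus a `strategy` column.
#' @export
compare_strategies <- function(cohort, targets, M = 30L, seed = NULL,
                               ridge = 0) {
  if (!is.null(seed)) set.seed(seed)
  model <- fit_imputation_model(cohort, ridge)

  pooled_of <- function(mi) {
    fits <- lapply(seq_len(mi$M), function(m)
      fit_logistic(completed_cohort(cohort, mi, m), ridge))
    if (mi$M >= 2L) pool_rubin(fits) else .single_fit_estimate(fits[[1L]])
  }
  res <- list(
    calibrated = pooled_of(run_mi(cohort, "calibrated", M, targets,
                                  ridge = ridge, model = model)),
    standard = pooled_of(run_mi(cohort, "standard", M, ridge = ridge,
                                model = model)),
    single_white = pooled_of(run_mi(cohort, "single_white")),
    complete_records = .single_fit_estimate(
      fit_logistic(run_mi(cohort, "complete_records"), ridge))
  )
  out <- do.call(rbind, lapply(names(res), function(s) {
    d <- res[[s]]; d$strategy <- s; d
  }))
  rownames(out) <- NULL
  class(out) <- c("strategy_comparison", "data.frame")
  out
}

#' @export
print.strategy_comparison <- function(x, digits = 2, ...) {
  eth <- x[grepl("^ethnicity", x$term), ]
  cat("Adjusted odds ratios by strategy (ethnicity contrasts):\n")
  wide <- stats::reshape(
    data.frame(term = eth$term, strategy = eth$strategy,
               or = sprintf("%.*f (%.*f to %.*f)", digits, eth$or,
                            digits, eth$or.low, digits, eth$or.high)),
    idvar = "term", timevar = "strategy", direction = "wide")
  names(wide) <- sub("^or\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
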