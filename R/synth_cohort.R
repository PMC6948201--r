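#' Generate demographic covariates for a synthetic cohort
#'
#' Samples sex, 10-year age group and Townsend deprivation quintile
#' independently from the configured marginals, samples ethnicity so that its
#' marginal expectation equals the census targets (optionally with a mild
#' deprivation association, see `ethnicity_dep_assoc`), and assigns
#' registration dates such that `eligible_fraction` of individuals satisfy
#' the 12-month registration rule at the index date.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer; when supplied the RNG is seeded here,
#'   otherwise the current RNG state is used (as [simulate_cohort()] does).
#' @return a data.frame with columns `id`, `sex`, `age_group`, `deprivation`,
#'   `ethnicity` (factors), `registration_start`, `registration_end` (Dates;
#'   `NA` end means still registered).
#' @export
generate_covariates <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  sex <- factor(sample(names(config$sex_marginal), n, TRUE, config$sex_marginal),
                levels = names(config$sex_marginal))
  age_group <- factor(sample(names(config$age_marginal), n, TRUE, config$age_marginal),
                      levels = names(config$age_marginal))
  deprivation <- factor(sample(names(config$deprivation_marginal), n, TRUE,
                               config$deprivation_marginal),
                        levels = names(config$deprivation_marginal))

  labs <- config$census$labels
  if (config$ethnicity_dep_assoc == 0) {
    ethnicity <- factor(sample(labs, n, TRUE, config$census$proportions),
                        levels = labs)
  } else {
    # tilt non-White weights by centred deprivation score, then renormalise;
    # centring keeps the marginal close to the census targets
    centre <- sum(config$deprivation_marginal * seq_along(config$deprivation_marginal))
    tilt <- exp(config$ethnicity_dep_assoc * (as.integer(deprivation) - centre))
    w <- matrix(config$census$proportions, n, length(labs), byrow = TRUE)
    w[, -1L] <- w[, -1L] * tilt
    p <- w / rowSums(w)
    ethnicity <- factor(labs[sample_categories(p, stats::runif(n))], levels = labs)
  }

  # registration tenure: eligible rows registered 12 months to ~20 years
  # before index; ineligible rows registered within the last 11 months
  idx <- config$index_date
  eligible <- stats::runif(n) < config$eligible_fraction
  days_back <- integer(n)
  days_back[eligible] <- sample.int(7300L - 366L + 1L, sum(eligible), TRUE) + 365L
  days_back[!eligible] <- sample.int(330L, sum(!eligible), TRUE)
  data.frame(
    id = seq_len(n),
    sex = sex,
    age_group = age_group,
    deprivation = deprivation,
    ethnicity = ethnicity,
    registration_start = idx - days_back,
    registration_end = as.Date(rep(NA_character_, n))
  )
}

#' Assign the type 2 diabetes outcome
#'
#' Draws a binary outcome per row from `plogis(alpha + eta_i)` where `eta_i`
#' sums the configured per-level log odds ratios and the intercept `alpha` is
#' root-found so the population-averaged prevalence over the generated rows
#' equals `target_overall_prevalence` within 1e-6.
#'
#' @param cohort output of [generate_covariates()] (complete covariates and
#'   ethnicity; call this before applying missingness).
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @return the cohort with an integer `t2d` column; the solved intercept is
#'   attached as attribute `"outcome_intercept"`.
#' @export
assign_outcome <- function(cohort, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (anyNA(cohort$ethnicity))
    stopf("assign_outcome: ethnicity must be fully observed (assign the outcome before applying missingness)")
  if (!is.null(seed)) set.seed(seed)
  eta <- .linear_predictor(cohort, config$true_log_odds)
  p_target <- config$target_overall_prevalence
  f <- function(a) mean(stats::plogis(a + eta)) - p_target
  lo <- f(-50); hi <- f(50)
  if (lo > 0 || hi < 0)
    stopf("assign_outcome: target prevalence %.6g unreachable; achievable range is (%.6g, %.6g)",
          p_target, mean(stats::plogis(-50 + eta)), mean(stats::plogis(50 + eta)))
  alpha <- stats::uniroot(f, c(-50, 50), tol = 1e-12)$root
  if (abs(f(alpha)) > 1e-6)
    stopf("assign_outcome: intercept root-finding failed (residual %.3g)", f(alpha))
  cohort$t2d <- stats::rbinom(nrow(cohort), 1L, stats::plogis(alpha + eta))
  attr(cohort, "outcome_intercept") <- alpha
  cohort
}

.linear_predictor <- function(cohort, tlo) {
  eta <- numeric(nrow(cohort))
  for (v in c("ethnicity", "sex", "age_group", "deprivation")) {
    eff <- tlo[[v]]
    lv <- levels(cohort[[v]])
    if (!all(lv %in% names(eff)))
      stopf("true_log_odds$%s lacks levels: %s", v,
            paste(setdiff(lv, names(eff)), collapse = ", "))
    eta <- eta + unname(eff[lv])[as.integer(cohort[[v]])]
  }
  eta
}

#' Apply MNAR missingness to ethnicity
#'
#' Sets ethnicity to missing per row with a probability determined by the
#' row's own (true) ethnic category — missing not at random — optionally
#' shifted on the logit scale by observed covariates. The pre-missingness
#' value is kept in an `ethnicity_true` column for bias evaluation in
#' simulation studies.
#'
#' @param cohort a cohort with fully observed `ethnicity`.
#' @param mech an [mnar_mechanism()].
#' @param seed optional integer seed.
#' @return the cohort with `ethnicity` containing `NA`s and a new
#'   `ethnicity_true` column.
#' @export
apply_mnar_missingness <- function(cohort, mech, seed = NULL) {
  stopifnot(inherits(mech, "mnar_mechanism"))
  if (anyNA(cohort$ethnicity))
    stopf("apply_mnar_missingness: ethnicity must be fully observed on input")
  lv <- levels(cohort$ethnicity)
  if (!all(lv %in% names(mech$prob_missing)))
    stopf("apply_mnar_missingness: mechanism lacks categories: %s",
          paste(setdiff(lv, names(mech$prob_missing)), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  p <- unname(mech$prob_missing[lv])[as.integer(cohort$ethnicity)]
  if (!is.null(mech$modifiers)) {
    for (v in names(mech$modifiers)) {
      if (is.null(cohort[[v]]))
        stopf("apply_mnar_missingness: modifier variable '%s' not in cohort", v)
      shift <- mech$modifiers[[v]][as.character(cohort[[v]])]
      shift[is.na(shift)] <- 0
      interior <- p > 0 & p < 1
      p[interior] <- stats::plogis(stats::qlogis(p[interior]) + shift[interior])
    }
  }
  cohort$ethnicity_true <- cohort$ethnicity
  miss <- stats::runif(nrow(cohort)) < p
  cohort$ethnicity[miss] <- NA
  cohort
}

#' Event types recognised by the case-ascertainment rule
#' @return character vector of the three coded record types.
#' @export
event_types <- function() c("diagnostic_code", "supporting_evidence", "treatment")

#' Generate a coded clinical event stream
#'
#' Every outcome-positive individual receives records of at least two
#' distinct event types dated on or before the index date (so the
#' two-of-three rule ascertains them); a configurable fraction of
#' outcome-negative individuals receives one or two records of a *single*
#' type, exercising the rule's negative branch.
#'
#' @param cohort a cohort with the `t2d` outcome assigned.
#' @param config a [simulation_config()] (supplies `index_date` and
#'   `decoy_fraction`).
#' @param seed optional integer seed.
#' @return a data.frame with columns `individual_id`, `event_type`,
#'   `event_date`.
#' @export
generate_event_stream <- function(cohort, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(cohort$t2d))
    stopf("generate_event_stream: assign the outcome before generating events")
  if (!is.null(seed)) set.seed(seed)
  idx <- config$index_date
  types <- event_types()
  acc_id <- list(); acc_type <- list(); acc_days <- list()

  pos <- which(cohort$t2d == 1L)
  if (length(pos)) {
    ntype <- sample(c(2L, 3L), length(pos), TRUE, c(0.6, 0.4))
    first_back <- sample.int(5475L, length(pos), TRUE)  # up to ~15 years
    # which of the three types each case carries: all three, or drop one
    dropped <- sample.int(3L, length(pos), TRUE)
    type_sets <- lapply(seq_along(pos), function(j)
      if (ntype[j] == 3L) types else types[-dropped[j]])
    acc_id[[1L]] <- rep(cohort$id[pos], ntype)
    acc_type[[1L]] <- unlist(type_sets, use.names = FALSE)
    # first record defines the diagnosis date; later records fall between it
    # and the index date
    gaps <- lapply(seq_along(pos), function(j)
      c(0L, sample.int(first_back[j], ntype[j] - 1L, replace = TRUE) - 1L))
    acc_days[[1L]] <- rep(first_back, ntype) - unlist(gaps, use.names = FALSE)
  }
  neg <- which(cohort$t2d == 0L)
  if (length(neg) && config$decoy_fraction > 0) {
    decoy <- neg[stats::runif(length(neg)) < config$decoy_fraction]
    if (length(decoy)) {
      nrec <- sample(c(1L, 2L), length(decoy), TRUE, c(0.7, 0.3))
      tt <- sample(types, length(decoy), TRUE)
      acc_id[[2L]] <- rep(cohort$id[decoy], nrec)
      acc_type[[2L]] <- rep(tt, nrec)
      acc_days[[2L]] <- sample.int(5475L, sum(nrec), TRUE)
    }
  }
  data.frame(
    individual_id = unlist(acc_id, use.names = FALSE) %||% integer(0),
    event_type = unlist(acc_type, use.names = FALSE) %||% character(0),
    event_date = idx - (unlist(acc_days, use.names = FALSE) %||% integer(0))
  )
}

#' Simulate a full synthetic cohort
#'
#' Chains [generate_covariates()], [assign_outcome()], optionally
#' [generate_event_stream()], and [apply_mnar_missingness()], seeding the RNG
#' once from `config$seed` so identical configurations yield byte-identical
#' output. Note that `events = FALSE` changes the downstream RNG stream.
#'
#' @param config a [simulation_config()].
#' @param events generate the coded event stream too? (default `TRUE`)
#' @return a list of class `synth_cohort` with elements `cohort`, `events`
#'   (or `NULL`) and `config`.
#' @export
simulate_cohort <- function(config, events = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cohort <- generate_covariates(config)
  cohort <- assign_outcome(cohort, config)
  ev <- if (events) generate_event_stream(cohort, config) else NULL
  cohort <- apply_mnar_missingness(cohort, config$missingness)
  structure(list(cohort = cohort, events = ev, config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %s individuals, %s cases (%.2f%%), %s missing ethnicity (%.1f%%)\n",
              format(nrow(x$cohort), big.mark = ","),
              format(sum(x$cohort$t2d), big.mark = ","),
              100 * mean(x$cohort$t2d),
              format(sum(is.na(x$cohort$ethnicity)), big.mark = ","),
              100 * mean(is.na(x$cohort$ethnicity))))
  if (!is.null(x$events))
    cat(sprintf("  event stream: %s records\n", format(nrow(x$events), big.mark = ",")))
  invisible(x)
}
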