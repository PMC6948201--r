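#' @keywords internal
sex_levels <- function() c("Men", "Women")

#' @keywords internal
age_levels <- function() {
  c("0-9", "10-19", "20-29", "30-39", "40-49",
    "50-59", "60-69", "70-79", "80+")
}

#' @keywords internal
deprivation_levels <- function() paste0("Q", 1:5)

#' Census target distribution over ethnic categories
#'
#' A population-level distribution of ethnicity (typically taken from the UK
#' census for the region the cohort is drawn from) used as the calibration
#' constraint of calibrated-delta multiple imputation: offsets are solved so
#' that the combined observed-plus-imputed distribution of ethnicity matches
#' these proportions.
#'
#' @param proportions numeric vector of category proportions; must sum to 1.
#' @param labels character labels, one per category; defaults to
#'   `names(proportions)`. Labels must match the ethnicity factor levels of
#'   the cohort the targets are used with.
#' @return an object of class `census_targets` with elements `labels` and
#'   `proportions`.
#' @seealso [default_census_targets()], [calibrate_delta()]
#' @export
census_targets <- function(proportions, labels = names(proportions)) {
  if (is.null(labels) || anyDuplicated(labels) > 0 || any(!nzchar(labels)))
    stopf("census_targets: category labels must be unique and non-empty")
  proportions <- as.numeric(proportions)
  if (length(proportions) != length(labels) || length(proportions) < 2L)
    stopf("census_targets: need one proportion per label (at least 2 categories)")
  if (any(!is.finite(proportions)) || any(proportions < 0) || any(proportions > 1))
    stopf("census_targets: proportions must lie in [0, 1]; got [%s]",
          paste(signif(proportions, 4), collapse = ", "))
  if (abs(sum(proportions) - 1) > 1e-12)
    stopf("census_targets: proportions must sum to 1 within 1e-12 (got %.15g)",
          sum(proportions))
  structure(list(labels = as.character(labels), proportions = proportions),
            class = "census_targets")
}

#' @export
print.census_targets <- function(x, ...) {
  cat("Census target distribution:\n")
  print(stats::setNames(round(x$proportions, 4), x$labels))
  invisible(x)
}

#' Illustrative default census targets
#'
#' A four-category ethnicity distribution (White, Asian, Black, Mixed/Other)
#' broadly evocative of an ethnically diverse UK urban population. These are
#' *illustrative defaults for simulation*, not official census figures; any
#' real analysis must supply the census distribution for its own catchment
#' population via [census_targets()].
#'
#' @return a `census_targets` object.
#' @export
default_census_targets <- function() {
  census_targets(c(White = 0.60, Asian = 0.18, Black = 0.13, `Mixed/Other` = 0.09))
}

#' MNAR missingness mechanism for ethnicity
#'
#' Missingness probabilities that depend on the (unobserved) ethnic category
#' itself — missing not at random. When all per-category probabilities are
#' equal the mechanism reduces to MCAR. Optional modifiers shift the
#' missingness log-odds by observed covariates (named numeric vectors keyed
#' by factor level, e.g. `list(deprivation = c(Q1 = 0, ..., Q5 = 0.3))`).
#'
#' @param prob_missing named numeric vector, one probability in \[0, 1\] per
#'   ethnic category.
#' @param modifiers optional named list of per-level logit shifts for
#'   observed covariates.
#' @return an object of class `mnar_mechanism`.
#' @seealso [default_mnar_mechanism()], [apply_mnar_missingness()]
#' @export
mnar_mechanism <- function(prob_missing, modifiers = NULL) {
  if (is.null(names(prob_missing)) || any(!nzchar(names(prob_missing))))
    stopf("mnar_mechanism: prob_missing must be named by ethnic category")
  prob_missing <- stats::setNames(as.numeric(prob_missing), names(prob_missing))
  if (any(!is.finite(prob_missing)) || any(prob_missing < 0) || any(prob_missing > 1))
    stopf("mnar_mechanism: missingness probabilities must lie in [0, 1]; got [%s]",
          paste(signif(prob_missing, 4), collapse = ", "))
  if (!is.null(modifiers) && (!is.list(modifiers) || is.null(names(modifiers))))
    stopf("mnar_mechanism: modifiers must be a named list of per-level logit shifts")
  structure(list(prob_missing = prob_missing, modifiers = modifiers),
            class = "mnar_mechanism")
}

#' Default MNAR mechanism tuned to an overall missingness fraction
#'
#' The default mechanism has missingness log-odds `base + offset[k]` for
#' category `k`. The minority-category offsets make ethnicity more often
#' missing for non-White individuals, so complete records over-represent the
#' White group; the common base is root-found (one-dimensional) so that the
#' population-averaged missingness under `census` equals `overall`.
#'
#' @param census a [census_targets()] object giving the population ethnicity
#'   distribution used to average the per-category probabilities.
#' @param overall target overall missing fraction (default 0.234, i.e. 23.4%).
#' @param offsets per-category log-odds offsets, in the order of
#'   `census$labels`; default `c(0, 1, 1, 1)`-style (0 for the first,
#'   reference, category and +1 for the rest).
#' @return an `mnar_mechanism`.
#' @export
default_mnar_mechanism <- function(census = default_census_targets(),
                                   overall = 0.234,
                                   offsets = NULL) {
  stopifnot(inherits(census, "census_targets"))
  K <- length(census$labels)
  if (is.null(offsets)) offsets <- c(0, rep(1, K - 1L))
  if (length(offsets) != K)
    stopf("default_mnar_mechanism: need one offset per census category")
  if (overall <= 0 || overall >= 1)
    stopf("default_mnar_mechanism: overall missing fraction must be in (0, 1)")
  f <- function(b) sum(census$proportions * stats::plogis(b + offsets)) - overall
  base <- stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
  mnar_mechanism(stats::setNames(stats::plogis(base + offsets), census$labels))
}

#' Default generating effects for the outcome model
#'
#' Per-level log odds ratios used by [assign_outcome()]. The defaults are the
#' adjusted odds ratios reported for the London THIN 2013 cross-section
#' (ethnicity, sex, 10-year age group and Townsend deprivation quintile, with
#' references White, men, 40-49 and quintile 1), so that cohorts simulated
#' with them carry realistic effect sizes.
#'
#' @return a named list of named numeric vectors on the log-odds scale, one
#'   per covariate, each with 0 at the reference level.
#' @export
default_true_log_odds <- function() {
  list(
    ethnicity = log(c(White = 1, Asian = 2.36, Black = 1.65, `Mixed/Other` = 1.17)),
    sex = log(c(Men = 1, Women = 0.77)),
    age_group = log(c(`0-9` = 0.01, `10-19` = 0.03, `20-29` = 0.12,
                      `30-39` = 0.33, `40-49` = 1, `50-59` = 2.52,
                      `60-69` = 4.93, `70-79` = 7.49, `80+` = 7.62)),
    deprivation = log(c(Q1 = 1, Q2 = 1.12, Q3 = 1.25, Q4 = 1.47, Q5 = 1.86))
  )
}

.default_sex_marginal <- function() c(Men = 0.49, Women = 0.51)

.default_age_marginal <- function() {
  stats::setNames(c(0.103, 0.113, 0.124, 0.162, 0.160, 0.132, 0.098, 0.063, 0.045),
                  age_levels())
}

.default_deprivation_marginal <- function() {
  stats::setNames(c(0.121, 0.160, 0.251, 0.254, 0.214), deprivation_levels())
}

.check_marginal <- function(x, what, levels = NULL) {
  if (is.null(names(x)) && !is.null(levels)) names(x) <- levels
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("invalid proportions in %s: values must lie in [0, 1]", what)
  if (abs(sum(x) - 1) > 1e-12)
    stopf("invalid proportions in %s: must sum to 1 within 1e-12 (got %.15g)",
          what, sum(x))
  x
}

#' Configuration of a synthetic primary-care cohort
#'
#' Bundles everything the generator needs: cohort size, demographic
#' marginals, the census ethnicity distribution, generating log-odds for the
#' type 2 diabetes outcome, the target overall prevalence, the MNAR
#' missingness mechanism for ethnicity, the index date and the random seed.
#'
#' @param n_individuals number of individuals (positive integer).
#' @param census a [census_targets()] distribution from which ethnicity is
#'   sampled (its marginal expectation).
#' @param sex_marginal,age_marginal,deprivation_marginal named proportion
#'   vectors over the sex (2), age-group (9) and deprivation-quintile (5)
#'   levels; each must sum to 1 within 1e-12.
#' @param true_log_odds list of per-level log odds ratios for the outcome
#'   model (see [default_true_log_odds()]).
#' @param target_overall_prevalence population-averaged outcome prevalence in
#'   (0, 1); the model intercept is root-found to achieve it.
#' @param missingness an [mnar_mechanism()] for ethnicity.
#' @param index_date the cross-sectional index date (default 2013-01-01).
#' @param eligible_fraction fraction of individuals whose registration date
#'   satisfies the 12-month rule at the index date (default 1).
#' @param decoy_fraction fraction of outcome-negative individuals who receive
#'   a single-record-type event stream, exercising the negative branch of the
#'   case-ascertainment rule (default 0.1).
#' @param ethnicity_dep_assoc optional association knob: per-quintile
#'   multiplicative tilt, on the log scale and centred at the mean quintile,
#'   applied to the non-White category weights (default 0 = independence).
#' @param seed integer random seed; [simulate_cohort()] seeds from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals,
                              census = default_census_targets(),
                              sex_marginal = .default_sex_marginal(),
                              age_marginal = .default_age_marginal(),
                              deprivation_marginal = .default_deprivation_marginal(),
                              true_log_odds = default_true_log_odds(),
                              target_overall_prevalence = 0.055,
                              missingness = default_mnar_mechanism(census),
                              index_date = as.Date("2013-01-01"),
                              eligible_fraction = 1,
                              decoy_fraction = 0.1,
                              ethnicity_dep_assoc = 0,
                              seed = 1L) {
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L)
    stopf("simulation_config: n_individuals must be a positive integer")
  stopifnot(inherits(census, "census_targets"),
            inherits(missingness, "mnar_mechanism"))
  sex_marginal <- .check_marginal(sex_marginal, "sex_marginal", sex_levels())
  age_marginal <- .check_marginal(age_marginal, "age_marginal", age_levels())
  deprivation_marginal <- .check_marginal(deprivation_marginal,
                                          "deprivation_marginal",
                                          deprivation_levels())
  if (!is.numeric(target_overall_prevalence) ||
      target_overall_prevalence <= 0 || target_overall_prevalence >= 1)
    stopf("simulation_config: target_overall_prevalence must lie strictly in (0, 1)")
  if (!setequal(names(missingness$prob_missing), census$labels))
    stopf("simulation_config: missingness categories [%s] do not match census labels [%s]",
          paste(names(missingness$prob_missing), collapse = ", "),
          paste(census$labels, collapse = ", "))
  for (v in c("ethnicity", "sex", "age_group", "deprivation")) {
    if (is.null(true_log_odds[[v]]) || any(!is.finite(true_log_odds[[v]])))
      stopf("simulation_config: true_log_odds$%s must be a finite named vector", v)
  }
  if (eligible_fraction < 0 || eligible_fraction > 1 ||
      decoy_fraction < 0 || decoy_fraction > 1)
    stopf("simulation_config: eligible_fraction and decoy_fraction must lie in [0, 1]")
  structure(list(
    n_individuals = n_individuals,
    census = census,
    sex_marginal = sex_marginal,
    age_marginal = age_marginal,
    deprivation_marginal = deprivation_marginal,
    true_log_odds = true_log_odds,
    target_overall_prevalence = target_overall_prevalence,
    missingness = missingness,
    index_date = as.Date(index_date),
    eligible_fraction = eligible_fraction,
    decoy_fraction = decoy_fraction,
    ethnicity_dep_assoc = ethnicity_dep_assoc,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort configuration: n = %s, index date %s, seed %d\n",
              format(x$n_individuals, big.mark = ","),
              format(x$index_date), x$seed))
  cat(sprintf("  target prevalence %.3f, overall missingness ~%.3f\n",
              x$target_overall_prevalence,
              sum(x$census$proportions *
                    x$missingness$prob_missing[x$census$labels])))
  print(x$census)
  invisible(x)
}
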