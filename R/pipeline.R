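#' Run the full analysis pipeline
#'
#' Chains the stages — simulate (or load) a cohort, apply eligibility,
#' ascertain cases from the event stream, run calibrated-delta multiple
#' imputation, fit and pool the adjusted logistic regression — and writes
#' all artifacts (CSV/JSON) plus a reproducibility manifest to `out_dir`.
#' Any stage failure is re-signalled with the stage named in the message.
#'
#' @param config a [simulation_config()], a named list of its arguments, or
#'   a path to a YAML/JSON file holding them.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the config seed.
#' @param m_imputations number of imputations (default 10).
#' @param targets [census_targets()] used for calibration; defaults to the
#'   config's census distribution (in a real analysis, supply the census of
#'   the catchment population here).
#' @param ridge optional ridge penalty forwarded to the model fits (useful
#'   at small cohort sizes where rare covariate cells can separate).
#' @param compare also run the four-strategy comparison and write it
#'   (default `FALSE`; substantially slower).
#' @param verbose log stage progress and exclusion counts to stderr.
#' @return invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, m_imputations = 10L,
                         targets = NULL, ridge = 0, compare = FALSE,
                         verbose = TRUE) {
  log_ <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  cfg <- stage("config", .as_simulation_config(config, seed))
  if (is.null(targets)) targets <- cfg$census
  if (!inherits(targets, "census_targets")) targets <- census_targets(unlist(targets))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  files <- list()

  log_("simulate: n = %d, seed = %d", cfg$n_individuals, cfg$seed)
  sim <- stage("simulate", simulate_cohort(cfg))
  utils::write.csv(sim$cohort, fp("cohort.csv"), row.names = FALSE, na = "")
  utils::write.csv(sim$events, fp("events.csv"), row.names = FALSE)
  files$cohort <- fp("cohort.csv"); files$events <- fp("events.csv")

  elig <- stage("eligibility",
                apply_eligibility(sim$cohort, eligibility_rule(cfg$index_date)))
  excl <- attr(elig, "exclusions")
  log_("eligibility: retained %d (excluded: %s)", excl[["retained"]],
       paste(names(excl)[1:3], excl[1:3], sep = "=", collapse = ", "))
  jsonlite::write_json(as.list(excl), fp("exclusions.json"), auto_unbox = TRUE)
  files$exclusions <- fp("exclusions.json")

  asc <- stage("ascertain",
               ascertain_cohort(sim$events, cfg$index_date, ids = elig$id))
  utils::write.csv(asc, fp("ascertainment.csv"), row.names = FALSE)
  files$ascertainment <- fp("ascertainment.csv")
  # analysis outcome comes from the case finder, not the generator's latent flag
  elig$t2d <- as.integer(asc$is_prevalent_at_index[match(elig$id, asc$individual_id)])
  log_("ascertain: %d prevalent cases (%.2f%%)", sum(elig$t2d),
       100 * mean(elig$t2d))

  tab1 <- stage("summarise", summarize_cohort(elig))
  utils::write.csv(tab1, fp("table1.csv"), row.names = FALSE)
  files$table1 <- fp("table1.csv")

  log_("impute: calibrated-delta MI, M = %d", m_imputations)
  mi <- stage("impute", run_mi(elig, "calibrated", M = m_imputations,
                               targets = targets, ridge = ridge))
  imp_long <- do.call(rbind, lapply(seq_len(mi$M), function(m)
    data.frame(individual_id = elig$id[mi$missing_index],
               imputation_index = m,
               ethnicity = as.character(mi$imputations[[m]][mi$missing_index]))))
  utils::write.csv(imp_long, fp("imputations.csv"), row.names = FALSE)
  files$imputations <- fp("imputations.csv")

  pooled <- stage("analyse", {
    fits <- lapply(seq_len(mi$M), function(m)
      fit_logistic(completed_cohort(elig, mi, m), ridge = ridge))
    pool_rubin(fits)
  })
  crude <- stage("analyse", crude_prevalence(mi, elig))
  tab2 <- .table2(crude, pooled)
  utils::write.csv(tab2, fp("table2.csv"), row.names = FALSE)
  files$table2 <- fp("table2.csv")

  if (compare) {
    cmp <- stage("compare", compare_strategies(elig, targets, M = m_imputations,
                                           ridge = ridge))
    utils::write.csv(cmp, fp("strategy_comparison.csv"), row.names = FALSE)
    files$strategy_comparison <- fp("strategy_comparison.csv")
  }

  manifest <- .manifest(cfg, m_imputations,
                        stages = list(simulated = nrow(sim$cohort),
                                      events = nrow(sim$events),
                                      eligible = nrow(elig),
                                      prevalent_cases = sum(elig$t2d),
                                      imputations = mi$M))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  files$manifest <- fp("manifest.json")
  log_("done: %d files in %s", length(files), out_dir)
  invisible(files)
}

.as_simulation_config <- function(config, seed = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!inherits(config, "simulation_config")) {
    args <- config
    if (!is.null(args$census) && !inherits(args$census, "census_targets"))
      args$census <- census_targets(unlist(args$census))
    if (!is.null(args$missingness) && !inherits(args$missingness, "mnar_mechanism"))
      args$missingness <- mnar_mechanism(unlist(args$missingness))
    if (!is.null(args$index_date)) args$index_date <- as.Date(args$index_date)
    for (nm in c("sex_marginal", "age_marginal", "deprivation_marginal"))
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    if (!is.null(args$true_log_odds))
      args$true_log_odds <- lapply(args$true_log_odds, unlist)
    config <- do.call(simulation_config, args)
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  config
}

# Stable manifest: the hash covers config, seed and row counts, but not the
# wall-clock timestamp, so re-runs of the same configuration agree.
.manifest <- function(cfg, m_imputations, stages) {
  cfg_stable <- list(
    n_individuals = cfg$n_individuals,
    census = stats::setNames(as.list(cfg$census$proportions), cfg$census$labels),
    sex_marginal = as.list(cfg$sex_marginal),
    age_marginal = as.list(cfg$age_marginal),
    deprivation_marginal = as.list(cfg$deprivation_marginal),
    true_log_odds = lapply(cfg$true_log_odds, as.list),
    target_overall_prevalence = cfg$target_overall_prevalence,
    missingness = as.list(cfg$missingness$prob_missing),
    index_date = format(cfg$index_date),
    eligible_fraction = cfg$eligible_fraction,
    decoy_fraction = cfg$decoy_fraction,
    seed = cfg$seed,
    m_imputations = m_imputations
  )
  config_hash <- .json_md5(cfg_stable)
  manifest_hash <- .json_md5(list(config_hash = config_hash, stages = stages))
  list(package = "calmi",
       version = as.character(utils::packageVersion("calmi")),
       seed = cfg$seed,
       config_hash = config_hash,
       stages = stages,
       manifest_hash = manifest_hash,
       created = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

.json_md5 <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Assemble a prevalence-and-OR table: one row per covariate level, crude
# prevalence with CI plus the adjusted OR (reference levels shown as OR 1).
.table2 <- function(crude, pooled) {
  var_cols <- c(ethnicity = "ethnicity", sex = "sex", age_group = "age_group",
                deprivation = "deprivation")
  or <- rep(NA_real_, nrow(crude)); or_lo <- or; or_hi <- or
  for (i in seq_len(nrow(crude))) {
    v <- crude$variable[i]; lev <- crude$level[i]
    term <- paste0(var_cols[[v]], lev)
    j <- match(term, pooled$term)
    if (!is.na(j)) {
      or[i] <- pooled$or[j]; or_lo[i] <- pooled$or.low[j]; or_hi[i] <- pooled$or.high[j]
    } else if (lev == .analysis_refs[[v]]) {
      or[i] <- 1
    }
  }
  data.frame(crude, adjusted_or = or, or_conf.low = or_lo, or_conf.high = or_hi)
}
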