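#' Ascertain type 2 diabetes from one individual's coded records
#'
#' Implements the two-of-three rule used for EHR case finding: an individual
#' is a case if records of at least two *distinct* types are present among
#' a diagnostic code, supporting evidence (e.g. retinopathy screening) and a
#' prescribed treatment. The diagnosis date is the earliest record of any of
#' the three types. Two records of the same type do not qualify.
#'
#' @param events data.frame of records for a single individual, with columns
#'   `individual_id`, `event_type` (one of [event_types()]) and `event_date`.
#' @return a one-row data.frame with `individual_id`, `is_case`,
#'   `diagnosis_date` (`NA` unless a case).
#' @export
#' @examples
#' ev <- data.frame(individual_id = 1,
#'                  event_type = c("diagnostic_code", "treatment"),
#'                  event_date = as.Date(c("2010-05-01", "2011-02-01")))
#' ascertain_t2d(ev)
ascertain_t2d <- function(events) {
  if (nrow(events)) {
    ids <- unique(events$individual_id)
    if (length(ids) > 1L)
      stopf("ascertain_t2d: events belong to %d individuals; supply one at a time (or use ascertain_cohort)",
            length(ids))
    .check_event_types(events$event_type)
  }
  is_case <- nrow(events) > 0L && length(unique(events$event_type)) >= 2L
  data.frame(
    individual_id = if (nrow(events)) events$individual_id[1L] else NA_integer_,
    is_case = is_case,
    diagnosis_date = if (is_case) min(as.Date(events$event_date)) else as.Date(NA)
  )
}

.check_event_types <- function(x) {
  bad <- setdiff(unique(x), event_types())
  if (length(bad))
    stopf("unknown event type(s): %s (expected one of %s)",
          paste(bad, collapse = ", "), paste(event_types(), collapse = ", "))
  invisible(TRUE)
}

#' Flag prevalent cases at an index date
#'
#' A case is prevalent at the index date when its diagnosis date falls on or
#' before that date (inclusive boundary).
#'
#' @param result data.frame from [ascertain_t2d()] (one or more rows).
#' @param index_date the cross-sectional index date.
#' @return `result` with a logical `is_prevalent_at_index` column.
#' @export
flag_prevalent <- function(result, index_date) {
  index_date <- as.Date(index_date)
  result$is_prevalent_at_index <-
    result$is_case & !is.na(result$diagnosis_date) &
    result$diagnosis_date <= index_date
  result
}

#' Ascertain cases for a whole cohort
#'
#' Vectorised application of [ascertain_t2d()] and [flag_prevalent()] over an
#' event stream. Individuals in `ids` with no events are returned as
#' non-cases.
#'
#' @param events event data.frame (`individual_id`, `event_type`,
#'   `event_date`) for many individuals.
#' @param index_date index date for the prevalence flag.
#' @param ids optional vector of all individual ids to report on (defaults to
#'   the ids present in `events`).
#' @return a data.frame with one row per id: `individual_id`, `is_case`,
#'   `diagnosis_date`, `is_prevalent_at_index`.
#' @export
ascertain_cohort <- function(events, index_date, ids = NULL) {
  if (nrow(events)) .check_event_types(events$event_type)
  ids <- ids %||% sort(unique(events$individual_id))
  if (nrow(events)) {
    f <- factor(events$individual_id)
    ntypes <- tapply(events$event_type, f, function(x) length(unique(x)))
    dmin <- as.Date(tapply(as.integer(as.Date(events$event_date)), f, min),
                    origin = "1970-01-01")
    ev_ids <- levels(f)
  } else {
    ntypes <- integer(0); dmin <- as.Date(integer(0), origin = "1970-01-01")
    ev_ids <- character(0)
  }
  m <- match(as.character(ids), ev_ids)
  is_case <- as.vector(!is.na(m) & ntypes[m] >= 2L)
  is_case[is.na(is_case)] <- FALSE
  diagnosis_date <- as.Date(as.vector(ifelse(is_case, as.integer(dmin[m]),
                                             NA_integer_)),
                            origin = "1970-01-01")
  flag_prevalent(
    data.frame(individual_id = ids, is_case = unname(is_case),
               diagnosis_date = diagnosis_date),
    index_date
  )
}

#' Eligibility rule for the cross-sectional sample
#'
#' @param index_date the index date (default 2013-01-01).
#' @param minimum_registration_months minimum registration tenure, in whole
#'   calendar months, required by the index date (default 12).
#' @param require_complete columns that must be non-missing (default age
#'   group, sex and deprivation; ethnicity may remain missing and is handled
#'   by imputation).
#' @return an object of class `eligibility_rule`.
#' @export
eligibility_rule <- function(index_date = as.Date("2013-01-01"),
                             minimum_registration_months = 12L,
                             require_complete = c("age_group", "sex", "deprivation")) {
  minimum_registration_months <- as.integer(minimum_registration_months)
  if (is.na(minimum_registration_months) || minimum_registration_months < 0L)
    stopf("eligibility_rule: minimum_registration_months must be >= 0")
  structure(list(index_date = as.Date(index_date),
                 minimum_registration_months = minimum_registration_months,
                 require_complete = require_complete),
            class = "eligibility_rule")
}

#' Apply the eligibility rule to a cohort
#'
#' Retains individuals who are actively registered at the index date, were
#' registered at least `minimum_registration_months` calendar months before
#' it, and are complete on the required columns. Row order is preserved and
#' sequential per-filter exclusion counts are attached as the `"exclusions"`
#' attribute.
#'
#' @param cohort cohort data.frame with `registration_start`,
#'   `registration_end` and the required columns.
#' @param rule an [eligibility_rule()].
#' @return the filtered cohort, with attribute `"exclusions"` (named integer
#'   vector: `not_active_at_index`, `registered_under_minimum`,
#'   `incomplete_covariates`, `retained`).
#' @export
apply_eligibility <- function(cohort, rule = eligibility_rule()) {
  stopifnot(inherits(rule, "eligibility_rule"))
  need <- c("registration_start", "registration_end", rule$require_complete)
  absent <- setdiff(need, names(cohort))
  if (length(absent))
    stopf("apply_eligibility: cohort lacks column(s): %s", paste(absent, collapse = ", "))
  idx <- rule$index_date
  start <- as.Date(cohort$registration_start)
  end <- as.Date(cohort$registration_end)
  active <- !is.na(start) & start <= idx & (is.na(end) | end >= idx)
  cutoff <- add_months(idx, -rule$minimum_registration_months)
  tenured <- !is.na(start) & start <= cutoff
  complete <- !Reduce(`|`, lapply(cohort[rule$require_complete], is.na))
  keep <- active & tenured & complete
  out <- cohort[keep, , drop = FALSE]
  attr(out, "exclusions") <- c(
    not_active_at_index = sum(!active),
    registered_under_minimum = sum(active & !tenured),
    incomplete_covariates = sum(active & tenured & !complete),
    retained = sum(keep)
  )
  out
}

#' Descriptive summary of a cohort
#'
#' Per-variable level counts and percentages of the cohort total (one
#' decimal place), in the style of a baseline characteristics table.
#' Ethnicity gets an explicit "Missing" level; a type 2 diabetes row is
#' added when the outcome column is present.
#'
#' @param cohort a non-empty cohort data.frame.
#' @return a data.frame with columns `variable`, `level`, `n`, `pct`.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0L)
    stopf("summarize_cohort: cannot summarise an empty cohort")
  N <- nrow(cohort)
  rows <- list()
  for (v in intersect(c("sex", "age_group", "deprivation", "ethnicity"),
                      names(cohort))) {
    x <- cohort[[v]]
    counts <- table(x)
    lev <- names(counts); n <- as.integer(counts)
    if (anyNA(x)) { lev <- c(lev, "Missing"); n <- c(n, sum(is.na(x))) }
    rows[[v]] <- data.frame(variable = v, level = lev, n = n)
  }
  if (!is.null(cohort$t2d))
    rows$t2d <- data.frame(variable = "type_2_diabetes", level = "Cases",
                           n = sum(cohort$t2d == 1L, na.rm = TRUE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$pct <- round(100 * out$n / N, 1)
  out
}
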