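#' Published descriptive counts for the London THIN 2013 cross-section
#'
#' Level counts of the demographic and outcome variables for the 404,318
#' individuals actively registered with London general practices
#' contributing to The Health Improvement Network (THIN) on 1 January 2013,
#' as published for that cohort. These counts serve two purposes: they are
#' the reference marginals behind the simulator defaults, and they let
#' worked-example percentages (e.g. the share of women, or the fraction with
#' missing ethnicity) be recomputed from printed numerators and the printed
#' denominator.
#'
#' @return a data.frame with columns `variable`, `level`, `n`; the cohort
#'   total (404,318) is attached as attribute `"total"`.
#' @export
thin_london_2013_counts <- function() {
  out <- data.frame(
    variable = c(rep("sex", 2L), rep("age_group", 9L), rep("deprivation", 5L),
                 rep("ethnicity", 5L), "type_2_diabetes"),
    level = c("Men", "Women",
              "0-9", "10-19", "20-29", "30-39", "40-49", "50-59", "60-69",
              "70-79", "80+",
              "Q1", "Q2", "Q3", "Q4", "Q5",
              "White", "Asian", "Black", "Mixed/Other", "Missing",
              "Cases"),
    n = c(198301L, 206017L,
          41601L, 45664L, 50065L, 65695L, 64837L, 53272L, 39427L, 25348L,
          18409L,
          48934L, 64788L, 101305L, 102626L, 86665L,
          224403L, 35027L, 30771L, 19483L, 94634L,
          22100L)
  )
  attr(out, "total") <- 404318L
  out
}
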