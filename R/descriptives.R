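# Descriptive tables over the clean case set: demographics by period,
# outcome counts, country counts.

.period_labels <- c(PRE = "2017-2019", POST = "2020-2024", ALL = "2017-2024")

.sex_levels <- c("F", "M", "UNK")

dimension_values <- function(cases, dimension) {
  switch(dimension,
    sex = factor(cases$sex, levels = .sex_levels),
    age_group = cases$age_group,
    occupation_group = cases$occupation_group,
    country = {
      v <- cases$country
      v[is.na(v)] <- "Unknown"
      lev <- sort(unique(v[v != "Unknown"]))
      factor(v, levels = c(lev, "Unknown"))
    },
    stop("unknown dimension: ", dimension)
  )
}

freq_one_stratum <- function(cases, dimension, label) {
  n_total <- nrow(cases)
  if (dimension == "outcome") {
    codes <- factor(unlist(cases$outcomes), levels = .outc_codes)
    counts <- table(codes)
  } else {
    counts <- table(dimension_values(cases, dimension))
  }
  dt <- data.table::data.table(
    stratum = label,
    category = names(counts),
    count = as.integer(counts)
  )
  dt[, percent := if (n_total == 0L) NA_real_ else
       round_half_up(100 * count / n_total, 1)]
  dt[, n_cases := n_total]
  dt[]
}

#' Tabulate the case set along one dimension
#'
#' Counts and percentages by category, per study period and pooled. The
#' percentage denominator is always the number of cases in the stratum; for
#' the multi-valued `outcome` dimension a report with several outcome codes
#' contributes to each code's count but only once to the denominator, so
#' outcome percentages need not sum to 100.
#'
#' Percentages are rounded half-away-from-zero to 1 decimal. An empty
#' stratum yields zero counts with missing (`NA`) percentages.
#'
#' @param cases clean case table from [build_cases()] (typically pre-filtered
#'   to the analysis set, e.g. TIN cases with statin as primary suspect).
#' @param dimension one of `"sex"`, `"age_group"`, `"occupation_group"`,
#'   `"outcome"`, `"country"`.
#' @param by_period if `TRUE` (default) emit one stratum per study period
#'   (2017–2019, 2020–2024) plus the pooled stratum; if `FALSE`, pooled only.
#' @return data.table with columns `stratum`, `category`, `count`,
#'   `percent`, `n_cases` (the stratum denominator).
#' @export
#' @examples
#' cases <- data.table::data.table(
#'   sex = c(rep("M", 12), rep("F", 3), "UNK"),
#'   period = "PRE", outcomes = list(character(0)))
#' tabulate_cases(cases, "sex", by_period = FALSE)
tabulate_cases <- function(cases,
                           dimension = c("sex", "age_group",
                                         "occupation_group", "outcome",
                                         "country"),
                           by_period = TRUE) {
  dimension <- match.arg(dimension)
  cases <- data.table::as.data.table(cases)
  out <- list(freq_one_stratum(cases, dimension, .period_labels[["ALL"]]))
  if (by_period) {
    out <- c(list(
      freq_one_stratum(cases[period == "PRE"], dimension,
                       .period_labels[["PRE"]]),
      freq_one_stratum(cases[period == "POST"], dimension,
                       .period_labels[["POST"]])), out)
  }
  data.table::rbindlist(out)
}

.outcome_severity <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Most serious outcome of a report
#'
#' Ranks outcome codes by the fixed severity order
#' death > life-threatening > hospitalization > disability > congenital
#' anomaly > required intervention > other.
#'
#' @param outcomes character vector of outcome codes for one report.
#' @return the most serious code, or `NA_character_` for an empty set.
#' @export
outcome_severity_rank <- function(outcomes) {
  outcomes <- outcomes[!is.na(outcomes) & outcomes %in% .outcome_severity]
  if (!length(outcomes)) return(NA_character_)
  .outcome_severity[min(match(outcomes, .outcome_severity))]
}
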