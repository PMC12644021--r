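# Published reference values of the FAERS 2017-2024 statin-TIN
# disproportionality analysis, shipped as in-code constants so that the
# package's conventions (rounding, IC definition, threshold semantics) can
# be checked against the printed numbers without any download.

#' Reference annual signal-detection metrics (statin–TIN, FAERS 2017–2024)
#'
#' The published annual TIN case counts, statin adverse-event report counts
#' and disproportionality metrics for the statin-class tubulointerstitial
#' nephritis analysis. Values are as printed (ROR/PRR/EBGM/IC rounded to 2
#' decimals at source).
#'
#' @return data.table with columns `year`, `tin_cases`, `statin_ades`,
#'   `ror`, `ror_l95`, `ror_u95`, `prr`, `ebgm`, `ic`.
#' @export
tin_annual_reference <- function() {
  data.table::data.table(
    year = 2017:2024,
    tin_cases = c(5L, 9L, 2L, 12L, 17L, 16L, 17L, 42L),
    statin_ades = c(7646L, 9639L, 12089L, 10088L, 7656L, 6976L, 7754L, 8503L),
    ror = c(0.80, 0.41, 0.07, 1.13, 2.08, 2.89, 2.40, 5.77),
    ror_l95 = c(0.33, 0.21, 0.017, 0.64, 1.29, 1.76, 1.49, 4.24),
    ror_u95 = c(1.92, 0.80, 0.27, 2.00, 3.35, 4.74, 3.88, 7.85),
    prr = c(0.80, 0.41, 0.07, 1.13, 2.08, 2.89, 2.40, 5.75),
    ebgm = c(0.81, 0.43, 0.08, 1.13, 2.01, 2.71, 2.30, 5.32),
    ic = c(-0.30, -1.22, -3.55, 0.17, 1.00, 1.44, 1.20, 2.41)
  )
}

#' Reference demographic counts of the statin–TIN cases
#'
#' Published counts of the TIN cases with a statin as primary suspect, by
#' study period (16 cases 2017–2019, 104 cases 2020–2024), for sex, age
#' group, reporter occupation and outcome.
#'
#' @return data.table with columns `dimension`, `category`, `period`
#'   (`"PRE"`/`"POST"`), `count`.
#' @export
tin_demographics_reference <- function() {
  rbind(
    data.table::data.table(
      dimension = "sex",
      category = rep(c("F", "M", "UNK"), 2),
      period = rep(c("PRE", "POST"), each = 3),
      count = c(3L, 12L, 1L, 57L, 32L, 15L)),
    data.table::data.table(
      dimension = "age_group",
      category = rep(c("0-17", "18-40", "41-60", "61-90", ">=90"), 2),
      period = rep(c("PRE", "POST"), each = 5),
      count = c(0L, 0L, 4L, 10L, 1L, 1L, 9L, 6L, 72L, 1L)),
    data.table::data.table(
      dimension = "occupation_group",
      category = rep(c("Unknown/other", "Physician (MD)",
                       "Other healthcare professional", "Pharmacist"), 2),
      period = rep(c("PRE", "POST"), each = 4),
      count = c(2L, 5L, 7L, 2L, 2L, 41L, 45L, 16L)),
    data.table::data.table(
      dimension = "outcome",
      category = c("HO", "LT", "HO", "LT", "DE"),
      period = c("PRE", "PRE", "POST", "POST", "POST"),
      count = c(8L, 1L, 68L, 5L, 1L))
  )
}
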