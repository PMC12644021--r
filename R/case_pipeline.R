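# From raw joined reports to the analysis set: deduplication, latest case
# version, statin primary-suspect exposure, TIN event flag, year stratum.

#' Analysis configuration
#'
#' @param target_pt MedDRA Preferred Term identifying the event of interest
#'   (matched literally after trim/whitespace-collapse/case-fold).
#' @param year_policy which date binds a report to a calendar year:
#'   `"fda_date"` (FDA receipt date, the default — the study window is framed
#'   in terms of submission), `"event_date"`, or `"quarter_file"`. Fallback
#'   chain: policy source, then FDA date, then the quarter file's year.
#' @param window two-element integer vector: first and last calendar year
#'   retained for stratified analysis.
#' @param include_fluvastatin widen the statin class to seven ingredients.
#' @param lexicon a [statin_lexicon()]; built from `include_fluvastatin` when
#'   `NULL`.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(target_pt = "Tubulointerstitial nephritis",
                            year_policy = c("fda_date", "event_date",
                                            "quarter_file"),
                            window = c(2017L, 2024L),
                            include_fluvastatin = FALSE,
                            lexicon = NULL) {
  year_policy <- match.arg(year_policy)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  structure(list(
    target_pt = target_pt, year_policy = year_policy,
    window = as.integer(window),
    include_fluvastatin = include_fluvastatin,
    lexicon = lexicon %||% statin_lexicon(include_fluvastatin)
  ), class = "analysis_config")
}

pt_fingerprint <- function(pts) {
  vapply(pts, function(p) {
    paste(sort(unique(normalize_pt(p))), collapse = "\x1f")
  }, character(1))
}

# sortable key for PRIMARYID tie-breaks: monotone in the numeric value for
# numeric ids, deterministic lexicographic order otherwise
pid_sort_key <- function(primaryid) {
  paste0(sprintf("%08d", nchar(primaryid)), primaryid)
}

#' Deduplicate joined reports
#'
#' Two passes, in the order the case-cleaning procedure prescribes:
#' \enumerate{
#'   \item exact duplicates on (PRIMARYID, EVENT_DT, PT-set fingerprint) are
#'     collapsed to a single record;
#'   \item among records sharing a CASEID, only the one with the largest
#'     CASEVERSION is retained (a missing version counts as 0; ties are broken
#'     toward the larger PRIMARYID, the later submission identifier).
#' }
#'
#' @param reports joined reports from [join_families()] / [bind_reports()].
#' @return the retained reports; attribute `dedup_audit` holds
#'   `input`, `retained` and removal counts by reason (`exact_dup`,
#'   `superseded_version`). Deduplication is idempotent.
#' @export
deduplicate <- function(reports) {
  dt <- data.table::as.data.table(reports)
  n_in <- nrow(dt)
  if (n_in == 0L) {
    data.table::setattr(dt, "dedup_audit", list(
      input = 0L, retained = 0L,
      removed = c(exact_dup = 0L, superseded_version = 0L)))
    return(dt[])
  }
  fp <- pt_fingerprint(dt$pts)
  key <- paste(dt$primaryid,
               data.table::fifelse(is.na(dt$event_dt), "", dt$event_dt),
               fp, sep = "\x1e")
  exact_dup <- duplicated(key)
  dt <- dt[!exact_dup]

  dt[, `:=`(
    .cv = data.table::fifelse(is.na(caseversion), 0L, caseversion),
    .pk = pid_sort_key(primaryid))]
  keep_idx <- dt[, {
    if (is.na(caseid[1L]) || .N == 1L) .I
    else .I[order(.cv, .pk)][.N]
  }, by = caseid]$V1
  keep_idx <- sort(keep_idx)
  superseded <- nrow(dt) - length(keep_idx)
  dt <- dt[keep_idx]
  dt[, c(".cv", ".pk") := NULL]

  data.table::setattr(dt, "dedup_audit", list(
    input = n_in, retained = nrow(dt),
    removed = c(exact_dup = sum(exact_dup),
                superseded_version = superseded)))
  dt[]
}

#' @rdname deduplicate
#' @param x output of [deduplicate()] (or [build_cases()]).
#' @export
dedup_audit <- function(x) attr(x, "dedup_audit")

#' Flag statin primary-suspect exposure for one report
#'
#' A report is statin-exposed for the case/non-case analysis only when some
#' drug with role code `PS` (Primary Suspect) classifies as a statin;
#' suspect-secondary and concomitant statins do not count. Ingredients are
#' collected from PS drugs only.
#'
#' @param drug_roles,drug_names,drug_ais character vectors describing the
#'   report's drug rows (parallel vectors).
#' @param lexicon a [statin_lexicon()].
#' @return list with `is_statin_ps` (logical) and `statin_ingredients`
#'   (character vector of canonical names, possibly empty).
#' @export
flag_exposure <- function(drug_roles, drug_names, drug_ais,
                          lexicon = statin_lexicon()) {
  ps <- !is.na(drug_roles) & drug_roles == "PS"
  ing <- character(0)
  if (any(ps)) {
    hits <- mapply(function(nm, ai) classify_statin(nm, ai, lexicon),
                   drug_names[ps], drug_ais[ps], USE.NAMES = FALSE)
    ing <- sort(unique(hits[!is.na(hits)]))
  }
  list(is_statin_ps = length(ing) > 0L, statin_ingredients = ing)
}

#' Flag the event of interest for one report
#'
#' @param pts character vector of the report's reaction PTs.
#' @param target_pt the PT to look for (default the TIN Preferred Term).
#' @return `TRUE` iff the target PT is present under case-insensitive,
#'   whitespace-normalized comparison. No synonym expansion.
#' @export
flag_event <- function(pts, target_pt = "Tubulointerstitial nephritis") {
  normalize_pt(target_pt) %in% normalize_pt(pts)
}

#' Assign a calendar year to each report
#'
#' @param event_dt,fda_dt partial date strings (YYYY, YYYYMM or YYYYMMDD).
#' @param src_year year of the quarter file the report came from.
#' @param policy see [analysis_config()].
#' @return integer vector of years (`NA` when no source resolves).
#' @export
assign_year <- function(event_dt, fda_dt, src_year,
                        policy = c("fda_date", "event_date", "quarter_file")) {
  policy <- match.arg(policy)
  fda_y <- year_of_date(fda_dt)
  out <- switch(policy,
    fda_date = fda_y,
    event_date = {
      ev <- year_of_date(event_dt)
      data.table::fifelse(is.na(ev), fda_y, ev)
    },
    quarter_file = as.integer(src_year)
  )
  out <- data.table::fifelse(is.na(out), fda_y, out)
  data.table::fifelse(is.na(out), as.integer(src_year), out)
}

.age_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                 DY = 1 / 365.25, HR = 1 / 8766)

#' Normalize an age to years
#'
#' FAERS ages carry a unit code: decades (DEC), years (YR), months (MON),
#' weeks (WK), days (DY) or hours (HR). A missing unit is interpreted as
#' years (the dominant convention in the source files); an unrecognized unit
#' yields `NA`.
#'
#' @param age numeric age values (non-negative).
#' @param age_cod unit codes.
#' @return numeric vector of ages in years.
#' @export
normalize_age <- function(age, age_cod) {
  age <- as.numeric(age)
  code <- toupper(as.character(age_cod))
  code[is.na(code) | code == ""] <- "YR"
  f <- .age_factor[code]
  out <- age * as.numeric(f)
  out[!is.na(age) & age < 0] <- NA_real_
  out
}

.age_group_levels <- c("0-17", "18-40", "41-60", "61-90", ">=90", "unknown")

#' Group ages in years into the reporting age bands
#'
#' Inclusive integer-year bands 0–17, 18–40, 41–60, 61–90, with ages above
#' 90 in the open top band (labelled `>=90` as in the published tables).
#'
#' @param age_years numeric ages in years.
#' @return factor with levels `r paste(faersignal:::.age_group_levels, collapse = ", ")`.
#' @export
group_age <- function(age_years) {
  fa <- floor(as.numeric(age_years))
  out <- rep("unknown", length(fa))
  out[!is.na(fa) & fa >= 0 & fa <= 17] <- "0-17"
  out[!is.na(fa) & fa >= 18 & fa <= 40] <- "18-40"
  out[!is.na(fa) & fa >= 41 & fa <= 60] <- "41-60"
  out[!is.na(fa) & fa >= 61 & fa <= 90] <- "61-90"
  out[!is.na(fa) & fa > 90] <- ">=90"
  factor(out, levels = .age_group_levels)
}

.occupation_levels <- c("Physician (MD)", "Pharmacist",
                        "Other healthcare professional", "Unknown/other")

#' Group reporter occupation codes
#'
#' `MD` maps to Physician, `PH` to Pharmacist, `OT`/`HP`/`RN` to other
#' healthcare professional, and `CN`/`LW`/missing to Unknown/other.
#'
#' @param occ_cod character vector of occupation codes.
#' @return factor with the four reporting groups.
#' @export
group_occupation <- function(occ_cod) {
  code <- toupper(as.character(occ_cod))
  out <- rep("Unknown/other", length(code))
  out[!is.na(code) & code == "MD"] <- "Physician (MD)"
  out[!is.na(code) & code == "PH"] <- "Pharmacist"
  out[!is.na(code) & code %in% c("OT", "HP", "RN")] <-
    "Other healthcare professional"
  factor(out, levels = .occupation_levels)
}

#' Resolve the reporting country
#'
#' The occurrence country is preferred; the reporter country (source of the
#' latest submission) is the fallback.
#'
#' @param occr_country,reporter_country 2-letter country codes or `NA`.
#' @return character vector of resolved codes (`NA` when both are missing).
#' @export
resolve_country <- function(occr_country, reporter_country) {
  out <- toupper(as.character(occr_country))
  rep_c <- toupper(as.character(reporter_country))
  miss <- is.na(out) | out == ""
  out[miss] <- rep_c[miss]
  out[is.na(out) | out == ""] <- NA_character_
  out
}

#' Build the clean analysis case set
#'
#' Runs the full case-cleaning pipeline over joined raw reports:
#' deduplication (exact-key collapse, latest CASEVERSION), statin
#' primary-suspect exposure, target-PT event flag, year assignment and
#' window filtering, and demographic normalization.
#'
#' @param reports joined reports ([bind_reports()] output).
#' @param config an [analysis_config()].
#' @return a data.table with one row per retained report (the `CleanCase`
#'   records): `caseid`, `primaryid`, `year`, `period` (`"PRE"` for
#'   2017–2019, `"POST"` after), `is_statin_ps`, `statin_ingredients`
#'   (list-column), `is_tin`, `pts` (list-column), `sex`, `age_years`,
#'   `age_group`, `occupation_group`, `outcomes` (list-column), `country`.
#'   Attribute `case_audit` carries stage-by-stage counts; attribute
#'   `dedup_audit` the dedup breakdown.
#' @export
build_cases <- function(reports, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  dt <- deduplicate(reports)
  daudit <- dedup_audit(dt)

  n_dedup <- nrow(dt)
  if (n_dedup == 0L) {
    out <- data.table::data.table(
      caseid = character(0), primaryid = character(0), year = integer(0),
      period = character(0), is_statin_ps = logical(0),
      statin_ingredients = list(), is_tin = logical(0), pts = list(),
      sex = character(0), age_years = numeric(0),
      age_group = factor(character(0), levels = .age_group_levels),
      occupation_group = factor(character(0), levels = .occupation_levels),
      outcomes = list(), country = character(0))
    data.table::setattr(out, "dedup_audit", daudit)
    data.table::setattr(out, "case_audit", list(
      input = daudit$input, deduplicated = 0L, no_year = 0L,
      out_of_window = 0L, cases = 0L, removed = daudit$removed))
    return(out[])
  }

  # exposure: unnest PS drugs, classify on unique names (PROD_AI first)
  row_id <- seq_len(nrow(dt))
  ps_list <- lapply(row_id, function(i) {
    roles <- dt$drug_roles[[i]]
    ps <- !is.na(roles) & roles == "PS"
    if (!any(ps)) return(NULL)
    list(.row = rep.int(i, sum(ps)),
         nm = dt$drug_names[[i]][ps], ai = dt$drug_ais[[i]][ps])
  })
  ps_tab <- data.table::rbindlist(ps_list)
  ing <- vector("list", nrow(dt))
  ing[] <- list(character(0))
  if (nrow(ps_tab)) {
    canon_ai <- classify_statin_vec(ps_tab$ai, config$lexicon)
    canon_nm <- classify_statin_vec(ps_tab$nm, config$lexicon)
    ps_tab[, canon := data.table::fifelse(is.na(canon_ai), canon_nm, canon_ai)]
    ing_by_row <- ps_tab[!is.na(canon),
                         .(ing = list(sort(unique(canon)))), by = .row]
    if (nrow(ing_by_row)) ing[ing_by_row$.row] <- ing_by_row$ing
  }

  target_norm <- normalize_pt(config$target_pt)
  is_tin <- vapply(dt$pts, function(p) target_norm %in% normalize_pt(p),
                   logical(1))

  yr <- assign_year(dt$event_dt, dt$fda_dt, dt$src_year, config$year_policy)
  no_year <- is.na(yr)
  in_window <- !no_year & yr >= config$window[1] & yr <= config$window[2]
  out_of_window <- !no_year & !in_window

  sex <- toupper(as.character(dt$sex))
  sex[is.na(sex) | !(sex %in% c("F", "M"))] <- "UNK"
  age_years <- normalize_age(dt$age, dt$age_cod)

  out <- data.table::data.table(
    caseid = dt$caseid, primaryid = dt$primaryid,
    year = yr,
    period = data.table::fifelse(yr <= 2019L, "PRE", "POST"),
    is_statin_ps = lengths(ing) > 0L,
    statin_ingredients = ing,
    is_tin = is_tin,
    pts = dt$pts,
    sex = sex,
    age_years = age_years,
    age_group = group_age(age_years),
    occupation_group = group_occupation(dt$occ_cod),
    outcomes = dt$outcomes,
    country = resolve_country(dt$occr_country, dt$reporter_country)
  )[in_window]

  data.table::setattr(out, "dedup_audit", daudit)
  data.table::setattr(out, "case_audit", list(
    input = daudit$input, deduplicated = n_dedup,
    no_year = sum(no_year), out_of_window = sum(out_of_window),
    cases = nrow(out), removed = daudit$removed))
  out[]
}

#' @rdname build_cases
#' @param x output of [build_cases()].
#' @export
case_audit <- function(x) attr(x, "case_audit")
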