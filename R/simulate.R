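# Synthetic FAERS-format spontaneous-report generator with planted ground
# truth: per-year statin primary-suspect share, a background TIN reporting
# rate, and a planted relative reporting-rate ratio rho(y) of TIN among
# statin-PS reports. Duplicates and multiple case versions are injected so
# the cleaning stages can be scored.

.default_rate_ratio <- c(`2017` = 1, `2018` = 1, `2019` = 1, `2020` = 1,
                         `2021` = 2, `2022` = 3, `2023` = 2.5, `2024` = 6)

#' Simulation configuration
#'
#' The defaults describe the study conditions the generator emulates: eight
#' report-years with a null statin–TIN association before 2021 and an
#' emergent signal after, peaking at a planted reporting-rate ratio of 6 in
#' 2024; elderly-skewed ages; hospitalization-heavy outcomes; a US-dominated
#' country mix.
#'
#' @param seed integer seed; together with the config it fully determines
#'   the output.
#' @param years report years.
#' @param reports_per_year reports per year (scalar or one per year).
#' @param n_background_drugs,n_background_pts size of the background drug
#'   and event vocabularies (sampled with power-law weights).
#' @param statin_share probability that a report has a statin as primary
#'   suspect (scalar or per year).
#' @param tin_background_rate probability that a non-statin report carries
#'   the TIN PT.
#' @param rate_ratio_by_year named vector: planted relative TIN reporting
#'   rate among statin-PS reports, by year. `tin_background_rate *
#'   max(rate_ratio)` must not exceed 1.
#' @param sex_probs,occ_probs,country_probs,outcome_probs category mixes
#'   (named, summing to 1 up to normalization).
#' @param age_mean,age_sd normal age model in years (clipped to 1–100).
#' @param dup_rate fraction of reports duplicated exactly.
#' @param dup_mode `"same_id"` emits the duplicate under the same PRIMARYID
#'   in the next quarter file (exercising the exact dedup key);
#'   `"fresh_id"` emits it under a fresh PRIMARYID sharing CASEID and
#'   CASEVERSION (exercising the version tie-break).
#' @param version_rate fraction of cases emitted with two case versions
#'   (the superseded version-1 record is injected alongside).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       years = 2017:2024,
                       reports_per_year = 5000L,
                       n_background_drugs = 60L,
                       n_background_pts = 150L,
                       statin_share = 0.10,
                       tin_background_rate = 0.008,
                       rate_ratio_by_year = .default_rate_ratio,
                       sex_probs = c(F = 0.50, M = 0.40, UNK = 0.10),
                       occ_probs = c(MD = 0.30, PH = 0.10, OT = 0.18,
                                     HP = 0.15, RN = 0.02, CN = 0.14,
                                     LW = 0.01, UNK = 0.10),
                       country_probs = c(US = 0.45, FR = 0.12, ES = 0.10,
                                         GB = 0.06, DE = 0.06, AU = 0.05,
                                         CA = 0.05, IT = 0.04, JP = 0.03,
                                         BR = 0.02, NL = 0.01, SE = 0.005,
                                         CH = 0.005),
                       outcome_probs = c(HO = 0.35, OT = 0.40, DS = 0.08,
                                         RI = 0.08, LT = 0.05, DE = 0.03,
                                         CA = 0.01),
                       age_mean = 67, age_sd = 15,
                       dup_rate = 0.02,
                       dup_mode = c("same_id", "fresh_id"),
                       version_rate = 0.03) {
  dup_mode <- match.arg(dup_mode)
  years <- as.integer(years)
  reports_per_year <- rep_len(as.integer(reports_per_year), length(years))
  statin_share <- rep_len(statin_share, length(years))
  rr <- rate_ratio_by_year
  if (is.null(names(rr))) names(rr) <- as.character(years)
  missing_years <- setdiff(as.character(years), names(rr))
  if (length(missing_years)) {
    rr[missing_years] <- 1
  }
  rr <- rr[as.character(years)]
  stopifnot(all(rr > 0), all(statin_share >= 0 & statin_share <= 1),
            tin_background_rate >= 0, dup_rate >= 0, dup_rate < 1,
            version_rate >= 0, version_rate < 1)
  if (tin_background_rate * max(rr) > 1) {
    stop("config error: tin_background_rate * max(rate_ratio) exceeds 1")
  }
  norm <- function(p) p / sum(p)
  structure(list(
    seed = as.integer(seed), years = years,
    reports_per_year = reports_per_year,
    n_background_drugs = as.integer(n_background_drugs),
    n_background_pts = as.integer(n_background_pts),
    statin_share = statin_share,
    tin_background_rate = tin_background_rate,
    rate_ratio_by_year = rr,
    sex_probs = norm(sex_probs), occ_probs = norm(occ_probs),
    country_probs = norm(country_probs), outcome_probs = norm(outcome_probs),
    age_mean = age_mean, age_sd = age_sd,
    dup_rate = dup_rate, dup_mode = dup_mode, version_rate = version_rate
  ), class = "sim_config")
}

.statin_forms <- data.frame(
  canonical = c("rosuvastatin", "atorvastatin", "simvastatin",
                "pravastatin", "pitavastatin", "lovastatin"),
  generic = c("ROSUVASTATIN CALCIUM", "ATORVASTATIN CALCIUM", "SIMVASTATIN",
              "PRAVASTATIN SODIUM", "PITAVASTATIN CALCIUM", "LOVASTATIN"),
  brand = c("CRESTOR", "LIPITOR", "ZOCOR", "PRAVACHOL", "LIVALO", "MEVACOR")
)

sample_probs <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic FAERS-format database
#'
#' Draws every report independently: its year, quarter and receipt date; a
#' statin primary suspect with the configured per-year share (otherwise a
#' background drug); the TIN PT with probability
#' `tin_background_rate * rho(year)` for statin-PS reports and
#' `tin_background_rate` otherwise; background PTs, concomitant drugs,
#' demographics and outcomes from the configured mixes. Exact duplicates and
#' superseded case versions are injected per the configured rates, and the
#' planted truth is recorded.
#'
#' @param config a [sim_config()].
#' @return list of class `faers_sim` with elements
#'   \describe{
#'     \item{bundles}{list of [quarter_bundle()] objects (4 per year);}
#'     \item{truth}{list with `rate_ratio` (per-year planted rho), `cells`
#'       (realized per-year `a`, `b`, `c`, `d` among unique reports),
#'       `duplicate_primaryids`, `superseded_primaryids`;}
#'     \item{config}{the config echoed back.}
#'   }
#' @export
#' @examples
#' sim <- simulate_faers(sim_config(seed = 7, years = 2024,
#'                                  reports_per_year = 200))
#' sim$truth$cells
simulate_faers <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n <- sum(config$reports_per_year)
  year <- rep(config$years, config$reports_per_year)
  share <- rep(config$statin_share, config$reports_per_year)
  rho <- rep(as.numeric(config$rate_ratio_by_year), config$reports_per_year)

  quarter <- sample.int(4L, n, replace = TRUE)
  fda_month <- (quarter - 1L) * 3L + sample.int(3L, n, replace = TRUE)
  fda_day <- sample.int(28L, n, replace = TRUE)
  fda_dt <- sprintf("%04d%02d%02d", year, fda_month, fda_day)

  ev_kind <- sample_probs(n, c(full = 0.6, ym = 0.1, y = 0.1, none = 0.2))
  ev_month <- sample.int(12L, n, replace = TRUE)
  ev_day <- sample.int(28L, n, replace = TRUE)
  event_dt <- data.table::fcase(
    ev_kind == "full", sprintf("%04d%02d%02d", year, ev_month, ev_day),
    ev_kind == "ym", sprintf("%04d%02d", year, ev_month),
    ev_kind == "y", sprintf("%04d", year),
    default = NA_character_)

  caseid <- as.character(100000000L + seq_len(n))
  caseversion <- rep(1L, n)

  is_statin <- runif(n) < share
  statin_idx <- sample.int(6L, n, replace = TRUE)
  use_brand <- runif(n) < 0.30
  ps_name <- ifelse(use_brand, .statin_forms$brand[statin_idx],
                    .statin_forms$generic[statin_idx])
  ps_ai <- ifelse(runif(n) < 0.85, .statin_forms$generic[statin_idx],
                  NA_character_)
  bg_drugs <- sprintf("DRUG%03d", seq_len(config$n_background_drugs))
  bg_w <- 1 / seq_len(config$n_background_drugs)
  bg_pick <- sample.int(config$n_background_drugs, n, replace = TRUE,
                        prob = bg_w)
  ps_name[!is_statin] <- bg_drugs[bg_pick[!is_statin]]
  ps_ai[!is_statin] <- ifelse(runif(sum(!is_statin)) < 0.8,
                              paste0(bg_drugs[bg_pick[!is_statin]], " AI"),
                              NA_character_)
  statin_ing <- ifelse(is_statin, .statin_forms$canonical[statin_idx],
                       NA_character_)

  p_tin <- ifelse(is_statin, config$tin_background_rate * rho,
                  config$tin_background_rate)
  is_tin <- runif(n) < p_tin

  # drug rows: PS drug plus 0-3 concomitant/secondary background drugs
  n_con <- sample(0:3, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  con_idx <- rep(seq_len(n), n_con)
  con_name <- bg_drugs[sample.int(config$n_background_drugs, length(con_idx),
                                  replace = TRUE, prob = bg_w)]
  con_role <- sample(c("C", "SS", "I"), length(con_idx), replace = TRUE,
                     prob = c(0.7, 0.2, 0.1))
  drug_long <- data.table::data.table(
    idx = c(seq_len(n), con_idx),
    role_cod = c(rep("PS", n), con_role),
    drugname = c(ps_name, con_name),
    prod_ai = c(ps_ai, ifelse(runif(length(con_idx)) < 0.8,
                              paste0(con_name, " AI"), NA_character_)))
  data.table::setorder(drug_long, idx)
  drug_long[, drug_seq := seq_len(.N), by = idx]

  # reaction rows: the TIN PT where planted, plus 0-3 background PTs
  # (at least one PT per report)
  bg_pts <- sprintf("Background event %03d", seq_len(config$n_background_pts))
  pt_w <- 1 / seq_len(config$n_background_pts)
  n_extra <- pmin(rgeom(n, 0.6), 3L)
  n_extra[!is_tin & n_extra == 0L] <- 1L
  extra_idx <- rep(seq_len(n), n_extra)
  extra_pt <- bg_pts[sample.int(config$n_background_pts, length(extra_idx),
                                replace = TRUE, prob = pt_w)]
  reac_long <- rbind(
    data.table::data.table(idx = which(is_tin),
                           pt = "Tubulointerstitial nephritis"),
    unique(data.table::data.table(idx = extra_idx, pt = extra_pt)))
  data.table::setorder(reac_long, idx, pt)

  # outcomes: 0-2 codes per report
  n_outc <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.55, 0.20))
  outc_idx <- rep(seq_len(n), n_outc)
  outc_cod <- sample_probs(length(outc_idx), config$outcome_probs)
  outc_long <- unique(data.table::data.table(idx = outc_idx,
                                             outc_cod = outc_cod))
  data.table::setorder(outc_long, idx, outc_cod)

  sex <- sample_probs(n, config$sex_probs)
  age_years <- pmin(pmax(round(rnorm(n, config$age_mean, config$age_sd)), 1),
                    100)
  unit_kind <- sample_probs(n, c(YR = 0.90, DEC = 0.04, MON = 0.03,
                                 none = 0.03))
  age <- data.table::fcase(
    unit_kind == "YR", as.numeric(age_years),
    unit_kind == "DEC", round(age_years / 10),
    unit_kind == "MON", as.numeric(age_years * 12L),
    default = NA_real_)
  age_cod <- ifelse(unit_kind == "none", NA_character_, unit_kind)
  occ <- sample_probs(n, config$occ_probs)
  occ[occ == "UNK"] <- NA_character_
  country <- sample_probs(n, config$country_probs)

  base <- data.table::data.table(
    idx = seq_len(n), caseid = caseid, caseversion = caseversion,
    year = year, quarter = quarter, event_dt = event_dt, fda_dt = fda_dt,
    sex = sex, age = age, age_cod = age_cod, occ_cod = occ,
    occr_country = country,
    reporter_country = sample_probs(n, config$country_probs),
    is_statin = is_statin, is_tin = is_tin, statin_ing = statin_ing)

  # inject case versions: selected cases become version 2, with the
  # superseded version-1 record emitted alongside (earlier receipt date)
  n_ver <- round(config$version_rate * n)
  n_dup <- round(config$dup_rate * n)
  pick <- if (n_ver + n_dup > 0) sample.int(n, n_ver + n_dup) else integer(0)
  ver_sel <- pick[seq_len(n_ver)]
  dup_sel <- pick[n_ver + seq_len(n_dup)]

  base[ver_sel, caseversion := 2L]
  base[, primaryid := paste0(caseid, caseversion)]

  superseded <- base[ver_sel][, `:=`(
    caseversion = 1L,
    primaryid = paste0(caseid, 1L),
    fda_dt = sprintf("%04d%02d%02d", year, (quarter - 1L) * 3L + 1L, 1L))]

  duplicates <- base[dup_sel]
  if (config$dup_mode == "same_id") {
    duplicates[, quarter := quarter %% 4L + 1L]
  } else {
    duplicates[, primaryid := paste0(primaryid, "9")]
  }

  all_rec <- rbind(base, superseded, duplicates)
  all_rec[, rec_id := .I]  # unique record key (same_id duplicates share primaryid)

  rec_rows <- function(long, cols) {
    m <- merge(all_rec[, .(idx, rec_id, primaryid)], long, by = "idx",
               allow.cartesian = TRUE)
    data.table::setorder(m, rec_id)
    m[, c("rec_id", "primaryid", cols), with = FALSE]
  }
  drug_all <- rec_rows(drug_long, c("drug_seq", "role_cod", "drugname",
                                    "prod_ai"))
  reac_all <- rec_rows(reac_long, "pt")
  outc_all <- rec_rows(outc_long, "outc_cod")

  demo_cols <- c("primaryid", "caseid", "caseversion", "event_dt", "fda_dt",
                 "sex", "age", "age_cod", "occ_cod", "occr_country",
                 "reporter_country")
  bundles <- list()
  for (y in config$years) {
    for (q in 1:4) {
      sel <- all_rec[year == y & quarter == q]
      data.table::setorder(sel, primaryid)
      rid <- sel$rec_id
      fam <- function(tab) tab[rec_id %in% rid][, !"rec_id"]
      bundles[[sprintf("%dQ%d", y, q)]] <- quarter_bundle(
        y, q,
        demo = sel[, demo_cols, with = FALSE],
        drug = fam(drug_all),
        reac = fam(reac_all),
        outc = fam(outc_all))
    }
  }

  cells <- base[, .(
    a = sum(is_statin & is_tin), b = sum(is_statin & !is_tin),
    c = sum(!is_statin & is_tin), d = sum(!is_statin & !is_tin)),
    by = year][order(year)]

  structure(list(
    bundles = bundles,
    truth = list(
      rate_ratio = config$rate_ratio_by_year,
      cells = cells,
      duplicate_primaryids = duplicates$primaryid,
      superseded_primaryids = superseded$primaryid),
    config = config
  ), class = "faers_sim")
}

#' Calibrate a simulation config to the published report margins
#'
#' Returns a config whose *expected* per-year statin-PS report counts equal
#' the published annual statin adverse-event counts and whose expected
#' statin TIN case counts equal the published annual TIN case counts
#' (see [tin_annual_reference()]): the statin share is set to
#' `statin_ades / reports_per_year` and the planted rate ratio to
#' `tin_cases / (statin_ades * tin_background_rate)`.
#'
#' @param reports_per_year database size per year (must exceed the largest
#'   annual statin count).
#' @param tin_background_rate background TIN reporting probability.
#' @param ... further arguments passed to [sim_config()].
#' @return a [sim_config()]; [expected_margins()] of it reproduces the
#'   published margins exactly.
#' @export
emulate_reference_margins <- function(reports_per_year = 60000L,
                                  tin_background_rate = 0.002, ...) {
  ref <- tin_annual_reference()
  if (reports_per_year <= max(ref$statin_ades)) {
    stop("reports_per_year must exceed the largest annual statin count")
  }
  share <- ref$statin_ades / reports_per_year
  rho <- ref$tin_cases / (ref$statin_ades * tin_background_rate)
  names(rho) <- as.character(ref$year)
  sim_config(years = ref$year, reports_per_year = reports_per_year,
             statin_share = share, tin_background_rate = tin_background_rate,
             rate_ratio_by_year = rho, ...)
}

#' Expected per-year margins of a simulation config
#'
#' @param config a [sim_config()].
#' @return data.table with `year`, `expected_statin_reports` and
#'   `expected_tin_statin_cases` (expectations, no sampling noise).
#' @export
expected_margins <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  data.table::data.table(
    year = config$years,
    expected_statin_reports = config$reports_per_year * config$statin_share,
    expected_tin_statin_cases = config$reports_per_year *
      config$statin_share * config$tin_background_rate *
      as.numeric(config$rate_ratio_by_year))
}
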