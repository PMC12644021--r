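# Fixtures built in code, plus independent oracles used across tests.

fixture_dir <- function() {
  system.file("extdata", "fixtures", package = "faersignal")
}

fixture_paths <- function() {
  d <- fixture_dir()
  list(demo = file.path(d, "DEMO24Q1.txt"),
       drug = file.path(d, "DRUG24Q1.txt"),
       reac = file.path(d, "REAC24Q1.txt"),
       outc = file.path(d, "OUTC24Q1.txt"))
}

# a minimal joined-report row constructor: the columns build_cases()
# and deduplicate() need
make_report <- function(primaryid, caseid = primaryid, caseversion = 1L,
                        event_dt = NA_character_, fda_dt = "20240110",
                        sex = "F", age = 70, age_cod = "YR",
                        occ_cod = "MD", occr_country = "US",
                        reporter_country = "US",
                        roles = "PS", drugs = "ROSUVASTATIN CALCIUM",
                        ais = NA_character_,
                        pts = "Tubulointerstitial nephritis",
                        outcomes = "HO",
                        src_year = 2024L, src_quarter = 1L) {
  data.table::data.table(
    primaryid = primaryid, caseid = caseid,
    caseversion = as.integer(caseversion),
    event_dt = event_dt, fda_dt = fda_dt, sex = sex, age = age,
    age_cod = age_cod, occ_cod = occ_cod, occr_country = occr_country,
    reporter_country = reporter_country,
    drug_roles = list(roles), drug_names = list(drugs),
    drug_ais = list(rep_len(ais, length(drugs))),
    pts = list(pts), outcomes = list(outcomes),
    n_drugs = length(drugs), n_pts = length(pts),
    src_year = as.integer(src_year), src_quarter = as.integer(src_quarter),
    no_drug = length(drugs) == 0L, no_reaction = length(pts) == 0L)
}

make_reports <- function(...) data.table::rbindlist(list(...))

# minimal clean-case constructor for the descriptive/dispro layers
make_cases <- function(n, year = 2024L, period = NULL, sex = "F",
                       age_group = "61-90", occupation_group = "Physician (MD)",
                       outcomes = list("HO"), country = "US",
                       is_statin_ps = TRUE, is_tin = TRUE) {
  period <- period %||% ifelse(year <= 2019, "PRE", "POST")
  data.table::data.table(
    caseid = as.character(seq_len(n)), primaryid = as.character(seq_len(n)),
    year = as.integer(year), period = period,
    is_statin_ps = is_statin_ps,
    statin_ingredients = replicate(n, "rosuvastatin", simplify = FALSE),
    is_tin = is_tin, pts = replicate(n, "Tubulointerstitial nephritis",
                                     simplify = FALSE),
    sex = sex,
    age_years = 70,
    age_group = factor(age_group,
                       levels = c("0-17", "18-40", "41-60", "61-90", ">=90",
                                  "unknown")),
    occupation_group = factor(occupation_group,
                              levels = c("Physician (MD)", "Pharmacist",
                                         "Other healthcare professional",
                                         "Unknown/other")),
    outcomes = rep_len(outcomes, n), country = country)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random valid quarter bundle for round-trip property tests
random_bundle <- function(n = 8, year = 2023L, quarter = 2L,
                          dollar_names = FALSE) {
  pid <- as.character(sample(1e6:2e6, n))
  demo <- data.table::data.table(
    primaryid = pid, caseid = as.character(sample(1e5:2e5, n)),
    caseversion = sample(c(NA, 1:3), n, replace = TRUE),
    event_dt = sample(c(NA, "2023", "202303", "20230312"), n, replace = TRUE),
    fda_dt = sprintf("2023%02d%02d", sample(1:12, n, TRUE), sample(1:28, n, TRUE)),
    sex = sample(c("F", "M", NA), n, TRUE),
    age = round(runif(n, 0, 95), 1), age_cod = sample(c("YR", "DEC", NA), n, TRUE),
    occ_cod = sample(c("MD", "PH", "OT", NA), n, TRUE),
    occr_country = sample(c("US", "FR", NA), n, TRUE),
    reporter_country = sample(c("US", "GB"), n, TRUE))
  nm <- if (dollar_names) "ATORVA$TATIN 20 MG" else "ATORVASTATIN CALCIUM"
  drug <- data.table::data.table(
    primaryid = rep(pid, each = 2), drug_seq = rep(1:2, n),
    role_cod = rep(c("PS", "C"), n),
    drugname = rep(c(nm, "ASPIRIN"), n),
    prod_ai = rep(c("ATORVASTATIN CALCIUM", NA), n))
  reac <- data.table::data.table(
    primaryid = pid,
    pt = sample(c("Tubulointerstitial nephritis", "Rash", "Nausea"), n, TRUE))
  outc <- data.table::data.table(
    primaryid = pid, outc_cod = sample(c("HO", "OT", "DE"), n, TRUE))
  quarter_bundle(year, quarter, demo, drug, reac, outc)
}

# independent EBGM oracle: numerical integration of the posterior of
# ln(lambda) under prior x Poisson likelihood (no digamma, no closed-form Qn)
oracle_posterior_mean_log <- function(n, E, prior) {
  logpost <- function(l) {
    log(prior$w * dgamma(l, prior$alpha1, rate = prior$beta1) +
        (1 - prior$w) * dgamma(l, prior$alpha2, rate = prior$beta2)) +
      dpois(n, l * E, log = TRUE)
  }
  m1 <- (prior$alpha1 + n) / (prior$beta1 + E)
  m2 <- (prior$alpha2 + n) / (prior$beta2 + E)
  C <- max(logpost(m1), logpost(m2))
  hi <- qgamma(1 - 1e-13, prior$alpha1 + n, rate = prior$beta1 + E) +
    qgamma(1 - 1e-13, prior$alpha2 + n, rate = prior$beta2 + E)
  # guard the integrable endpoint singularity at l = 0 (shape < 1 components)
  safe <- function(f) function(l) {
    v <- f(l)
    v[!is.finite(v)] <- 0
    v
  }
  Z <- integrate(safe(function(l) exp(logpost(l) - C)), 0, hi,
                 rel.tol = 1e-12, subdivisions = 2000L)$value
  M <- integrate(safe(function(l) log(l) * exp(logpost(l) - C)), 0, hi,
                 rel.tol = 1e-12, subdivisions = 2000L)$value
  M / Z
}

strip_audit <- function(x) {
  x <- as.data.frame(x)
  for (a in c("audit", "dedup_audit", "case_audit")) attr(x, a) <- NULL
  x
}
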