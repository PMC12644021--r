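test_that("exact duplicates on (PRIMARYID, EVENT_DT, PT set) collapse", {
  r <- make_report("10", event_dt = "20240101",
                   pts = c("Rash", "Tubulointerstitial nephritis"))
  r2 <- make_report("10", event_dt = "20240101",
                    pts = c("Tubulointerstitial nephritis", "Rash"))  # reordered
  dd <- deduplicate(make_reports(r, r2))
  expect_equal(nrow(dd), 1L)
  expect_equal(unname(dedup_audit(dd)$removed["exact_dup"]), 1L)
})

test_that("only the latest CASEVERSION of a case survives", {
  reports <- make_reports(
    make_report("1001", caseid = "100", caseversion = 1),
    make_report("1002", caseid = "100", caseversion = 2),
    make_report("1003", caseid = "100", caseversion = 3))
  dd <- deduplicate(reports)
  expect_equal(dd$primaryid, "1003")
  expect_equal(unname(dedup_audit(dd)$removed["superseded_version"]), 2L)
})

test_that("version ties break toward the larger PRIMARYID; missing version loses", {
  reports <- make_reports(
    make_report("9", caseid = "7", caseversion = 2),
    make_report("11", caseid = "7", caseversion = 2),   # numeric 11 > 9
    make_report("12", caseid = "7", caseversion = NA))
  dd <- deduplicate(reports)
  expect_equal(dd$primaryid, "11")
})

test_that("a mixed 5-report fixture retains 3 with a full audit", {
  reports <- make_reports(
    make_report("1", caseid = "A", caseversion = 1),
    make_report("2", caseid = "A", caseversion = 2),       # supersedes 1
    make_report("3", caseid = "B", event_dt = "20240201"),
    make_report("3", caseid = "B", event_dt = "20240201"), # exact dup of 3
    make_report("4", caseid = "C"))
  dd <- deduplicate(reports)
  aud <- dedup_audit(dd)
  expect_equal(nrow(dd), 3L)
  expect_setequal(dd$primaryid, c("2", "3", "4"))
  expect_equal(unname(aud$removed), c(1L, 1L))
  # conservation: input = retained + removals by reason
  expect_equal(aud$input, aud$retained + sum(aud$removed))
})

test_that("deduplication is idempotent on random report sets", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    reports <- data.table::rbindlist(lapply(seq_len(n), function(i) {
      make_report(as.character(sample(1:15, 1)),
                  caseid = as.character(sample(1:10, 1)),
                  caseversion = sample(c(NA, 1:3), 1),
                  event_dt = sample(c(NA, "2024", "20240101"), 1),
                  pts = sample(c("Rash", "Nausea", "Pyrexia"),
                               sample(1:2, 1)))
    }))
    d1 <- deduplicate(reports)
    d2 <- deduplicate(d1)
    expect_equal(strip_audit(d2), strip_audit(d1))
    expect_equal(dedup_audit(d2)$removed,
                 c(exact_dup = 0L, superseded_version = 0L))
    aud <- dedup_audit(d1)
    expect_equal(aud$input, aud$retained + sum(aud$removed))
  }
})

test_that("statin classification consults PROD_AI first, then DRUGNAME", {
  lex <- statin_lexicon()
  expect_equal(classify_statin("ROSUVASTATIN CALCIUM", NA, lex), "rosuvastatin")
  expect_equal(classify_statin("CRESTOR", "ROSUVASTATIN CALCIUM", lex),
               "rosuvastatin")
  expect_equal(classify_statin("CRESTOR", NA, lex), "rosuvastatin")
  expect_equal(classify_statin("METFORMIN", "METFORMIN HYDROCHLORIDE", lex),
               NA_character_)
  # word-boundary matching: no false hit inside an unrelated name
  expect_equal(classify_statin("NYSTATIN", NA, lex), NA_character_)
  expect_equal(classify_statin("lipitor 20mg tablets", NA, lex),
               "atorvastatin")
})

test_that("fluvastatin is excluded by default and available by switch", {
  expect_equal(classify_statin("LESCOL", "FLUVASTATIN SODIUM",
                               statin_lexicon()), NA_character_)
  expect_equal(classify_statin("LESCOL", "FLUVASTATIN SODIUM",
                               statin_lexicon(include_fluvastatin = TRUE)),
               "fluvastatin")
  expect_length(statin_ingredients(), 6L)
})

test_that("exposure requires the statin in the Primary Suspect role", {
  # statin as secondary suspect only: not exposed
  f <- flag_exposure(c("SS", "PS"), c("CRESTOR", "METFORMIN"),
                     c(NA, NA))
  expect_false(f$is_statin_ps)
  # statin PS + concomitant aspirin: exposed
  f <- flag_exposure(c("PS", "C"), c("CRESTOR", "ASPIRIN"), c(NA, NA))
  expect_true(f$is_statin_ps)
  expect_equal(f$statin_ingredients, "rosuvastatin")
  # two PS statins: both ingredients recorded, report counted once
  f <- flag_exposure(c("PS", "PS"), c("LIPITOR", "CRESTOR"), c(NA, NA))
  expect_true(f$is_statin_ps)
  expect_equal(f$statin_ingredients, c("atorvastatin", "rosuvastatin"))
})

test_that("the event flag matches the target PT literally, normalized", {
  expect_true(flag_event(c("Tubulointerstitial nephritis", "Rash")))
  expect_true(flag_event("TUBULOINTERSTITIAL  NEPHRITIS "))
  expect_false(flag_event("Nephritis allergic"))  # no synonym expansion
})

test_that("year assignment follows the policy with the fallback chain", {
  expect_equal(assign_year(NA, "20240312", 2023, "fda_date"), 2024L)
  expect_equal(assign_year("2019", "20200101", 2020, "event_date"), 2019L)
  expect_equal(assign_year(NA, NA, 2022, "fda_date"), 2022L)
  expect_equal(assign_year(NA, NA, 2022, "event_date"), 2022L)
  expect_equal(assign_year("20190501", "20200101", 2020, "quarter_file"),
               2020L)
})

test_that("ages normalize by unit code and group on the published bands", {
  expect_equal(normalize_age(6, "DEC"), 60)
  expect_equal(normalize_age(720, "MON"), 60)
  expect_equal(normalize_age(52.1775, "WK"), 1)
  expect_equal(normalize_age(365.25, "DY"), 1)
  expect_equal(normalize_age(8766, "HR"), 1)
  expect_true(is.na(normalize_age(50, "XX")))   # unknown unit
  expect_equal(normalize_age(50, NA), 50)       # missing unit read as years
  expect_equal(as.character(group_age(normalize_age(6, "DEC"))), "41-60")
  expect_equal(as.character(group_age(95)), ">=90")
  expect_equal(as.character(group_age(NA)), "unknown")

  # boundary enumeration oracle over integer ages 0..120
  oracle <- function(a) {
    if (a <= 17) "0-17" else if (a <= 40) "18-40" else if (a <= 60) "41-60"
    else if (a <= 90) "61-90" else ">=90"
  }
  ages <- 0:120
  expect_equal(as.character(group_age(ages)),
               vapply(ages, oracle, character(1)))
})

test_that("occupation and country resolve per the reporting groups", {
  expect_equal(as.character(group_occupation("MD")), "Physician (MD)")
  expect_equal(as.character(group_occupation("PH")), "Pharmacist")
  expect_equal(as.character(group_occupation(c("OT", "HP", "RN"))),
               rep("Other healthcare professional", 3))
  expect_equal(as.character(group_occupation(c("CN", "LW", NA))),
               rep("Unknown/other", 3))
  expect_equal(resolve_country("FR", "US"), "FR")
  expect_equal(resolve_country(NA, "US"), "US")
  expect_true(is.na(resolve_country(NA, NA)))
})

test_that("build_cases assembles flags, strata and window filtering", {
  reports <- make_reports(
    make_report("1", fda_dt = "20180601", age = 7, age_cod = "DEC"),
    make_report("2", fda_dt = "20240110", roles = c("PS", "C"),
                drugs = c("LIPITOR", "ASPIRIN"), pts = "Rash"),
    make_report("3", fda_dt = "20150101"),          # outside window
    make_report("4", fda_dt = NA, src_year = 2021))  # fallback to file year
  cases <- build_cases(reports)
  expect_equal(nrow(cases), 3L)
  expect_equal(case_audit(cases)$out_of_window, 1L)
  c1 <- cases[cases$primaryid == "1"]
  expect_equal(c1$period, "PRE")
  expect_true(c1$is_tin)
  expect_equal(as.character(c1$age_group), "61-90")
  c2 <- cases[cases$primaryid == "2"]
  expect_equal(c2$period, "POST")
  expect_false(c2$is_tin)
  expect_true(c2$is_statin_ps)
  expect_equal(c2$statin_ingredients[[1]], "atorvastatin")
  expect_equal(cases[cases$primaryid == "4"]$year, 2021L)
  # flags are pure functions of the report: rebuilding changes nothing
  cases2 <- build_cases(reports)
  expect_equal(strip_audit(cases2), strip_audit(cases))
})
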