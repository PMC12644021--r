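small_config <- function(seed = 5, ...) {
  sim_config(seed = seed, years = 2023:2024, reports_per_year = 600,
             statin_share = 0.15, tin_background_rate = 0.02,
             rate_ratio_by_year = c(`2023` = 1, `2024` = 4), ...)
}

test_that("identical seed and config give byte-identical output files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulate(small_config(), d1)
  run_simulate(small_config(), d2)
  for (f in list.files(d1, pattern = "\\.txt$")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  run_simulate(small_config(seed = 6), d3)
  expect_false(identical(readLines(file.path(d1, "DEMO24Q1.txt")),
                         readLines(file.path(d3, "DEMO24Q1.txt"))))
})

test_that("truth cells equal a brute-force recount of the emitted files", {
  d <- withr::local_tempdir()
  sim <- run_simulate(small_config(), d)
  # independent recount with base R string handling only
  read_fam <- function(prefix) {
    files <- list.files(d, pattern = paste0("^", prefix, ".*\\.txt$"),
                        full.names = TRUE)
    do.call(rbind, lapply(files, function(f) {
      lines <- readLines(f)
      hdr <- strsplit(lines[1], "$", fixed = TRUE)[[1]]
      if (length(lines) < 2) {
        return(NULL)
      }
      m <- do.call(rbind, lapply(strsplit(lines[-1], "$", fixed = TRUE),
                                 function(p) p[seq_along(hdr)]))
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- hdr
      df
    }))
  }
  demo <- read_fam("DEMO"); drug <- read_fam("DRUG"); reac <- read_fam("REAC")
  # collapse exact duplicates (identical full records), then keep the
  # largest caseversion per caseid (tie: larger primaryid)
  demo <- unique(demo)
  demo$cv <- as.integer(demo$caseversion)
  demo <- demo[order(demo$caseid, demo$cv, nchar(demo$primaryid),
                     demo$primaryid), ]
  demo <- demo[!duplicated(demo$caseid, fromLast = TRUE), ]
  statin_names <- c("ROSUVASTATIN", "ATORVASTATIN", "SIMVASTATIN",
                    "PRAVASTATIN", "PITAVASTATIN", "LOVASTATIN",
                    "CRESTOR", "LIPITOR", "ZOCOR", "PRAVACHOL", "LIVALO",
                    "MEVACOR")
  ps <- drug[drug$role_cod == "PS", ]
  ps$is_statin <- grepl(paste(statin_names, collapse = "|"), ps$drugname)
  statin_pids <- unique(ps$primaryid[ps$is_statin])
  tin_pids <- unique(reac$primaryid[reac$pt == "Tubulointerstitial nephritis"])
  demo$year <- as.integer(substr(demo$fda_dt, 1, 4))
  recount <- do.call(rbind, lapply(sort(unique(demo$year)), function(y) {
    dd <- demo[demo$year == y, ]
    s <- dd$primaryid %in% statin_pids
    t <- dd$primaryid %in% tin_pids
    data.frame(year = y, a = sum(s & t), b = sum(s & !t),
               c = sum(!s & t), d = sum(!s & !t))
  }))
  expect_equal(recount$a, sim$truth$cells$a)
  expect_equal(recount$b, sim$truth$cells$b)
  expect_equal(recount$c, sim$truth$cells$c)
  expect_equal(recount$d, sim$truth$cells$d)
})

test_that("injected duplicates and versions are removed by the pipeline", {
  for (mode in c("same_id", "fresh_id")) {
    sim <- simulate_faers(small_config(dup_mode = mode))
    reports <- bind_reports(sim$bundles)
    dd <- deduplicate(reports)
    aud <- dedup_audit(dd)
    n_dup <- length(sim$truth$duplicate_primaryids)
    n_ver <- length(sim$truth$superseded_primaryids)
    expect_equal(aud$input - aud$retained, n_dup + n_ver, info = mode)
    expect_equal(nrow(dd), sum(sim$truth$cells[, c("a", "b", "c", "d")]),
                 info = mode)
    if (mode == "same_id") {
      expect_equal(unname(aud$removed["exact_dup"]), n_dup)
      expect_equal(unname(aud$removed["superseded_version"]), n_ver)
    }
    # none of the superseded version-1 records survive
    expect_length(intersect(dd$primaryid, sim$truth$superseded_primaryids), 0)
  }
})

test_that("with no duplicates or versions, dedup removes nothing", {
  sim <- simulate_faers(small_config(dup_rate = 0, version_rate = 0))
  dd <- deduplicate(bind_reports(sim$bundles))
  expect_equal(dedup_audit(dd)$removed,
               c(exact_dup = 0L, superseded_version = 0L))
})

test_that("probability overflow after rate-ratio scaling is a config error", {
  expect_error(sim_config(tin_background_rate = 0.3,
                          rate_ratio_by_year = c(`2024` = 6), years = 2024),
               "exceeds 1")
})

test_that("margin emulation reproduces the published expectations exactly", {
  cfg <- emulate_reference_margins()
  em <- expected_margins(cfg)
  ref <- tin_annual_reference()
  expect_equal(em$expected_statin_reports, as.numeric(ref$statin_ades))
  expect_equal(em$expected_tin_statin_cases, as.numeric(ref$tin_cases))
  # e.g. 8,503 expected statin reports in 2024, 2 expected TIN cases in 2019
  expect_equal(em$expected_statin_reports[em$year == 2024], 8503)
  expect_equal(em$expected_tin_statin_cases[em$year == 2019], 2)
})

test_that("realized margins track the emulated expectations within noise", {
  # two years only, to keep the check quick
  cfg2 <- sim_config(seed = 11, years = c(2019L, 2024L),
                     reports_per_year = 20000L,
                     statin_share = c(12089, 8503) / 20000,
                     tin_background_rate = 0.002,
                     rate_ratio_by_year = c(
                       `2019` = 2 / (12089 * 0.002),
                       `2024` = 42 / (8503 * 0.002)))
  sim <- simulate_faers(cfg2)
  cells <- sim$truth$cells
  ab <- cells$a + cells$b
  expect_lt(abs(ab[cells$year == 2024] - 8503), 4 * sqrt(8503))
  expect_lt(abs(ab[cells$year == 2019] - 12089), 4 * sqrt(12089))
  expect_lte(abs(cells$a[cells$year == 2024] - 42), 4 * sqrt(42))
})
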