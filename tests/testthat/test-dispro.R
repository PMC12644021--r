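test_that("ROR and its Woolf interval match direct evaluation", {
  r <- ror(contingency_table(10, 20, 30, 240))
  expect_equal(r$ror, 4.00, tolerance = 1e-12)
  # direct Woolf formula as independent oracle
  se <- sqrt(1 / 10 + 1 / 20 + 1 / 30 + 1 / 240)
  expect_equal(r$lower, exp(log(4) - 1.96 * se), tolerance = 1e-12)
  expect_equal(r$upper, exp(log(4) + 1.96 * se), tolerance = 1e-12)
  expect_equal(round(r$lower, 2), 1.71)
  expect_equal(round(r$upper, 2), 9.35)
  expect_false(r$corrected)
})

test_that("independence gives ROR = PRR = 1", {
  tab <- contingency_table(5, 50, 20, 200)
  expect_equal(ror(tab)$ror, 1.0)
  expect_equal(prr(tab)$prr, 1.0)
})

test_that("PRR matches its defining ratio", {
  p <- prr(contingency_table(10, 20, 30, 240))
  expect_equal(p$prr, (10 / 30) / (30 / 270), tolerance = 1e-12)
  expect_equal(p$prr, 3.0)
})

test_that("the Haldane correction handles zero cells, applied only then", {
  tab0 <- contingency_table(0, 20, 30, 240)
  r <- ror(tab0, correction = "haldane")
  expect_true(r$corrected)
  expect_equal(r$ror, (0.5 * 240.5) / (20.5 * 30.5), tolerance = 1e-12)
  expect_gt(r$ror, 0)
  # no zero cell: correction not applied even when requested
  expect_false(ror(contingency_table(1, 20, 30, 240))$corrected)
  # zero cell without correction is signaled, not silently NaN
  expect_error(ror(tab0, correction = "none"), class = "faersignal_undefined")
  expect_error(prr(contingency_table(5, 20, 0, 240), correction = "none"),
               class = "faersignal_undefined")
})

test_that("empty margins are signaled as undefined", {
  expect_error(ror(contingency_table(0, 0, 30, 240)),
               class = "faersignal_undefined")
  expect_error(prr(contingency_table(5, 20, 0, 0)),
               class = "faersignal_undefined")
})

test_that("ROR and PRR are scale-invariant; EBGM is not (shrinkage)", {
  tab <- contingency_table(12, 40, 55, 900)
  k <- 7
  tabk <- contingency_table(12 * k, 40 * k, 55 * k, 900 * k)
  expect_equal(ror(tabk)$ror, ror(tab)$ror, tolerance = 1e-12)
  expect_equal(prr(tabk)$prr, prr(tab)$prr, tolerance = 1e-12)
  e1 <- mgps_posterior(tab$a, tab$expected)$ebgm
  e2 <- mgps_posterior(tabk$a, tabk$expected)$ebgm
  expect_gt(abs(e1 - e2), 1e-6)
})

test_that("build_table splits statin-PS/TIN cells within the stratum", {
  # 10 reports: 3 statin-PS, 2 TIN, 1 overlapping -> (1, 2, 1, 6)
  cases <- rbind(
    make_cases(1, is_statin_ps = TRUE, is_tin = TRUE),
    make_cases(2, is_statin_ps = TRUE, is_tin = FALSE),
    make_cases(1, is_statin_ps = FALSE, is_tin = TRUE),
    make_cases(6, is_statin_ps = FALSE, is_tin = FALSE))
  tab <- build_table(cases, year = 2024)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 2, 1, 6))
  expect_equal(tab$n, 10)
  expect_equal(tab$expected, 3 * 2 / 10)
  # margin identity from published 2024 counts: a = 42, a+b = 8503
  tab24 <- contingency_table(42, 8503 - 42, 100, 1000)
  expect_equal(tab24$drug_margin, 8503)
  # empty stratum: all-zero table
  tab0 <- build_table(cases, year = 2019)
  expect_equal(c(tab0$a, tab0$b, tab0$c, tab0$d), c(0, 0, 0, 0))
})

test_that("IC conventions: log2 of EBGM, and the shrunk obs/exp variant", {
  expect_equal(round_half_up(ic(5.32), 2), 2.41)
  expect_equal(ic(1), 0)
  expect_equal(round_half_up(ic(2.71), 2), 1.44)
  tab <- contingency_table(10, 20, 30, 240)
  expect_equal(ic(tab, method = "shrunk_obs_exp"),
               log2(10.5 / (tab$expected + 0.5)))
  expect_error(ic(-1), class = "faersignal_undefined")
})

test_that("threshold semantics are strict/non-strict exactly as published", {
  f <- flag_signal(5.77, 5.75, 5.32, 2.41)
  expect_true(all(f))
  f <- flag_signal(0.07, 0.07, 0.08, -3.55)
  expect_false(any(f))
  # PRR fires at equality (>= 2); others are strict
  f <- flag_signal(1.5, 2.0, 2.1, 0.5)
  expect_true(f[["flag_prr"]])
  expect_true(f[["important_signal"]])
  f <- flag_signal(1.0, 2.0, 2.0, 0.0)
  expect_false(f[["flag_ror"]])
  expect_false(f[["flag_ebgm"]])
  expect_false(f[["flag_ic"]])
  # undefined metrics make their criterion false
  f <- flag_signal(NA, 2.5, 2.5, 1)
  expect_false(f[["flag_ror"]])
  expect_false(f[["important_signal"]])
})

test_that("Woolf 95% interval covers the null in 93-97% of null tables", {
  set.seed(20240501)
  n_sim <- 500
  covered <- logical(n_sim)
  p_drug <- 0.05; p_event <- 0.05; N <- 20000
  probs <- c(p_drug * p_event, p_drug * (1 - p_event),
             (1 - p_drug) * p_event, (1 - p_drug) * (1 - p_event))
  for (i in seq_len(n_sim)) {
    cells <- as.vector(rmultinom(1, N, probs))
    r <- ror(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    covered[i] <- r$lower <= 1 && 1 <= r$upper
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("large-count limit: ROR, PRR and EBGM approach n/E", {
  # rare event, small drug share: the three estimators converge on the
  # relative reporting rate n/E
  tab <- contingency_table(200, 99800, 10000, 9990000)
  rr <- tab$a / tab$expected
  expect_equal(ror(tab)$ror / rr, 1, tolerance = 0.02)
  expect_equal(prr(tab)$prr / rr, 1, tolerance = 0.02)
  e <- mgps_posterior(tab$a, tab$expected)$ebgm
  expect_equal(e / rr, 1, tolerance = 0.02)
})

test_that("the chi-square companion is computed but plays no role in flags", {
  x <- prr_chisq(contingency_table(10, 20, 30, 240))
  expect_gt(x, 0)
  m <- matrix(c(10, 20, 30, 240), nrow = 2, byrow = TRUE)
  expect_equal(x, unname(suppressWarnings(chisq.test(m)$statistic)))
})

test_that("annual_metrics mirrors the per-year table schema and flags", {
  cases <- rbind(
    make_cases(8, year = 2023, is_statin_ps = TRUE, is_tin = TRUE),
    make_cases(100, year = 2023, is_statin_ps = TRUE, is_tin = FALSE),
    make_cases(20, year = 2023, is_statin_ps = FALSE, is_tin = TRUE),
    make_cases(2000, year = 2023, is_statin_ps = FALSE, is_tin = FALSE))
  am <- annual_metrics(cases, years = 2022:2023)
  expect_equal(nrow(am), 2L)
  expect_false(am$analyzable[am$year == 2022])
  row <- am[am$year == 2023]
  expect_true(row$analyzable)
  expect_equal(row$tin_cases, 8L)
  expect_equal(row$statin_ades, 108L)
  tab <- build_table(cases, year = 2023)
  expect_equal(row$ror, ror(tab)$ror)
  expect_equal(row$ic, log2(row$ebgm), tolerance = 1e-12)
})
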