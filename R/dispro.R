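# Case/non-case disproportionality: 2x2 contingency tables per stratum,
# ROR with Woolf intervals, PRR, IC, and four-threshold signal flagging.
# The empirical-Bayes (MGPS) machinery lives in mgps.R.

#' Construct a 2x2 disproportionality contingency table
#'
#' Cells follow the case/non-case convention: `a` target-event reports for
#' the drug of interest, `b` other reports for the drug of interest, `c`
#' target-event reports for all other drugs, `d` all remaining reports.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param label optional stratum label.
#' @return object of class `contingency_table` with the cells, the total
#'   `n`, the drug and event margins, and the expected count
#'   `expected = (a+b)(a+c)/n` under independence.
#' @export
#' @examples
#' contingency_table(10, 20, 30, 240)
contingency_table <- function(a, b, c, d, label = NULL) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(is.finite(cells)), all(cells >= 0))
  n <- a + b + c + d
  structure(list(
    a = a, b = b, c = c, d = d, n = n,
    drug_margin = a + b, event_margin = a + c,
    expected = if (n > 0) (a + b) * (a + c) / n else 0,
    label = label
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table%s a=%g b=%g c=%g d=%g N=%g E=%.3g>\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$a, x$b, x$c, x$d, x$n, x$expected))
  invisible(x)
}

#' Build the stratum contingency table from clean cases
#'
#' Within the stratum, `a` counts statin-primary-suspect reports carrying the
#' target PT, `b` the remaining statin-PS reports, and `c`/`d` the same split
#' over all other reports (the database background, including reports where a
#' statin appears only as secondary suspect or concomitant). Each report
#' counts once even if several statin ingredients are primary suspects.
#'
#' @param cases clean case table from [build_cases()].
#' @param year restrict to one calendar year (optional).
#' @param period restrict to one study period, `"PRE"` or `"POST"` (optional).
#' @return a [contingency_table()]; an empty stratum yields the all-zero
#'   table (non-analyzable downstream).
#' @export
build_table <- function(cases, year = NULL, period = NULL) {
  cases <- data.table::as.data.table(cases)
  label <- "pooled"
  if (!is.null(year)) {
    keep <- !is.na(cases[["year"]]) & cases[["year"]] == year
    cases <- cases[keep]
    label <- as.character(year)
  } else if (!is.null(period)) {
    keep <- !is.na(cases[["period"]]) & cases[["period"]] == period
    cases <- cases[keep]
    label <- period
  }
  a <- sum(cases$is_statin_ps & cases$is_tin)
  b <- sum(cases$is_statin_ps & !cases$is_tin)
  cc <- sum(!cases$is_statin_ps & cases$is_tin)
  d <- sum(!cases$is_statin_ps & !cases$is_tin)
  contingency_table(a, b, cc, d, label = label)
}

apply_correction <- function(tab, correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  zero <- any(c(tab$a, tab$b, tab$c, tab$d) == 0)
  if (correction == "haldane" && zero) {
    list(a = tab$a + 0.5, b = tab$b + 0.5, c = tab$c + 0.5, d = tab$d + 0.5,
         corrected = TRUE)
  } else {
    list(a = tab$a, b = tab$b, c = tab$c, d = tab$d, corrected = FALSE)
  }
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d)/(b c)`; the 95% interval is
#' `exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))` (Woolf's log-odds
#' variance). With `correction = "haldane"` (default), 0.5 is added to every
#' cell — but only when some cell is zero.
#'
#' @param tab a [contingency_table()].
#' @param correction `"haldane"` (conditional 0.5 continuity correction) or
#'   `"none"`.
#' @param z normal quantile for the interval (1.96 for 95%).
#' @return list with `ror`, `lower`, `upper`, and `corrected` (whether the
#'   continuity correction was applied).
#' @export
#' @examples
#' ror(contingency_table(10, 20, 30, 240))
ror <- function(tab, correction = c("haldane", "none"), z = 1.96) {
  stopifnot(inherits(tab, "contingency_table"))
  if (tab$a + tab$b == 0 || tab$c + tab$d == 0) {
    undefined_metric("ROR undefined: empty drug or background margin")
  }
  cl <- apply_correction(tab, correction)
  if (any(c(cl$a, cl$b, cl$c, cl$d) == 0)) {
    undefined_metric("ROR undefined: zero cell without continuity correction")
  }
  est <- (cl$a * cl$d) / (cl$b * cl$c)
  se <- sqrt(1 / cl$a + 1 / cl$b + 1 / cl$c + 1 / cl$d)
  list(ror = est, lower = exp(log(est) - z * se),
       upper = exp(log(est) + z * se), corrected = cl$corrected)
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`: the proportion of target-event reports
#' among drug-of-interest reports over the same proportion in the rest of
#' the database.
#'
#' @inheritParams ror
#' @return list with `prr` and `corrected`.
#' @export
prr <- function(tab, correction = c("haldane", "none")) {
  stopifnot(inherits(tab, "contingency_table"))
  if (tab$a + tab$b == 0 || tab$c + tab$d == 0) {
    undefined_metric("PRR undefined: empty drug or background margin")
  }
  cl <- apply_correction(tab, correction)
  if (cl$c == 0) {
    undefined_metric("PRR undefined: no background target-event reports")
  }
  list(prr = (cl$a / (cl$a + cl$b)) / (cl$c / (cl$c + cl$d)),
       corrected = cl$corrected)
}

#' Classic PRR chi-square companion statistic
#'
#' Yates-corrected chi-square of the 2x2 table (the companion statistic of
#' the classic Evans PRR rule). Reported for reference; it takes no part in
#' the package's signal flagging, which uses the four-threshold rule only.
#'
#' @param tab a [contingency_table()].
#' @return the chi-square value (1 df).
#' @export
prr_chisq <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  m <- matrix(c(tab$a, tab$b, tab$c, tab$d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(NA_real_)
  unname(suppressWarnings(stats::chisq.test(m, correct = TRUE)$statistic))
}

#' Information component
#'
#' Under the default convention the IC is `log2(EBGM)`: the printed IC of
#' the reference annual metrics equals the base-2 log of the printed EBGM.
#' The `"shrunk_obs_exp"` variant `log2((a + 0.5)/(E + 0.5))` is offered for
#' reuse.
#'
#' @param x an EBGM value (method `"log2_ebgm"`) or a
#'   [contingency_table()] (method `"shrunk_obs_exp"`).
#' @param method IC convention.
#' @return IC in bits.
#' @export
#' @examples
#' ic(5.32)  # 2.41 bits at 2 dp
ic <- function(x, method = c("log2_ebgm", "shrunk_obs_exp")) {
  method <- match.arg(method)
  if (method == "log2_ebgm") {
    ebgm <- if (inherits(x, "contingency_table")) {
      stop("log2_ebgm convention needs an EBGM value, not a table")
    } else {
      as.numeric(x)
    }
    if (any(ebgm <= 0, na.rm = TRUE)) {
      undefined_metric("IC undefined for non-positive EBGM")
    }
    log2(ebgm)
  } else {
    stopifnot(inherits(x, "contingency_table"))
    log2((x$a + 0.5) / (x$expected + 0.5))
  }
}

#' Signal-flagging thresholds
#'
#' The four-threshold rule: a criterion fires when `ROR > 1`, `PRR >= 2`,
#' `EBGM > 2` or `IC > 0`; an *important* signal must meet all four.
#'
#' @param ror_gt,prr_ge,ebgm_gt,ic_gt criterion cutoffs (strict for ROR,
#'   EBGM and IC; non-strict for PRR).
#' @param require_all if `TRUE` the important-signal flag is the conjunction
#'   of the four criteria.
#' @param ror_ci_lower_gt optional additional criterion on the ROR interval
#'   lower bound (off by default).
#' @return list of class `signal_thresholds`.
#' @export
signal_thresholds <- function(ror_gt = 1, prr_ge = 2, ebgm_gt = 2, ic_gt = 0,
                              require_all = TRUE, ror_ci_lower_gt = NULL) {
  structure(list(ror_gt = ror_gt, prr_ge = prr_ge, ebgm_gt = ebgm_gt,
                 ic_gt = ic_gt, require_all = require_all,
                 ror_ci_lower_gt = ror_ci_lower_gt),
            class = "signal_thresholds")
}

#' Apply the four-threshold signal rule
#'
#' Undefined (`NA`) metrics make their criterion `FALSE`.
#'
#' @param ror,prr,ebgm,ic point estimates (scalars; `NA` allowed).
#' @param ror_lower optional ROR interval lower bound (used only when the
#'   thresholds enable the interval criterion).
#' @param thresholds a [signal_thresholds()].
#' @return named logical vector: `flag_ror`, `flag_prr`, `flag_ebgm`,
#'   `flag_ic`, `important_signal`.
#' @export
#' @examples
#' flag_signal(5.77, 5.75, 5.32, 2.41)
flag_signal <- function(ror, prr, ebgm, ic, ror_lower = NA,
                        thresholds = signal_thresholds()) {
  stopifnot(inherits(thresholds, "signal_thresholds"))
  f <- c(
    flag_ror = isTRUE(ror > thresholds$ror_gt),
    flag_prr = isTRUE(prr >= thresholds$prr_ge),
    flag_ebgm = isTRUE(ebgm > thresholds$ebgm_gt),
    flag_ic = isTRUE(ic > thresholds$ic_gt)
  )
  if (!is.null(thresholds$ror_ci_lower_gt)) {
    f <- c(f, flag_ror_ci = isTRUE(ror_lower > thresholds$ror_ci_lower_gt))
  }
  important <- if (thresholds$require_all) all(f) else any(f)
  c(f, important_signal = important)
}

#' Annual signal-detection metrics
#'
#' Builds the per-year contingency tables from the clean case set and
#' computes ROR (with Woolf 95% interval), PRR, EBGM, IC and the
#' four-threshold flags, mirroring an annual signal-metrics table. Rounding
#' is left to presentation: all values are returned at full precision.
#'
#' @param cases clean case table from [build_cases()].
#' @param years calendar years to analyze.
#' @param prior an [mgps_prior()] for the EBGM shrinker (the literature
#'   default unless you fit one with [fit_mgps_prior()]).
#' @param thresholds a [signal_thresholds()].
#' @param correction continuity-correction policy for ROR/PRR.
#' @param ic_method IC convention, see [ic()].
#' @param z normal quantile for the ROR interval.
#' @return data.table with one row per year: `year`, `tin_cases` (a),
#'   `statin_ades` (a+b), `ror`, `ror_l95`, `ror_u95`, `prr`, `ebgm`, `ic`,
#'   `qn`, the four criterion flags, `important_signal`, and `analyzable`.
#'   Years with no drug-of-interest reports (or an empty background) are
#'   marked non-analyzable with `NA` metrics and all-false flags.
#' @export
annual_metrics <- function(cases, years = 2017:2024,
                           prior = default_mgps_prior(),
                           thresholds = signal_thresholds(),
                           correction = c("haldane", "none"),
                           ic_method = c("log2_ebgm", "shrunk_obs_exp"),
                           z = 1.96) {
  correction <- match.arg(correction)
  ic_method <- match.arg(ic_method)
  rows <- lapply(years, function(y) {
    tab <- build_table(cases, year = y)
    base <- data.table::data.table(
      year = as.integer(y), tin_cases = tab$a, statin_ades = tab$drug_margin,
      ror = NA_real_, ror_l95 = NA_real_, ror_u95 = NA_real_,
      prr = NA_real_, ebgm = NA_real_, ic = NA_real_, qn = NA_real_)
    analyzable <- tab$drug_margin > 0 && (tab$c + tab$d) > 0 &&
      tab$expected > 0
    if (analyzable) {
      r <- tryCatch(ror(tab, correction, z = z),
                    faersignal_undefined = function(e) NULL)
      p <- tryCatch(prr(tab, correction),
                    faersignal_undefined = function(e) NULL)
      post <- mgps_posterior(tab$a, tab$expected, prior)
      if (!is.null(r)) base[, `:=`(ror = r$ror, ror_l95 = r$lower,
                                   ror_u95 = r$upper)]
      if (!is.null(p)) base[, prr := p$prr]
      base[, `:=`(ebgm = post$ebgm, qn = post$qn)]
      base[, ic := if (ic_method == "log2_ebgm") ic(post$ebgm) else
                     ic(tab, method = "shrunk_obs_exp")]
    }
    fl <- flag_signal(base$ror, base$prr, base$ebgm, base$ic,
                      ror_lower = base$ror_l95, thresholds = thresholds)
    for (nm in names(fl)) data.table::set(base, j = nm, value = fl[[nm]])
    base[, analyzable := analyzable]
    base
  })
  data.table::rbindlist(rows)
}
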