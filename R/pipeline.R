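# Assembled pipeline runs and report artifacts: simulate -> ingest ->
# analyze -> report, with per-stage audit counts and atomic CSV/JSON output.

write_csv_atomic <- function(dt, path) {
  atomic_write(function(tmp) data.table::fwrite(dt, tmp), path)
}

write_json_atomic <- function(x, path) {
  atomic_write(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }, path)
}

#' Discover FAERS quarter files in a directory
#'
#' Looks for the `DEMO<yy>Q<q>.txt` naming convention (as written by
#' [write_quarter()]) and collects the sibling DRUG/REAC/OUTC files.
#'
#' @param directory input directory.
#' @return data.table with columns `year`, `quarter`, `demo`, `drug`,
#'   `reac`, `outc` (file paths).
#' @export
discover_quarters <- function(directory) {
  demos <- list.files(directory, pattern = "^DEMO[0-9]{2}Q[1-4]\\.txt$",
                      full.names = TRUE)
  if (!length(demos)) stop("no DEMO<yy>Q<q>.txt files found in ", directory)
  tag <- sub("^DEMO([0-9]{2}Q[1-4])\\.txt$", "\\1", basename(demos))
  yy <- as.integer(substr(tag, 1, 2))
  out <- data.table::data.table(
    year = ifelse(yy >= 50L, 1900L + yy, 2000L + yy),
    quarter = as.integer(substr(tag, 4, 4)),
    demo = demos,
    drug = file.path(directory, paste0("DRUG", tag, ".txt")),
    reac = file.path(directory, paste0("REAC", tag, ".txt")),
    outc = file.path(directory, paste0("OUTC", tag, ".txt")))
  missing <- !file.exists(out$drug) | !file.exists(out$reac) |
    !file.exists(out$outc)
  if (any(missing)) {
    stop("incomplete quarter(s): ",
         paste(out$year[missing], "Q", out$quarter[missing], collapse = ", "))
  }
  data.table::setorder(out, year, quarter)
  out[]
}

#' Simulate a database and write it as FAERS-style quarter files
#'
#' @param config a [sim_config()].
#' @param outdir output directory; quarter files, `sim_truth.csv` (realized
#'   per-year cells) and `sim_config.json` (config echo) are written there.
#' @return the [simulate_faers()] result, invisibly.
#' @export
run_simulate <- function(config = sim_config(), outdir) {
  sim <- simulate_faers(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  for (b in sim$bundles) write_quarter(b, outdir)
  write_csv_atomic(sim$truth$cells, file.path(outdir, "sim_truth.csv"))
  cfg <- sim$config
  class(cfg) <- NULL
  write_json_atomic(cfg, file.path(outdir, "sim_config.json"))
  invisible(sim)
}

#' Ingest a directory of quarter files into joined reports
#'
#' @param indir directory holding the quarter files.
#' @return data.table of joined reports ([bind_reports()] output).
#' @export
run_ingest <- function(indir) {
  q <- discover_quarters(indir)
  bundles <- lapply(seq_len(nrow(q)), function(i) {
    read_quarter(list(demo = q$demo[i], drug = q$drug[i],
                      reac = q$reac[i], outc = q$outc[i]),
                 year = q$year[i], quarter = q$quarter[i])
  })
  bind_reports(bundles)
}

#' Run the full analysis and write the report tables
#'
#' Builds the clean case set, restricts the descriptive tables to the
#' analysis cases (target event with statin as primary suspect), computes
#' the annual signal metrics over all reports, and writes:
#' `table2_demographics.csv`, `figure1_outcomes.csv`,
#' `figure2_countries.csv`, `table3_signal_metrics.csv` and `audit.json`.
#' All files are written atomically (temp file, then rename).
#'
#' @param reports joined reports ([run_ingest()] or [bind_reports()]).
#' @param outdir output directory (created if absent).
#' @param config an [analysis_config()].
#' @param prior an [mgps_prior()] for the EBGM shrinker.
#' @param thresholds a [signal_thresholds()].
#' @return list with elements `cases`, `annual`, `demographics`, `outcomes`,
#'   `countries`, `audit`, invisibly.
#' @export
run_analyze <- function(reports, outdir, config = analysis_config(),
                        prior = default_mgps_prior(),
                        thresholds = signal_thresholds()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  cases <- build_cases(reports, config)
  analysis_set <- cases[cases$is_statin_ps & cases$is_tin]

  demographics <- data.table::rbindlist(lapply(
    c("sex", "age_group", "occupation_group"),
    function(d) cbind(dimension = d, tabulate_cases(analysis_set, d))))
  outcomes <- tabulate_cases(analysis_set, "outcome")
  countries <- tabulate_cases(analysis_set, "country")
  years <- seq(config$window[1], config$window[2])
  annual <- annual_metrics(cases, years = years, prior = prior,
                           thresholds = thresholds)

  audit <- case_audit(cases)
  audit$analysis_cases <- nrow(analysis_set)

  write_csv_atomic(demographics, file.path(outdir, "table2_demographics.csv"))
  write_csv_atomic(outcomes, file.path(outdir, "figure1_outcomes.csv"))
  write_csv_atomic(countries, file.path(outdir, "figure2_countries.csv"))
  write_csv_atomic(annual, file.path(outdir, "table3_signal_metrics.csv"))
  write_json_atomic(audit, file.path(outdir, "audit.json"))

  invisible(list(cases = cases, annual = annual, demographics = demographics,
                 outcomes = outcomes, countries = countries, audit = audit))
}

#' Render a plain-text summary of an analysis run
#'
#' Reads `table3_signal_metrics.csv` from an analysis output directory and
#' writes `report.md`, a short markdown summary naming the flagged years.
#'
#' @param outdir directory holding [run_analyze()] outputs.
#' @return the report path, invisibly.
#' @export
run_report <- function(outdir) {
  path <- file.path(outdir, "table3_signal_metrics.csv")
  if (!file.exists(path)) stop("no table3_signal_metrics.csv in ", outdir)
  annual <- data.table::fread(path)
  fmt2 <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", round_half_up(x, 2)))
  lines <- c(
    "# Signal-detection summary", "",
    sprintf("Analyzed years: %d-%d. Total target-event cases with the drug class as primary suspect: %d.",
            min(annual$year), max(annual$year), sum(annual$tin_cases)), "",
    "| Year | Cases | Drug reports | ROR (95% CI) | PRR | EBGM | IC | Important signal |",
    "|------|-------|--------------|--------------|-----|------|----|------------------|",
    sprintf("| %d | %d | %d | %s (%s-%s) | %s | %s | %s | %s |",
            annual$year, annual$tin_cases, annual$statin_ades,
            fmt2(annual$ror), fmt2(annual$ror_l95), fmt2(annual$ror_u95),
            fmt2(annual$prr), fmt2(annual$ebgm), fmt2(annual$ic),
            ifelse(annual$important_signal, "yes", "no")),
    "")
  flagged <- annual$year[annual$important_signal]
  lines <- c(lines, if (length(flagged)) {
    sprintf("Years flagged as important signals (all four criteria met): %s.",
            paste(flagged, collapse = ", "))
  } else {
    "No year met all four signal criteria."
  })
  out <- file.path(outdir, "report.md")
  atomic_write(function(tmp) writeLines(lines, tmp), out)
  invisible(out)
}
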