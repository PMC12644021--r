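# FAERS quarterly ASCII ingestion: $-delimited files with a header line,
# one file per family (DEMO, DRUG, REAC, OUTC). PRIMARYID is the spine that
# links the families.

.faers_schemas <- list(
  demo = list(
    cols = c("primaryid", "caseid", "caseversion", "event_dt", "fda_dt",
             "sex", "age", "age_cod", "occ_cod", "occr_country",
             "reporter_country"),
    integer = "caseversion", numeric = "age", mandatory = "primaryid"
  ),
  drug = list(
    cols = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    integer = "drug_seq", numeric = character(),
    mandatory = c("primaryid", "drugname")
  ),
  reac = list(
    cols = c("primaryid", "pt"),
    integer = character(), numeric = character(),
    mandatory = c("primaryid", "pt")
  ),
  outc = list(
    cols = c("primaryid", "outc_cod"),
    integer = character(), numeric = character(),
    mandatory = c("primaryid", "outc_cod")
  )
)

.role_codes <- c("PS", "SS", "C", "I")
.outc_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

# "$" inside a free-text field is written escaped so that the round trip is
# exact; real FAERS extracts never contain the escape, so decoding is a no-op
# on them.
escape_dollar   <- function(x) gsub("$", "&#36;", x, fixed = TRUE)
unescape_dollar <- function(x) gsub("&#36;", "$", x, fixed = TRUE)

read_faers_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(!validUTF8(lines))) lines <- iconv(lines, "latin1", "UTF-8")
  lines
}

#' Read one FAERS-style ASCII file
#'
#' Low-level reader for a single `$`-delimited family file. The first line is
#' the header (column names matched case-insensitively). Rows with fewer
#' fields than the header are counted as malformed and skipped; rows with
#' more fields have the overflow joined back into the last column (embedded
#' delimiters in free text are not escaped in real FAERS extracts).
#'
#' @param path file path.
#' @param family one of `"demo"`, `"drug"`, `"reac"`, `"outc"`.
#' @return a [data.table::data.table] of typed records. Attribute `audit`
#'   carries counts of malformed and rejected rows.
#' @export
read_faers_file <- function(path, family = c("demo", "drug", "reac", "outc")) {
  family <- match.arg(family)
  schema <- .faers_schemas[[family]]
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- read_faers_lines(path)
  if (length(lines) == 0L) stop("file ", path, " is empty (no header line)")

  header <- tolower(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]])
  missing_cols <- setdiff(schema$mandatory, header)
  if (length(missing_cols)) {
    stop("file ", path, " is missing mandatory column(s): ",
         paste(toupper(missing_cols), collapse = ", "))
  }
  ncol <- length(header)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]

  audit <- c(malformed = 0L, rejected = 0L)
  if (length(body)) {
    parts <- strsplit(body, "$", fixed = TRUE)
    lens <- lengths(parts)
    # a line ending in "$" drops the trailing empty field in strsplit
    short_by_one <- lens == ncol - 1L & endsWith(body, "$")
    parts[short_by_one] <- lapply(parts[short_by_one], function(p) c(p, ""))
    lens[short_by_one] <- ncol
    audit["malformed"] <- sum(lens < ncol)
    parts <- parts[lens >= ncol]
    parts <- lapply(parts, function(p) {
      if (length(p) > ncol) {
        p[ncol] <- paste(p[ncol:length(p)], collapse = "$")
        p <- p[seq_len(ncol)]
      }
      p
    })
    dt <- data.table::as.data.table(do.call(rbind, parts))
  } else {
    dt <- data.table::as.data.table(
      matrix(character(0), nrow = 0L, ncol = ncol))
  }
  data.table::setnames(dt, header)
  for (j in names(dt)) data.table::set(dt, j = j, value = {
    v <- unescape_dollar(trimws(dt[[j]]))
    v[v == ""] <- NA_character_
    v
  })

  # canonical column order: schema columns first (absent ones created as NA),
  # unknown extras preserved after them as opaque payload
  for (cn in setdiff(schema$cols, names(dt))) {
    data.table::set(dt, j = cn, value = NA_character_)
  }
  data.table::setcolorder(dt, c(schema$cols, setdiff(names(dt), schema$cols)))

  for (cn in schema$integer) {
    data.table::set(dt, j = cn, value = suppressWarnings(as.integer(dt[[cn]])))
  }
  for (cn in schema$numeric) {
    data.table::set(dt, j = cn, value = suppressWarnings(as.numeric(dt[[cn]])))
  }

  keep <- rep(TRUE, nrow(dt))
  if (family == "drug") {
    keep <- is.na(dt$role_cod) | dt$role_cod %in% .role_codes
  } else if (family == "outc") {
    keep <- !is.na(dt$outc_cod) & dt$outc_cod %in% .outc_codes
  } else if (family == "reac") {
    keep <- !is.na(dt$pt) & nzchar(dt$pt)
  } else if (family == "demo") {
    keep <- !is.na(dt$primaryid) & !duplicated(dt$primaryid)
    bad_age <- !is.na(dt$age) & dt$age < 0
    if (any(bad_age)) data.table::set(dt, which(bad_age), "age", NA_real_)
    bad_cv <- !is.na(dt$caseversion) & dt$caseversion < 1L
    if (any(bad_cv)) {
      data.table::set(dt, which(bad_cv), "caseversion", NA_integer_)
    }
  }
  keep <- keep & !is.na(dt$primaryid)
  audit["rejected"] <- sum(!keep)
  dt <- dt[keep]
  data.table::setattr(dt, "audit", audit)
  dt[]
}

#' Bundle one quarter's file families
#'
#' Constructs a validated `quarter_bundle`: DRUG/REAC/OUTC rows whose
#' PRIMARYID has no DEMO row are orphans and are dropped with a logged count
#' (DEMO is the spine of the linkage).
#'
#' @param year calendar year of the quarter.
#' @param quarter quarter number, 1–4.
#' @param demo,drug,reac,outc data.tables as returned by [read_faers_file()].
#' @param audit optional named list of per-family read audits.
#' @return an object of class `quarter_bundle`.
#' @export
quarter_bundle <- function(year, quarter, demo, drug, reac, outc,
                           audit = list()) {
  stopifnot(length(year) == 1L, length(quarter) == 1L, quarter %in% 1:4)
  demo <- data.table::as.data.table(demo)
  orphans <- c(drug = 0L, reac = 0L, outc = 0L)
  trim <- function(dt, fam) {
    dt <- data.table::as.data.table(dt)
    keep <- dt$primaryid %in% demo$primaryid
    orphans[[fam]] <<- sum(!keep)
    dt[keep]
  }
  b <- structure(list(
    year = as.integer(year), quarter = as.integer(quarter),
    demo = demo, drug = trim(drug, "drug"), reac = trim(reac, "reac"),
    outc = trim(outc, "outc"),
    audit = c(audit, list(orphans_dropped = orphans))
  ), class = "quarter_bundle")
  b
}

#' @export
print.quarter_bundle <- function(x, ...) {
  cat(sprintf("<quarter_bundle %dQ%d: %d reports, %d drug rows, %d reactions, %d outcomes>\n",
              x$year, x$quarter, nrow(x$demo), nrow(x$drug), nrow(x$reac),
              nrow(x$outc)))
  invisible(x)
}

#' Read a FAERS quarter
#'
#' Reads the DEMO, DRUG, REAC and OUTC files of one quarter and bundles them.
#' Paths to optional families (THER, INDI, RPSR) are accepted and ignored.
#'
#' @param paths named list or character vector with elements `demo`, `drug`,
#'   `reac`, `outc` (names matched case-insensitively).
#' @param year,quarter which quarter the files cover.
#' @return a [quarter_bundle()].
#' @export
#' @examples
#' dir <- system.file("extdata", "fixtures", package = "faersignal")
#' b <- read_quarter(list(
#'   demo = file.path(dir, "DEMO24Q1.txt"), drug = file.path(dir, "DRUG24Q1.txt"),
#'   reac = file.path(dir, "REAC24Q1.txt"), outc = file.path(dir, "OUTC24Q1.txt")),
#'   year = 2024, quarter = 1)
#' b
read_quarter <- function(paths, year, quarter) {
  paths <- as.list(paths)
  names(paths) <- tolower(names(paths))
  need <- c("demo", "drug", "reac", "outc")
  if (!all(need %in% names(paths))) {
    stop("paths must name all of: ", paste(need, collapse = ", "))
  }
  fams <- lapply(need, function(f) read_faers_file(paths[[f]], f))
  names(fams) <- need
  quarter_bundle(year, quarter,
                 demo = fams$demo, drug = fams$drug,
                 reac = fams$reac, outc = fams$outc,
                 audit = lapply(fams, attr, "audit"))
}

format_field <- function(v) {
  out <- if (is.numeric(v)) {
    ifelse(is.na(v), "", format(v, trim = TRUE, scientific = FALSE, digits = 15))
  } else {
    ifelse(is.na(v), "", escape_dollar(as.character(v)))
  }
  out
}

write_faers_file <- function(dt, path) {
  cols <- names(dt)
  body <- if (nrow(dt)) {
    do.call(paste, c(lapply(dt, format_field), sep = "$"))
  } else {
    character(0)
  }
  atomic_write(function(tmp) {
    writeLines(c(paste(cols, collapse = "$"), body), tmp, useBytes = TRUE)
  }, path)
}

#' Write a quarter bundle as FAERS-style ASCII files
#'
#' Inverse of [read_quarter()]: `read_quarter(write_quarter(b))` reproduces
#' `b` field for field.
#'
#' @param bundle a [quarter_bundle()].
#' @param directory output directory (created if absent).
#' @return named character vector of the four file paths.
#' @export
write_quarter <- function(bundle, directory) {
  stopifnot(inherits(bundle, "quarter_bundle"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(directory)) stop("cannot create directory ", directory)
  }
  yy <- bundle$year %% 100L
  paths <- c(
    demo = file.path(directory, sprintf("DEMO%02dQ%d.txt", yy, bundle$quarter)),
    drug = file.path(directory, sprintf("DRUG%02dQ%d.txt", yy, bundle$quarter)),
    reac = file.path(directory, sprintf("REAC%02dQ%d.txt", yy, bundle$quarter)),
    outc = file.path(directory, sprintf("OUTC%02dQ%d.txt", yy, bundle$quarter))
  )
  for (fam in names(paths)) write_faers_file(bundle[[fam]], paths[[fam]])
  paths
}

#' Join the file families of a bundle into per-report records
#'
#' One joined record per DEMO PRIMARYID, carrying all of the report's drugs
#' (with role codes), reaction PTs and outcome codes as list-columns.
#' Reports with no drug rows or no reaction rows are flagged, not dropped.
#'
#' @param bundle a [quarter_bundle()].
#' @return a [data.table::data.table] with one row per report; columns from
#'   DEMO plus list-columns `pts`, `drug_roles`, `drug_names`, `drug_ais`,
#'   `outcomes`, counts `n_drugs`/`n_pts`, flags `no_drug`/`no_reaction`, and
#'   the source file coordinates `src_year`/`src_quarter`.
#' @export
join_families <- function(bundle) {
  stopifnot(inherits(bundle, "quarter_bundle"))
  demo <- data.table::copy(bundle$demo)
  empty_chr <- list(character(0))

  agg_drug <- bundle$drug[order(primaryid, drug_seq),
    .(drug_roles = list(role_cod), drug_names = list(drugname),
      drug_ais = list(prod_ai)), by = primaryid]
  agg_reac <- bundle$reac[, .(pts = list(pt)), by = primaryid]
  agg_outc <- bundle$outc[, .(outcomes = list(outc_cod)), by = primaryid]

  joined <- agg_drug[demo, on = "primaryid"]
  joined <- agg_reac[joined, on = "primaryid"]
  joined <- agg_outc[joined, on = "primaryid"]
  # restore demo order
  joined <- joined[match(demo$primaryid, joined$primaryid)]

  fill_empty <- function(col) {
    v <- joined[[col]]
    v[vapply(v, is.null, logical(1))] <- empty_chr
    v
  }
  for (col in c("drug_roles", "drug_names", "drug_ais", "pts", "outcomes")) {
    data.table::set(joined, j = col, value = fill_empty(col))
  }
  joined[, `:=`(
    n_drugs = lengths(drug_roles), n_pts = lengths(pts),
    src_year = bundle$year, src_quarter = bundle$quarter
  )]
  joined[, `:=`(no_drug = n_drugs == 0L, no_reaction = n_pts == 0L)]
  data.table::setcolorder(joined, c("primaryid", "caseid"))
  joined[]
}

#' Stack joined reports from several quarter bundles
#'
#' @param bundles list of [quarter_bundle()] objects.
#' @return single data.table of joined reports (see [join_families()]).
#' @export
bind_reports <- function(bundles) {
  data.table::rbindlist(lapply(bundles, join_families), use.names = TRUE,
                        fill = TRUE)
}
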