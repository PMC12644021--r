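`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Presentation rounding used throughout the package's tables: 18.75 rounds to
#' 18.8 and -18.75 to -18.8, matching the convention of published
#' pharmacovigilance tables rather than the banker's rounding of [round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(18.75, 6.25, 69.231), 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny relative nudge guards against values like 18.75 that decimal
  # arithmetic leaves a hair below the .5 boundary
  z <- abs(x) * p
  sign(x) * floor(z + 0.5 + sqrt(.Machine$double.eps) * pmax(z, 1)) / p
}

#' Normalize a MedDRA Preferred Term string for comparison
#'
#' Trims, collapses internal whitespace and case-folds. No synonym or SMQ
#' expansion is performed: PTs are matched literally.
#'
#' @param x character vector of PT strings.
#' @return normalized character vector.
#' @export
normalize_pt <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Parse a possibly partial FAERS date
#'
#' FAERS dates come as YYYY, YYYYMM or YYYYMMDD. A partial date is never
#' coerced to a fake full date: unknown components are returned as `NA`.
#'
#' @param x character (or numeric) vector of date strings.
#' @return a [data.table::data.table] with integer columns `year`, `month`,
#'   `day` (NA where the component is unknown or the string is unparseable).
#' @export
parse_partial_date <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)] <- NA_character_
  n <- nchar(x)
  yr <- suppressWarnings(as.integer(substr(x, 1L, 4L)))
  mo <- suppressWarnings(as.integer(ifelse(!is.na(n) & n >= 6L, substr(x, 5L, 6L), NA)))
  dy <- suppressWarnings(as.integer(ifelse(!is.na(n) & n == 8L, substr(x, 7L, 8L), NA)))
  mo[!is.na(mo) & (mo < 1L | mo > 12L)] <- NA_integer_
  dy[!is.na(dy) & (dy < 1L | dy > 31L)] <- NA_integer_
  data.table::data.table(year = yr, month = mo, day = dy)
}

year_of_date <- function(x) parse_partial_date(x)$year

# classed error so callers can distinguish "statistically undefined" from bugs
undefined_metric <- function(msg) {
  stop(structure(class = c("faersignal_undefined", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# atomic write: write to a temp file in the same directory, then rename
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}
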