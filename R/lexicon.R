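# Statin name lexicon: verbatim DRUGNAME / PROD_AI tokens -> canonical
# ingredient. The canonical set is the six statins of the analysis;
# fluvastatin can be enabled for reuse but is off by default.

.statin_entries <- function() {
  rbind(
    # generics (the ingredient token also covers salt forms by word-boundary
    # matching, e.g. "ROSUVASTATIN CALCIUM")
    data.frame(token = c("rosuvastatin", "atorvastatin", "simvastatin",
                         "pravastatin", "pitavastatin", "lovastatin"),
               canonical = c("rosuvastatin", "atorvastatin", "simvastatin",
                             "pravastatin", "pitavastatin", "lovastatin")),
    # common US brand names incl. combination products
    data.frame(
      token = c("crestor", "ezallor",
                "lipitor", "caduet", "atorvaliq", "lypqozet",
                "zocor", "vytorin", "simcor", "flolipid", "juvisync",
                "pravachol",
                "livalo", "zypitamag",
                "mevacor", "altoprev", "advicor"),
      canonical = c("rosuvastatin", "rosuvastatin",
                    "atorvastatin", "atorvastatin", "atorvastatin",
                    "atorvastatin",
                    "simvastatin", "simvastatin", "simvastatin", "simvastatin",
                    "simvastatin",
                    "pravastatin",
                    "pitavastatin", "pitavastatin",
                    "lovastatin", "lovastatin", "lovastatin"))
  )
}

.fluvastatin_entries <- function() {
  data.frame(token = c("fluvastatin", "lescol"),
             canonical = c("fluvastatin", "fluvastatin"))
}

#' Canonical statin ingredient names
#' @param include_fluvastatin add fluvastatin to the class (off by default).
#' @return character vector of canonical ingredient names.
#' @export
statin_ingredients <- function(include_fluvastatin = FALSE) {
  base <- c("rosuvastatin", "atorvastatin", "simvastatin", "pravastatin",
            "pitavastatin", "lovastatin")
  if (include_fluvastatin) c(base, "fluvastatin") else base
}

#' Build a statin name lexicon
#'
#' Maps verbatim name tokens (generic names, salts implicit via word-boundary
#' matching, common brand names and combination products) to a canonical
#' ingredient. Matching downstream is case-insensitive on word-boundary
#' tokens so that, e.g., `"ROSUVASTATIN CALCIUM"` matches `rosuvastatin` but
#' `"nystatin"` matches nothing.
#'
#' @param include_fluvastatin include fluvastatin entries (default `FALSE`;
#'   the analysis class comprises six statins).
#' @param extra optional data.frame with columns `token`, `canonical` to
#'   append (user extension).
#' @param file optional path to a lexicon file: one `token<TAB>canonical`
#'   entry per line, `#` comments. Entries are appended to the defaults.
#' @return object of class `statin_lexicon`: data.frame with columns
#'   `token`, `canonical`, ordered longest token first.
#' @export
#' @examples
#' lex <- statin_lexicon()
#' classify_statin("CRESTOR", NA, lex)
statin_lexicon <- function(include_fluvastatin = FALSE, extra = NULL,
                           file = NULL) {
  lex <- .statin_entries()
  if (include_fluvastatin) lex <- rbind(lex, .fluvastatin_entries())
  if (!is.null(file)) lex <- rbind(lex, read_lexicon_file(file))
  if (!is.null(extra)) {
    stopifnot(all(c("token", "canonical") %in% names(extra)))
    lex <- rbind(lex, extra[, c("token", "canonical")])
  }
  lex$token <- tolower(trimws(lex$token))
  lex$canonical <- tolower(trimws(lex$canonical))
  lex <- unique(lex)
  lex <- lex[order(-nchar(lex$token), lex$token), ]
  rownames(lex) <- NULL
  class(lex) <- c("statin_lexicon", "data.frame")
  lex
}

#' Read a lexicon file
#'
#' @param file path; one `token<TAB>canonical` per line, `#` starts a comment.
#' @return data.frame with columns `token`, `canonical`.
#' @export
read_lexicon_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(token = character(0), canonical = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed lexicon line(s): ",
                     paste(lines[bad], collapse = "; "))
  data.frame(token = vapply(parts, `[[`, "", 1L),
             canonical = vapply(parts, `[[`, "", 2L))
}

#' Classify a drug name as a statin ingredient
#'
#' Consults `prod_ai` (active ingredient) first, then `drugname`, returning
#' the canonical ingredient of the first (longest-token) lexicon match, or
#' `NA` if neither field matches.
#'
#' @param drugname verbatim DRUGNAME string (may be `NA`).
#' @param prod_ai PROD_AI active-ingredient string (may be `NA`).
#' @param lexicon a [statin_lexicon()].
#' @return canonical ingredient name, or `NA_character_`.
#' @export
classify_statin <- function(drugname, prod_ai, lexicon = statin_lexicon()) {
  match_one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    s <- tolower(s)
    for (i in seq_len(nrow(lexicon))) {
      pat <- paste0("\\b", lexicon$token[i], "\\b")
      if (grepl(pat, s, perl = TRUE)) return(lexicon$canonical[i])
    }
    NA_character_
  }
  out <- match_one(prod_ai)
  if (is.na(out)) out <- match_one(drugname)
  out
}

# vectorized classifier over many name strings; returns canonical or NA.
# Matches on the unique strings only, so a large report table with a small
# vocabulary costs one regex pass per lexicon token.
classify_statin_vec <- function(x, lexicon = statin_lexicon()) {
  ux <- unique(x)
  res <- rep(NA_character_, length(ux))
  lx <- tolower(ux)
  todo <- !is.na(lx) & nzchar(lx)
  for (i in seq_len(nrow(lexicon))) {
    if (!any(todo)) break
    hit <- todo & grepl(paste0("\\b", lexicon$token[i], "\\b"), lx, perl = TRUE)
    res[hit] <- lexicon$canonical[i]
    todo <- todo & !hit
  }
  res[match(x, ux)]
}
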