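#' Normalize a drug name against a synonym vocabulary
#'
#' Spontaneous reports name the same active ingredient many ways: generic
#' name, brand name, stray trademark glyphs, inconsistent case and spacing.
#' Normalization uppercases, trims, collapses internal whitespace, strips
#' trademark glyphs (®, ™) and then maps the result through a
#' synonym vocabulary to a canonical active-ingredient token. Unmapped names
#' are returned uppercased/trimmed, so the function is total and idempotent.
#'
#' @param raw Character vector of raw drug-name strings.
#' @param vocabulary Named character vector mapping synonym (name, matched
#'   case-insensitively) to canonical token (value), e.g.
#'   `c(PIQRAY = "ALPELISIB", VIJOICE = "ALPELISIB")`. See
#'   [vocabulary_from_queries()].
#' @return Character vector of canonical tokens.
#' @examples
#' normalize_drug_name("  ibrance ®", c(IBRANCE = "PALBOCICLIB"))
#' @export
normalize_drug_name <- function(raw, vocabulary = character()) {
  x <- toupper(as.character(raw))
  x <- gsub("[®™]", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  if (length(vocabulary)) {
    names(vocabulary) <- toupper(trimws(names(vocabulary)))
    vocabulary <- toupper(trimws(vocabulary))
    hit <- match(x, names(vocabulary))
    x[!is.na(hit)] <- unname(vocabulary[hit[!is.na(hit)]])
  }
  x
}

#' Add normalized drug names to a universe
#'
#' Adds (or overwrites) the `normalized_name` column of the drug table by
#' applying [normalize_drug_name()] to each raw mention. Routes and dosage
#' strings are left raw; the deduplication key normalizes them on the fly.
#'
#' @param universe A [faers_universe()].
#' @inheritParams normalize_drug_name
#' @return The universe with a `normalized_name` column on `$drug`.
#' @export
normalize_drugs <- function(universe, vocabulary = character()) {
  stopifnot(inherits(universe, "faers_universe"))
  universe$drug$normalized_name <-
    normalize_drug_name(universe$drug$drugname, vocabulary)
  universe
}

#' Build a synonym vocabulary from drug queries
#'
#' Collects the synonym lists of one or more [drug_query()] objects into the
#' named-vector form [normalize_drug_name()] expects.
#'
#' @param queries A single [drug_query()] or a list of them.
#' @return Named character vector, synonym -> canonical token.
#' @export
vocabulary_from_queries <- function(queries) {
  if (inherits(queries, "drug_query")) queries <- list(queries)
  out <- unlist(lapply(queries, function(q) {
    stats::setNames(rep(q$canonical, length(q$synonyms)), q$synonyms)
  }))
  if (is.null(out)) character() else out
}
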