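#' Define a reaction term set
#'
#' A term set is a named collection of MedDRA-style preferred terms used to
#' filter reaction mentions. Matching is exact on the trimmed,
#' case-insensitive term — never substring matching, which would spuriously
#' capture unrelated preferred terms that merely contain a keyword.
#'
#' @param name Label, e.g. `"SAMT"`.
#' @param terms Character vector of preferred terms (non-empty).
#' @param per_drug Logical flag: `TRUE` for term sets whose membership is
#'   drug-specific (the per-drug registration-trial sets).
#' @return An object of class `term_set`.
#' @export
term_set <- function(name, terms, per_drug = FALSE) {
  terms <- unique(toupper(trimws(as.character(terms))))
  terms <- terms[terms != ""]
  if (length(terms) == 0) {
    stop("term set '", name, "' has no terms", call. = FALSE)
  }
  structure(list(name = as.character(name), terms = terms,
                 per_drug = isTRUE(per_drug)),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat("<term_set> ", x$name, if (x$per_drug) " (per-drug)", ": ",
      length(x$terms), " term(s)\n  ", paste(tolower(x$terms), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Built-in stomatitis term filters
#'
#' Returns the four filter strategies used to screen kinase-inhibitor reports
#' for stomatitis-associated adverse events:
#'
#' * `stomatitis` — the single preferred term "stomatitis";
#' * `samt` — Stomatitis-Associated Main Terms: the three most frequent
#'   stomatitis-related terms (stomatitis, aphthous ulcer, mouth ulceration);
#' * `ctt` — Comprehensive Trial Terms: the 11 preferred terms pooled from
#'   the four drugs' phase III registration trials;
#' * `ott` — Original Trial Terms: per-drug registration-trial term lists.
#'   These are label content that varies by drug and are therefore supplied
#'   by the caller (`ott_terms`, a named list of term vectors keyed by
#'   canonical drug token); when absent an empty placeholder is returned with
#'   a warning.
#'
#' By construction `stomatitis` ⊆ `samt` ⊆ `ctt`.
#'
#' @param ott_terms Optional named list: canonical drug token -> character
#'   vector of that drug's registration-trial terms.
#' @return Named list of [term_set()] objects (`ott` is a named list of
#'   per-drug term sets when configured, otherwise `NULL`).
#' @export
builtin_term_sets <- function(ott_terms = NULL) {
  samt <- c("stomatitis", "aphthous ulcer", "mouth ulceration")
  ctt <- c(samt,
           "lip ulceration", "glossodynia", "glossitis", "cheilitis",
           "oral pain", "gingival pain", "oral discomfort",
           "oropharyngeal pain")
  out <- list(
    stomatitis = term_set("STOMATITIS_ONLY", "stomatitis"),
    samt = term_set("SAMT", samt),
    ctt = term_set("CTT", ctt)
  )
  if (is.null(ott_terms)) {
    warning("no per-drug OTT terms configured; 'ott' is NULL", call. = FALSE)
    out$ott <- NULL
  } else {
    stopifnot(is.list(ott_terms), !is.null(names(ott_terms)))
    out$ott <- lapply(stats::setNames(nm = names(ott_terms)), function(d) {
      term_set(paste0("OTT_", d), ott_terms[[d]], per_drug = TRUE)
    })
  }
  out
}

#' Define a drug query
#'
#' A drug query names one active ingredient by its canonical token, the
#' generic and brand synonyms that should map to it, and the inclusive
#' receipt-quarter extraction window (typically first approval quarter to the
#' end of the analyzed snapshot).
#'
#' @param canonical Canonical active-ingredient token (uppercased).
#' @param synonyms Character vector of generic/brand names (non-empty; the
#'   canonical token is added automatically).
#' @param window_start,window_end Inclusive `"YYYYQn"` quarter bounds.
#' @return An object of class `drug_query`.
#' @export
drug_query <- function(canonical, synonyms = character(),
                       window_start, window_end) {
  canonical <- toupper(trimws(canonical))
  synonyms <- unique(c(canonical, toupper(trimws(as.character(synonyms)))))
  synonyms <- synonyms[synonyms != ""]
  if (length(synonyms) == 0) {
    stop("drug query needs at least one synonym", call. = FALSE)
  }
  if (quarter_index(window_start) > quarter_index(window_end)) {
    stop("window start ", window_start, " is after end ", window_end,
         call. = FALSE)
  }
  structure(list(canonical = canonical, synonyms = synonyms,
                 window_start = window_start, window_end = window_end),
            class = "drug_query")
}

#' @export
print.drug_query <- function(x, ...) {
  cat("<drug_query> ", x$canonical, " [", x$window_start, " - ",
      x$window_end, "]\n  synonyms: ", paste(x$synonyms, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Built-in kinase-inhibitor drug queries
#'
#' The four HR+/HER2- breast-cancer kinase inhibitors analyzed by the
#' pipeline, each with its brand-name synonyms and the extraction window from
#' its first FDA-approval quarter through the Q1 2025 snapshot.
#'
#' @return Named list of [drug_query()] objects.
#' @export
builtin_drug_queries <- function() {
  list(
    alpelisib = drug_query("ALPELISIB", c("PIQRAY", "VIJOICE"),
                           "2019Q2", "2025Q1"),
    capivasertib = drug_query("CAPIVASERTIB", "TRUQAP", "2023Q4", "2025Q1"),
    everolimus = drug_query("EVEROLIMUS", c("AFINITOR", "ZORTRESS"),
                            "2009Q2", "2025Q1"),
    palbociclib = drug_query("PALBOCICLIB", "IBRANCE", "2015Q1", "2025Q1")
  )
}

#' Select the reports that mention a drug inside its window
#'
#' Returns the sub-universe of reports carrying at least one drug mention
#' whose normalized name equals the query's canonical token and whose receipt
#' quarter falls inside the query's inclusive window. Reports with an NA
#' receipt quarter are excluded (they cannot be windowed).
#'
#' @param universe A deduplicated, normalized [faers_universe()].
#' @param query A [drug_query()].
#' @return A [faers_universe()] subset of the input.
#' @export
select_drug_reports <- function(universe, query) {
  stopifnot(inherits(universe, "faers_universe"),
            inherits(query, "drug_query"))
  if (!"normalized_name" %in% names(universe$drug) &&
      nrow(universe$drug) > 0) {
    stop("drug names are not normalized; run normalize_drugs() first",
         call. = FALSE)
  }
  hit_ids <- unique(universe$drug$primaryid[
    universe$drug$normalized_name == query$canonical])
  lo <- quarter_index(query$window_start)
  hi <- quarter_index(query$window_end)
  qi <- quarter_index(universe$demo$receipt_quarter)
  in_window <- !is.na(qi) & qi >= lo & qi <= hi
  ids <- intersect(hit_ids, universe$demo$primaryid[in_window])
  subset_universe(universe, ids)
}

#' Count reports matching each term of a filter
#'
#' Counts, for each preferred term of a term set, the number of distinct
#' reports containing that term, plus a total under one of two conventions:
#'
#' * `sum_of_terms` — the column sum of the per-term counts; a report
#'   containing two matching terms contributes twice.
#' * `unique_reports` — the number of distinct reports matching at least one
#'   term; never larger than `sum_of_terms`.
#'
#' @param universe A [faers_universe()] (typically the output of
#'   [select_drug_reports()]).
#' @param set A [term_set()].
#' @param mode Counting convention for the total.
#' @return A list of class `term_counts`: `per_term` (tibble of `term`, `n`),
#'   `total`, `total_unique`, `mode`.
#' @export
count_term_matches <- function(universe, set,
                               mode = c("sum_of_terms", "unique_reports")) {
  if (!is.character(mode) ||
      !all(mode %in% c("sum_of_terms", "unique_reports"))) {
    stop("unknown counting mode: ", paste(mode, collapse = ", "),
         call. = FALSE)
  }
  mode <- match.arg(mode)
  stopifnot(inherits(universe, "faers_universe"), inherits(set, "term_set"))
  pt <- toupper(trimws(universe$reac$pt))
  per_term <- vapply(set$terms, function(tm) {
    dplyr::n_distinct(universe$reac$primaryid[pt == tm])
  }, integer(1))
  unique_total <- dplyr::n_distinct(
    universe$reac$primaryid[pt %in% set$terms])
  structure(list(
    per_term = tibble::tibble(term = tolower(set$terms),
                              n = unname(per_term)),
    total = if (mode == "sum_of_terms") sum(per_term) else unique_total,
    total_unique = unique_total,
    mode = mode,
    set = set$name
  ), class = "term_counts")
}

#' @export
print.term_counts <- function(x, ...) {
  cat("<term_counts> ", x$set, " (", x$mode, ")\n", sep = "")
  print(x$per_term)
  cat("total: ", x$total, "  (unique reports: ", x$total_unique, ")\n",
      sep = "")
  invisible(x)
}

#' Aggregate a per-term count table into filter totals
#'
#' Given an already-tabulated per-term report count table (e.g. a published
#' count matrix with one row per preferred term and one column per drug),
#' computes each filter's total as the sum of the counts of its member terms.
#' Only the `sum_of_terms` convention is computable from marginal per-term
#' counts, since term overlap within reports is unknown.
#'
#' @param counts Data frame with a `term` column plus one numeric column per
#'   drug.
#' @param sets List of [term_set()] objects.
#' @return Tibble with one row per term set and one column per drug.
#' @export
aggregate_term_counts <- function(counts, sets) {
  stopifnot(is.data.frame(counts), "term" %in% names(counts))
  tm <- toupper(trimws(counts$term))
  drugs <- setdiff(names(counts), "term")
  rows <- lapply(sets, function(s) {
    stopifnot(inherits(s, "term_set"))
    missing <- setdiff(s$terms, tm)
    if (length(missing)) {
      warning("term(s) absent from count table treated as 0: ",
              paste(tolower(missing), collapse = ", "), call. = FALSE)
    }
    sel <- tm %in% s$terms
    out <- lapply(counts[sel, drugs, drop = FALSE], sum)
    tibble::as_tibble(c(list(set = s$name), out))
  })
  dplyr::bind_rows(rows)
}
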