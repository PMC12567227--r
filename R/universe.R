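#' Construct a report universe
#'
#' A `faers_universe` holds one quarter-stamped spontaneous-report collection
#' as three tidy tables keyed by `primaryid`, mirroring the layout of the
#' public FAERS quarterly extract:
#'
#' * `demo` — one row per report record: `primaryid`, `caseid`,
#'   `receipt_quarter` (`"YYYYQn"`).
#' * `drug` — one row per drug mention: `primaryid`, `drugname` (raw string),
#'   `route`, `dose`, `role` (`PS`/`SS`/`C`/`I`/`UNK`), and, once
#'   [normalize_drugs()] has run, `normalized_name`.
#' * `reac` — one row per reaction mention: `primaryid`, `pt`
#'   (MedDRA-preferred-term-like string).
#'
#' Before deduplication a universe may contain several records sharing a
#' `primaryid`; [total_reports()] counts distinct primary IDs (the N of the
#' disproportionality contingency tables) while [n_records()] counts raw
#' demographics rows.
#'
#' @param demo,drug,reac Data frames with at least the columns listed above.
#' @return An object of class `faers_universe`.
#' @seealso [read_quarterly_files()], [deduplicate()], [generate_reports()]
#' @export
faers_universe <- function(demo, drug, reac) {
  demo <- tibble::as_tibble(demo)
  drug <- tibble::as_tibble(drug)
  reac <- tibble::as_tibble(reac)
  need <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      stop(what, " table lacks required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  need(demo, c("primaryid", "caseid", "receipt_quarter"), "demo")
  need(drug, c("primaryid", "drugname", "route", "dose", "role"), "drug")
  need(reac, c("primaryid", "pt"), "reac")
  if (any(is.na(demo$primaryid) | demo$primaryid == "")) {
    stop("every report needs a non-empty primaryid", call. = FALSE)
  }
  qok <- is.na(demo$receipt_quarter) |
    grepl("^[0-9]{4}Q[1-4]$", demo$receipt_quarter)
  if (!all(qok)) {
    stop("malformed receipt_quarter value(s): ",
         paste(utils::head(unique(demo$receipt_quarter[!qok]), 3), collapse = ", "),
         call. = FALSE)
  }
  structure(list(demo = demo, drug = drug, reac = reac),
            class = "faers_universe")
}

#' @rdname faers_universe
#' @param universe A `faers_universe`.
#' @export
total_reports <- function(universe) {
  stopifnot(inherits(universe, "faers_universe"))
  dplyr::n_distinct(universe$demo$primaryid)
}

#' @rdname faers_universe
#' @export
n_records <- function(universe) {
  stopifnot(inherits(universe, "faers_universe"))
  nrow(universe$demo)
}

#' @export
print.faers_universe <- function(x, ...) {
  qs <- x$demo$receipt_quarter
  qs <- qs[!is.na(qs)]
  cat("<faers_universe>\n")
  cat("  reports: ", total_reports(x), " distinct primary IDs (",
      n_records(x), " demo records)\n", sep = "")
  cat("  drug mentions: ", nrow(x$drug),
      if ("normalized_name" %in% names(x$drug)) " (normalized)" else "",
      "\n", sep = "")
  cat("  reaction mentions: ", nrow(x$reac), "\n", sep = "")
  if (length(qs)) {
    cat("  quarters: ", min(qs), " to ", max(qs), "\n", sep = "")
  }
  invisible(x)
}

# Restrict a universe to a set of primary IDs, keeping all three tables in
# step. Internal; selection semantics live in select_drug_reports().
subset_universe <- function(universe, ids) {
  faers_universe(
    demo = dplyr::filter(universe$demo, .data$primaryid %in% ids),
    drug = dplyr::filter(universe$drug, .data$primaryid %in% ids),
    reac = dplyr::filter(universe$reac, .data$primaryid %in% ids)
  )
}
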