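#' Deduplicate case records
#'
#' Removes duplicate records on the key (primary ID, normalized drug name,
#' route of administration, dosage) before any counting. Because one report
#' carries many drug mentions but a single primary ID, the key is applied as
#' a two-level rule, each level logged separately:
#'
#' 1. **Within-report collapse** — drug mentions of the same report sharing an
#'    identical (normalized name, route, dosage) key are collapsed to one;
#'    byte-identical repeated reaction mentions are likewise collapsed.
#' 2. **Report drop** — demographics records that repeat an already-seen
#'    primary ID are dropped (a re-emitted record shares its key fields with
#'    the original by construction of the join on `primaryid`).
#'
#' Missing route/dosage compare equal as empty strings; first occurrence in
#' file order wins. The operation is idempotent and never increases the
#' report count.
#'
#' @param universe A [faers_universe()] whose drug table carries
#'   `normalized_name` (run [normalize_drugs()] first).
#' @return The deduplicated universe, with the removal log — a tibble of
#'   `rule` and `removed` counts — attached as attribute `"removal_log"`.
#' @export
deduplicate <- function(universe) {
  stopifnot(inherits(universe, "faers_universe"))
  if (nrow(universe$drug) > 0 && !"normalized_name" %in% names(universe$drug)) {
    stop("drug names are not normalized; run normalize_drugs() first",
         call. = FALSE)
  }

  demo <- universe$demo
  keep_demo <- !duplicated(demo$primaryid)
  dropped_reports <- sum(!keep_demo)

  drug <- universe$drug
  if (nrow(drug) > 0) {
    key <- paste(drug$primaryid,
                 drug$normalized_name,
                 norm_field(drug$route),
                 norm_field(drug$dose),
                 sep = "\r")
    keep_drug <- !duplicated(key)
  } else {
    keep_drug <- logical(0)
  }
  collapsed_drugs <- sum(!keep_drug)

  reac <- universe$reac
  if (nrow(reac) > 0) {
    rkey <- paste(reac$primaryid, toupper(trimws(reac$pt)), sep = "\r")
    keep_reac <- !duplicated(rkey)
  } else {
    keep_reac <- logical(0)
  }
  collapsed_reacs <- sum(!keep_reac)

  out <- faers_universe(demo[keep_demo, ], drug[keep_drug, ], reac[keep_reac, ])
  attr(out, "removal_log") <- tibble::tibble(
    rule = c("duplicate_report_drop", "within_report_drug_collapse",
             "within_report_reaction_collapse"),
    removed = c(dropped_reports, collapsed_drugs, collapsed_reacs)
  )
  out
}

#' Collapse multiple versions of a case
#'
#' FAERS cases are resubmitted over time: several records with distinct
#' primary IDs can share one case ID. Under `mode = "latest"` only the record
#' with the highest primary ID per case is retained (FAERS primary IDs embed
#' the version, so the highest sorts last); `mode = "all"` leaves the
#' universe unchanged.
#'
#' @param universe A [faers_universe()].
#' @param mode `"latest"` or `"all"`.
#' @return The filtered universe.
#' @export
case_version_resolution <- function(universe, mode = c("latest", "all")) {
  if (!is.character(mode) || !all(mode %in% c("latest", "all"))) {
    stop("unknown case-version mode: ", paste(mode, collapse = ", "),
         " (use 'latest' or 'all')", call. = FALSE)
  }
  mode <- match.arg(mode)
  stopifnot(inherits(universe, "faers_universe"))
  if (mode == "all" || nrow(universe$demo) == 0) return(universe)
  demo <- universe$demo
  ord <- order(demo$caseid, demo$primaryid, method = "radix",
               decreasing = c(FALSE, TRUE))
  keep_ids <- demo$primaryid[ord][!duplicated(demo$caseid[ord])]
  out <- subset_universe(universe, keep_ids)
  # preserve original record order
  out$demo <- out$demo[order(match(out$demo$primaryid, demo$primaryid)), ]
  out
}

# Route/dosage fields of the dedup key: case/whitespace-insensitive, missing
# values equal to empty.
norm_field <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[is.na(x)] <- ""
  x
}
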