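#' Read a FAERS-style quarterly extract
#'
#' Reads the three quarterly files (demographics, drug, reaction) and joins
#' them into a [faers_universe()] by report identifier. The public FAERS ASCII
#' dialect is dollar-delimited with a single header row; a plain CSV dialect
#' is accepted via `dialect = "csv"`. Only the columns the pipeline needs are
#' required (`primaryid`, `caseid`, `fda_dt` in DEMO; `primaryid`, `drugname`,
#' `route`, `dose_vbm`, `role_cod` in DRUG; `primaryid`, `pt` in REAC); extra
#' columns are ignored because FAERS schemas drift between quarters.
#'
#' The receipt quarter is derived from the `fda_dt` receipt date when present;
#' otherwise `quarter` supplies the file's quarter label. Drug or reaction
#' rows whose `primaryid` has no demographics row are orphans: they are
#' dropped with a warning and counted in the read log. Raw strings are
#' preserved untouched; name normalization is a separate, explicit step
#' ([normalize_drugs()]).
#'
#' @param demo_path,drug_path,reac_path Paths to the three files.
#' @param dialect `"faers"` (dollar-delimited) or `"csv"`.
#' @param quarter Optional `"YYYYQn"` label used when `fda_dt` is absent or
#'   blank.
#' @param quiet Suppress the read-log message.
#' @return A [faers_universe()]. The read log (records read, joined, orphaned)
#'   is attached as attribute `"read_log"`.
#' @export
read_quarterly_files <- function(demo_path, drug_path, reac_path,
                                 dialect = c("faers", "csv"),
                                 quarter = NULL, quiet = FALSE) {
  dialect <- match.arg(dialect)
  for (p in c(demo_path, drug_path, reac_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  demo <- read_dialect(demo_path, dialect,
                       c("primaryid", "caseid"))
  drug <- read_dialect(drug_path, dialect,
                       c("primaryid", "drugname", "route", "dose_vbm", "role_cod"))
  reac <- read_dialect(reac_path, dialect, c("primaryid", "pt"))

  rq <- if ("fda_dt" %in% names(demo)) quarter_from_date(demo$fda_dt) else
    rep(NA_character_, nrow(demo))
  if (anyNA(rq)) {
    if (!is.null(quarter)) {
      quarter_index(quarter) # validates the label
      rq[is.na(rq)] <- quarter
    } else if (nrow(demo) > 0 && all(is.na(rq))) {
      warning("no receipt dates and no quarter label supplied; ",
              "receipt_quarter is NA", call. = FALSE)
    }
  }

  demo_out <- tibble::tibble(
    primaryid = as.character(demo$primaryid),
    caseid = as.character(demo$caseid),
    receipt_quarter = rq
  )
  known <- unique(demo_out$primaryid)
  drug_out <- tibble::tibble(
    primaryid = as.character(drug$primaryid),
    drugname = as.character(drug$drugname),
    route = blank_na(drug$route),
    dose = blank_na(drug$dose_vbm),
    role = blank_na(drug$role_cod)
  )
  reac_out <- tibble::tibble(
    primaryid = as.character(reac$primaryid),
    pt = as.character(reac$pt)
  )
  orphan_drug <- !(drug_out$primaryid %in% known)
  orphan_reac <- !(reac_out$primaryid %in% known)
  n_orphan <- sum(orphan_drug) + sum(orphan_reac)
  if (n_orphan > 0) {
    warning(n_orphan, " drug/reaction record(s) reference no demographics ",
            "record and were dropped", call. = FALSE)
  }
  universe <- faers_universe(demo_out,
                             drug_out[!orphan_drug, ],
                             reac_out[!orphan_reac, ])
  log <- tibble::tibble(
    file = c("demo", "drug", "reac"),
    read = c(nrow(demo), nrow(drug), nrow(reac)),
    joined = c(nrow(demo), sum(!orphan_drug), sum(!orphan_reac)),
    orphaned = c(0L, sum(orphan_drug), sum(orphan_reac))
  )
  if (!quiet) {
    message("read ", nrow(demo), " demo, ", nrow(drug), " drug, ",
            nrow(reac), " reac records (", n_orphan, " orphaned)")
  }
  attr(universe, "read_log") <- log
  universe
}

#' Write a universe as FAERS-style quarterly files
#'
#' Inverse of [read_quarterly_files()]: emits DEMO/DRUG/REAC files in the
#' chosen dialect such that re-reading reproduces the universe exactly
#' (receipt quarters are serialized as the first day of the quarter).
#'
#' @inheritParams read_quarterly_files
#' @param universe A [faers_universe()].
#' @param out_dir Output directory (created if absent).
#' @param stem Filename stem; files are named `<stem>_demo.txt` etc. (`.csv`
#'   for the CSV dialect).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_quarterly_files <- function(universe, out_dir, dialect = c("faers", "csv"),
                                  stem = "faers") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(universe, "faers_universe"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  ext <- if (dialect == "csv") ".csv" else ".txt"
  paths <- c(
    demo = file.path(out_dir, paste0(stem, "_demo", ext)),
    drug = file.path(out_dir, paste0(stem, "_drug", ext)),
    reac = file.path(out_dir, paste0(stem, "_reac", ext))
  )
  demo <- tibble::tibble(
    primaryid = universe$demo$primaryid,
    caseid = universe$demo$caseid,
    fda_dt = date_from_quarter(universe$demo$receipt_quarter)
  )
  drug <- tibble::tibble(
    primaryid = universe$drug$primaryid,
    drugname = universe$drug$drugname,
    route = universe$drug$route,
    dose_vbm = universe$drug$dose,
    role_cod = universe$drug$role
  )
  reac <- universe$reac[, c("primaryid", "pt")]
  write_dialect(demo, paths[["demo"]], dialect)
  write_dialect(drug, paths[["drug"]], dialect)
  write_dialect(reac, paths[["reac"]], dialect)
  invisible(paths)
}

delim_for <- function(dialect) if (dialect == "csv") "," else "$"

read_dialect <- function(path, dialect, required) {
  df <- readr::read_delim(
    path, delim = delim_for(dialect),
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE,
    trim_ws = FALSE
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "),
         " (expected at least: ", paste(required, collapse = ", "), ")",
         call. = FALSE)
  }
  df
}

write_dialect <- function(df, path, dialect) {
  df[] <- lapply(df, function(x) ifelse(is.na(x), "", as.character(x)))
  if (dialect == "csv") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_delim(df, path, delim = "$", progress = FALSE)
  }
}

blank_na <- function(x) {
  x <- as.character(x)
  ifelse(is.na(x), "", x)
}
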