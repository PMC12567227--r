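#' Configure an end-to-end pipeline run
#'
#' Bundles everything one analysis needs: exactly one input source (a trio of
#' quarterly files or a [synthetic_config()]), the drug queries and term
#' sets, the counting mode for filter totals, the zero-cell policy, the
#' case-version policy, and the seed. Validation happens here, before any
#' computation.
#'
#' @param input_files Optional named list with `demo`, `drug`, `reac` paths
#'   and optionally `dialect` (default `"faers"`) and `quarter`.
#' @param synthetic Optional [synthetic_config()].
#' @param queries Named list of [drug_query()] objects (default the built-in
#'   kinase-inhibitor queries).
#' @param sets Named list of [term_set()] objects (default the built-in
#'   stomatitis filters, without OTT).
#' @param mode Counting convention for filter totals
#'   (`"sum_of_terms"`/`"unique_reports"`).
#' @param zero_policy `"haldane"` or `"strict"`.
#' @param dedup_mode Case-version policy, `"latest"` or `"all"`.
#' @param seed Integer seed (overrides the synthetic config's seed so a run
#'   has a single source of randomness).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_files = NULL, synthetic = NULL,
                       queries = builtin_drug_queries(),
                       sets = suppressWarnings(builtin_term_sets())[
                         c("stomatitis", "samt", "ctt")],
                       mode = c("sum_of_terms", "unique_reports"),
                       zero_policy = c("haldane", "strict"),
                       dedup_mode = c("latest", "all"),
                       seed = 1L) {
  mode <- match.arg(mode)
  zero_policy <- match.arg(zero_policy)
  dedup_mode <- match.arg(dedup_mode)
  if (is.null(input_files) == is.null(synthetic)) {
    stop("exactly one input source required: input_files or synthetic",
         call. = FALSE)
  }
  if (!is.null(input_files)) {
    missing <- setdiff(c("demo", "drug", "reac"), names(input_files))
    if (length(missing)) {
      stop("input_files lacks path(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  if (length(queries) == 0 || !all(vapply(queries, inherits, TRUE, "drug_query"))) {
    stop("queries must be a non-empty list of drug_query objects",
         call. = FALSE)
  }
  if (length(sets) == 0 || !all(vapply(sets, inherits, TRUE, "term_set"))) {
    stop("sets must be a non-empty list of term_set objects", call. = FALSE)
  }
  structure(list(input_files = input_files, synthetic = synthetic,
                 queries = queries, sets = sets, mode = mode,
                 zero_policy = zero_policy, dedup_mode = dedup_mode,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full disproportionality pipeline
#'
#' Executes read (or generate) -> normalize -> deduplicate -> case-version
#' collapse -> per-drug selection -> per-filter counting -> contingency
#' tables -> ROR/PRR/IC and tests, and assembles four artifacts:
#'
#' * `term_counts` — per-term report count matrix (terms x drugs), the
#'   layout of a published count table;
#' * `signals` — one row per drug x term set with cells, all metrics,
#'   bounds, p-values and significance flags;
#' * `percentages` — filter total / drug total x 100 per drug x set, under
#'   both counting conventions;
#' * `manifest` — config echo, seed, formula variants and caveats.
#'
#' When `out_dir` is given the tables are written as CSV and the manifest as
#' JSON; re-running with the same config and seed reproduces the files
#' byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress stage messages.
#' @return The result bundle (list), invisibly when writing, with the
#'   deduplicated universe attached as `$universe`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[pvsignal] ", ...)

  if (!is.null(config$input_files)) {
    f <- config$input_files
    say("reading quarterly files")
    universe <- read_quarterly_files(
      f$demo, f$drug, f$reac,
      dialect = if (is.null(f$dialect)) "faers" else f$dialect,
      quarter = f$quarter, quiet = quiet)
  } else {
    say("generating synthetic universe (n = ", config$synthetic$n_reports, ")")
    syn <- config$synthetic
    syn$seed <- config$seed
    universe <- generate_reports(syn)$universe
  }

  vocab <- vocabulary_from_queries(config$queries)
  universe <- normalize_drugs(universe, vocab)
  say("deduplicating")
  universe <- deduplicate(universe)
  removal_log <- attr(universe, "removal_log")
  universe <- case_version_resolution(universe, config$dedup_mode)
  n_total <- total_reports(universe)
  say("universe: ", n_total, " deduplicated reports")

  all_terms <- unique(unlist(lapply(config$sets, function(s) s$terms)))
  union_set <- term_set("ALL_FILTER_TERMS", all_terms)

  counts_rows <- list()
  pct_rows <- list()
  for (qn in names(config$queries)) {
    q <- config$queries[[qn]]
    sel <- select_drug_reports(universe, q)
    drug_total <- total_reports(sel)
    per_term <- count_term_matches(sel, union_set, config$mode)$per_term
    counts_rows[[qn]] <- dplyr::mutate(per_term, drug = q$canonical,
                                       .before = 1)
    for (sn in names(config$sets)) {
      tc <- count_term_matches(sel, config$sets[[sn]], "sum_of_terms")
      pct_rows[[paste(qn, sn)]] <- tibble::tibble(
        drug = q$canonical,
        set = config$sets[[sn]]$name,
        drug_total = drug_total,
        total_sum_of_terms = tc$total,
        total_unique_reports = tc$total_unique,
        pct_sum_of_terms = percent_of_reports(tc$total, drug_total),
        pct_unique_reports = percent_of_reports(tc$total_unique, drug_total)
      )
    }
  }
  term_counts <- dplyr::bind_rows(counts_rows) |>
    tidyr::pivot_wider(names_from = "drug", values_from = "n")
  percentages <- dplyr::bind_rows(pct_rows)

  say("computing disproportionality statistics")
  signals <- analyze_signals(universe, config$queries, config$sets,
                             config$zero_policy)

  manifest <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    seed = config$seed,
    counting_mode = config$mode,
    zero_policy = config$zero_policy,
    dedup_mode = config$dedup_mode,
    n_reports = n_total,
    removal_log = removal_log,
    formulas = list(
      ror = "ROR=(a*d)/(b*c); 95% CI exp(ln ROR +/- 1.96*sqrt(1/a+1/b+1/c+1/d))",
      prr = "PRR=[a/(a+b)]/[c/(c+d)]; 95% CI exp(ln PRR +/- 1.96*sqrt(1/a-1/(a+b)+1/c-1/(c+d)))",
      ic = "IC=log2((a+0.5)/(E+0.5)), E=(a+b)(a+c)/n; credibility bounds IC -3.3(a+.5)^-1/2 -2(a+.5)^-3/2 / +2.4(a+.5)^-1/2 -0.5(a+.5)^-3/2",
      zero_cells = "Haldane-Anscombe +0.5 on all cells only when a cell is 0"
    ),
    notes = paste(
      "sum_of_terms totals count a report once per matching term and can",
      "exceed unique-report totals when terms co-occur; contingency cells",
      "always use unique-report counting so a+b+c+d = N.")
  )

  bundle <- list(term_counts = term_counts, signals = signals,
                 percentages = percentages, manifest = manifest,
                 universe = universe)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(term_counts, file.path(out_dir, "term_counts.csv"),
                     progress = FALSE)
    readr::write_csv(signals, file.path(out_dir, "signals.csv"),
                     progress = FALSE)
    readr::write_csv(percentages, file.path(out_dir, "percentages.csv"),
                     progress = FALSE)
    readr::write_csv(removal_log, file.path(out_dir, "removal_log.csv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("wrote results to ", out_dir)
    return(invisible(bundle))
  }
  bundle
}

#' Percentage of a drug's reports captured by a filter
#'
#' `100 * filter_total / drug_total`, reported to two decimals — the summary
#' used to compare how much of a drug's report volume each term filter
#' captures.
#'
#' @param filter_total Reports matching the filter.
#' @param drug_total All reports for the drug (must be > 0 for a defined
#'   percentage; zero yields `NA` with a warning).
#' @return Numeric percentage rounded to 2 decimals.
#' @export
percent_of_reports <- function(filter_total, drug_total) {
  out <- ifelse(drug_total > 0, round(100 * filter_total / drug_total, 2),
                NA_real_)
  if (anyNA(out)) {
    warning("percentage undefined for drug_total = 0", call. = FALSE)
  }
  out
}
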