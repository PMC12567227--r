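#' Configure the synthetic report generator
#'
#' Describes a FAERS-like universe with known ground truth: each report draws
#' one primary-suspect drug from a weighted vocabulary, experiences a
#' filter-matching event with probability `p1` when that drug is the target
#' and `p0` otherwise (so the planted reporting odds ratio is
#' `[p1/(1-p1)] / [p0/(1-p0)]`), and carries brand-name synonym noise,
#' concomitant drug mentions, background reaction terms, a receipt quarter,
#' and injected duplicate records.
#'
#' Defaults emulate a large-database screen for a strong
#' mTOR-inhibitor-scale signal: 50,000 reports, a background event
#' probability of 0.005, and a planted odds ratio of 30 against the
#' everolimus target; [event_prob_for_or()] converts a desired odds ratio
#' into `p1`.
#'
#' @param n_reports Number of base reports (> 0).
#' @param drug_vocabulary Named list: canonical token -> character vector of
#'   brand synonyms (may be empty).
#' @param background_drug_weights Sampling weights over the vocabulary's
#'   canonical tokens (default uniform).
#' @param target_drug Canonical token carrying the planted association.
#' @param event_terms Preferred terms drawn (uniformly) when an event occurs.
#' @param p0 Background probability of an event term per report.
#' @param p1 Event probability given the target drug.
#' @param duplicate_rate Fraction of reports re-emitted as duplicates.
#' @param duplicate_mode `"exact"` re-emits with the same primary ID (tests
#'   duplicate-record removal); `"case_version"` re-emits under a new
#'   primary ID sharing the case ID (tests case-version collapse).
#' @param synonym_swap_rate Fraction of target-style drug mentions rendered
#'   as a brand synonym (with occasional trademark glyphs and case noise).
#' @param quarter_range Inclusive `"YYYYQn"` window receipt quarters are
#'   drawn from, uniformly.
#' @param noise_terms Background reaction terms every report also carries.
#' @param seed Integer seed; generation is fully reproducible given it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 50000,
                             drug_vocabulary = default_drug_vocabulary(),
                             background_drug_weights = NULL,
                             target_drug = "EVEROLIMUS",
                             event_terms = c("stomatitis", "aphthous ulcer",
                                             "mouth ulceration"),
                             p0 = 0.005,
                             p1 = event_prob_for_or(0.005, 30),
                             duplicate_rate = 0.05,
                             duplicate_mode = c("exact", "case_version"),
                             synonym_swap_rate = 0.3,
                             quarter_range = c("2009Q2", "2025Q1"),
                             noise_terms = c("nausea", "fatigue", "headache",
                                             "diarrhoea", "rash", "vomiting",
                                             "dizziness", "arthralgia"),
                             seed = 1L) {
  duplicate_mode <- match.arg(duplicate_mode)
  target_drug <- toupper(target_drug)
  if (n_reports <= 0) stop("n_reports must be positive", call. = FALSE)
  for (p in c(p0 = p0, p1 = p1, duplicate_rate = duplicate_rate,
              synonym_swap_rate = synonym_swap_rate)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("probabilities and rates must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!target_drug %in% toupper(names(drug_vocabulary))) {
    stop("target_drug '", target_drug, "' is not in the vocabulary",
         call. = FALSE)
  }
  names(drug_vocabulary) <- toupper(names(drug_vocabulary))
  if (is.null(background_drug_weights)) {
    background_drug_weights <- rep(1, length(drug_vocabulary))
  }
  stopifnot(length(background_drug_weights) == length(drug_vocabulary),
            all(background_drug_weights >= 0))
  quarter_index(quarter_range) # validate
  structure(list(
    n_reports = as.integer(n_reports),
    drug_vocabulary = drug_vocabulary,
    background_drug_weights = background_drug_weights,
    target_drug = target_drug,
    event_terms = toupper(event_terms),
    p0 = p0, p1 = p1,
    duplicate_rate = duplicate_rate,
    duplicate_mode = duplicate_mode,
    synonym_swap_rate = synonym_swap_rate,
    quarter_range = quarter_range,
    noise_terms = toupper(noise_terms),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_drug_vocabulary <- function() {
  list(
    ALPELISIB = c("PIQRAY", "VIJOICE"),
    CAPIVASERTIB = "TRUQAP",
    EVEROLIMUS = c("AFINITOR", "ZORTRESS"),
    PALBOCICLIB = "IBRANCE",
    LETROZOLE = character(),
    FULVESTRANT = "FASLODEX",
    EXEMESTANE = "AROMASIN",
    METFORMIN = character(),
    ATORVASTATIN = "LIPITOR",
    LISINOPRIL = character()
  )
}

#' @rdname synthetic_config
#' @param or Desired planted reporting odds ratio.
#' @export
event_prob_for_or <- function(p0, or) {
  odds <- or * p0 / (1 - p0)
  odds / (1 + odds)
}

#' Generate a synthetic report universe with ground truth
#'
#' Draws `config$n_reports` independent reports, then appends duplicate
#' records on the configured channel. Because duplicates are drawn after all
#' base-report randomness, the deduplicated universe is identical to a
#' duplicate-free generation under the same seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `universe` (a [faers_universe()]) and `truth`, which
#'   records the analytic planted odds ratio, the planted duplicate counts,
#'   per-report labels (drug, event flag, duplicate linkage), and the config.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(config) {
  n <- config$n_reports
  vocab <- config$drug_vocabulary
  tokens <- names(vocab)

  caseid <- sprintf("%08d", seq_len(n) + 10000000L)
  primaryid <- paste0(caseid, "-1")
  drug_tok <- sample(tokens, n, replace = TRUE,
                     prob = config$background_drug_weights)
  is_target <- drug_tok == config$target_drug
  event <- stats::runif(n) < ifelse(is_target, config$p1, config$p0)
  event_term <- sample(config$event_terms, n, replace = TRUE)
  noise_term <- sample(config$noise_terms, n, replace = TRUE)
  quarters <- sample(quarter_seq(config$quarter_range[1],
                                 config$quarter_range[2]),
                     n, replace = TRUE)

  # render the raw suspect-drug string: possibly a brand synonym, possibly
  # with a trademark glyph or lowered case
  raw <- drug_tok
  has_syn <- lengths(vocab)[drug_tok] > 0
  swap <- stats::runif(n) < config$synonym_swap_rate & has_syn
  if (any(swap)) {
    raw[swap] <- vapply(drug_tok[swap], function(tok) {
      s <- vocab[[tok]]
      s[sample.int(length(s), 1L)]
    }, character(1))
    glyph <- swap & stats::runif(n) < 0.25
    raw[glyph] <- paste0(raw[glyph], "®")
  }
  lower <- stats::runif(n) < 0.3
  raw[lower] <- tolower(raw[lower])

  route <- sample(c("ORAL", "", "INTRAVENOUS"), n, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
  dose <- sample(c("", "50 MG", "100 MG", "5 MG DAILY"), n, replace = TRUE,
                 prob = c(0.4, 0.2, 0.2, 0.2))

  # concomitant mentions never include the target, so the planted odds
  # ratio is carried by the suspect drug alone
  n_extra <- stats::rbinom(n, 2L, 0.3)
  co_ids <- rep(primaryid, n_extra)
  co_tok <- sample(setdiff(tokens, config$target_drug), sum(n_extra),
                   replace = TRUE)

  demo <- tibble::tibble(primaryid = primaryid, caseid = caseid,
                         receipt_quarter = quarters)
  drug <- dplyr::bind_rows(
    tibble::tibble(primaryid = primaryid, drugname = raw, route = route,
                   dose = dose, role = "PS"),
    tibble::tibble(primaryid = co_ids, drugname = co_tok, route = "",
                   dose = "", role = "C")
  ) |> dplyr::arrange(.data$primaryid)
  reac <- dplyr::bind_rows(
    tibble::tibble(primaryid = primaryid, pt = tolower(noise_term)),
    tibble::tibble(primaryid = primaryid[event],
                   pt = tolower(event_term[event]))
  ) |> dplyr::arrange(.data$primaryid)

  # duplicate injection happens strictly after all base randomness
  n_dup <- round(config$duplicate_rate * n)
  dup_idx <- if (n_dup > 0) sample.int(n, n_dup) else integer(0)
  planted_exact <- 0L
  planted_versions <- 0L
  if (n_dup > 0) {
    if (config$duplicate_mode == "exact") {
      dup_id <- primaryid[dup_idx]
      planted_exact <- n_dup
    } else {
      dup_id <- paste0(caseid[dup_idx], "-2")
      planted_versions <- n_dup
    }
    src_ids <- primaryid[dup_idx]
    demo <- dplyr::bind_rows(demo, tibble::tibble(
      primaryid = dup_id, caseid = caseid[dup_idx],
      receipt_quarter = quarters[dup_idx]))
    base_drug <- dplyr::filter(drug, .data$primaryid %in% src_ids)
    base_reac <- dplyr::filter(reac, .data$primaryid %in% src_ids)
    remap <- stats::setNames(dup_id, src_ids)
    base_drug$primaryid <- unname(remap[base_drug$primaryid])
    base_reac$primaryid <- unname(remap[base_reac$primaryid])
    drug <- dplyr::bind_rows(drug, base_drug)
    reac <- dplyr::bind_rows(reac, base_reac)
  }

  truth <- list(
    true_odds_ratio = (config$p1 / (1 - config$p1)) /
      (config$p0 / (1 - config$p0)),
    planted_duplicates = planted_exact,
    planted_case_versions = planted_versions,
    labels = tibble::tibble(
      primaryid = primaryid, caseid = caseid, drug = drug_tok,
      event = event,
      duplicate_of = NA_character_
    ),
    duplicated_ids = primaryid[dup_idx],
    config = config
  )
  list(universe = faers_universe(demo, drug, reac), truth = truth)
}

#' Run the full pipeline on a synthetic universe and compare to truth
#'
#' Normalizes, deduplicates, collapses case versions, builds the 2x2 table
#' for the target drug and event term set, and reports the estimated ROR
#' with its 95% interval next to the planted odds ratio, flagging whether
#' the interval covers it.
#'
#' @param universe,truth Output of [generate_reports()].
#' @param query Optional [drug_query()]; defaults to the config's target
#'   drug over the full generation window.
#' @param set Optional [term_set()]; defaults to the config's event terms.
#' @inheritParams ror_with_ci
#' @return One-row tibble: cells, `ror`, `ror_low`, `ror_high`,
#'   `true_or`, `covered`.
#' @export
recover_parameters <- function(universe, truth, query = NULL, set = NULL,
                               zero_policy = "haldane") {
  cfg <- truth$config
  if (is.null(query)) {
    query <- drug_query(cfg$target_drug,
                        cfg$drug_vocabulary[[cfg$target_drug]],
                        cfg$quarter_range[1], cfg$quarter_range[2])
  }
  if (is.null(set)) set <- term_set("EVENT", cfg$event_terms)
  u <- normalize_drugs(universe, vocabulary_from_queries(query))
  u <- deduplicate(u)
  u <- case_version_resolution(u, "latest")
  t <- build_table(u, query, set)
  ci <- ror_with_ci(t, zero_policy)
  tibble::tibble(
    a = t$a, b = t$b, c = t$c, d = t$d, n = t$n,
    ror = ci$estimate, ror_low = ci$low, ror_high = ci$high,
    true_or = truth$true_odds_ratio,
    covered = ci$low <= truth$true_odds_ratio &
      truth$true_odds_ratio <= ci$high
  )
}
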