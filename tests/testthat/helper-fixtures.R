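# Build a small universe from compact per-report specs.
# reports: named list, primaryid -> list(q = quarter, case = caseid,
#   drugs = character vector of raw names, reacs = character vector of PTs,
#   route/dose optional vectors recycled against drugs)
mk_universe <- function(reports) {
  demo <- drug <- reac <- list()
  for (id in names(reports)) {
    r <- reports[[id]]
    demo[[id]] <- tibble::tibble(
      primaryid = id,
      caseid = if (is.null(r$case)) id else r$case,
      receipt_quarter = if (is.null(r$q)) "2020Q1" else r$q
    )
    nd <- length(r$drugs)
    drug[[id]] <- tibble::tibble(
      primaryid = id,
      drugname = r$drugs,
      route = rep_len(if (is.null(r$route)) "" else r$route, nd),
      dose = rep_len(if (is.null(r$dose)) "" else r$dose, nd),
      role = "PS"
    )
    reac[[id]] <- tibble::tibble(primaryid = id, pt = r$reacs)
  }
  faers_universe(dplyr::bind_rows(demo), dplyr::bind_rows(drug),
                 dplyr::bind_rows(reac))
}

# A universe of n reports where the first n_drug mention DRUGX, and given
# index sets carry the event term; everything else gets a filler reaction.
mk_partition_universe <- function(n, drug_ids, event_ids,
                                  drug = "DRUGX", term = "stomatitis") {
  ids <- sprintf("R%03d", seq_len(n))
  reports <- lapply(seq_len(n), function(i) {
    list(
      drugs = if (i %in% drug_ids) drug else "OTHERDRUG",
      reacs = if (i %in% event_ids) c(term, "nausea") else "nausea"
    )
  })
  names(reports) <- ids
  mk_universe(reports)
}

# All-time query for the toy drug above
toy_query <- function(drug = "DRUGX") {
  drug_query(drug, character(), "1990Q1", "2030Q4")
}

# Independent brute-force recount of per-term matches: plain loops over
# reports, no set operations shared with the implementation.
oracle_term_counts <- function(universe, terms, mode) {
  terms <- toupper(trimws(terms))
  ids <- unique(universe$demo$primaryid)
  per <- stats::setNames(integer(length(terms)), terms)
  n_unique <- 0L
  for (id in ids) {
    pts <- toupper(trimws(universe$reac$pt[universe$reac$primaryid == id]))
    hit_any <- FALSE
    for (tm in terms) {
      if (tm %in% pts) {
        per[[tm]] <- per[[tm]] + 1L
        hit_any <- TRUE
      }
    }
    if (hit_any) n_unique <- n_unique + 1L
  }
  list(per_term = unname(per),
       total = if (mode == "sum_of_terms") sum(per) else n_unique)
}

# Exact two-sided Fisher p by enumeration with choose() arithmetic —
# independent of the dhyper-based implementation.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; nn <- c + d; k <- a + c
  if (m + nn == 0) return(1)
  support <- max(0, k - nn):min(k, m)
  probs <- choose(m, support) * choose(nn, k - support) / choose(m + nn, k)
  p_obs <- choose(m, a) * choose(nn, c) / choose(m + nn, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
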