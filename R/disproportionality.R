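#' 2x2 contingency table for one drug-event pair
#'
#' Cells follow the standard disproportionality layout over a universe of N
#' distinct reports: `a` = reports with the target drug and a matching event
#' term, `b` = target drug without a match, `c` = all other reports with a
#' match, `d` = all other reports without. Reports are counted once
#' (unique-report convention), so `a + b + c + d = N`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Object of class `contingency_2x2` with fields `a`, `b`, `c`, `d`,
#'   `n`, and a `degenerate` flag (any margin zero).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  # doubles, not integers: margin products overflow 32-bit at database scale
  cells <- as.numeric(c(a, b, c, d))
  if (length(cells) != 4 || any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative counts", call. = FALSE)
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 degenerate = (a + b == 0) || (c + d == 0) ||
                   (a + c == 0) || (b + d == 0)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("<contingency_2x2> n = ", x$n,
      if (x$degenerate) "  [degenerate margin]", "\n", sep = "")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "other"), c("event", "no event")))
  print(m)
  invisible(x)
}

#' Build the contingency table for a drug query and term filter
#'
#' Partitions a deduplicated universe into the four cells: the drug's
#' selected reports ([select_drug_reports()]) split by whether they match at
#' least one filter term, and all remaining reports split the same way.
#' Unique-report counting is always used here — a report is one row of the
#' 2x2 universe — even when filter totals are elsewhere reported under the
#' `sum_of_terms` convention.
#'
#' @param universe A deduplicated, normalized [faers_universe()].
#' @param query A [drug_query()].
#' @param set A [term_set()].
#' @return A [contingency_2x2()]. A drug with zero selected reports yields
#'   `a = b = 0` and is flagged degenerate.
#' @export
build_table <- function(universe, query, set) {
  stopifnot(inherits(universe, "faers_universe"),
            inherits(set, "term_set"))
  sel <- select_drug_reports(universe, query)
  drug_ids <- unique(sel$demo$primaryid)
  all_ids <- unique(universe$demo$primaryid)
  pt <- toupper(trimws(universe$reac$pt))
  match_ids <- unique(universe$reac$primaryid[pt %in% set$terms])
  a <- length(intersect(drug_ids, match_ids))
  b <- length(drug_ids) - a
  c_ <- length(setdiff(intersect(all_ids, match_ids), drug_ids))
  d <- length(all_ids) - length(drug_ids) - c_
  contingency_2x2(a, b, c_, d)
}

# Apply the Haldane-Anscombe policy: +0.5 on every cell, only when some cell
# is zero. strict errors instead.
corrected_cells <- function(t, zero_policy, metric) {
  cells <- c(a = t$a, b = t$b, c = t$c, d = t$d)
  if (any(cells == 0)) {
    if (zero_policy == "strict") {
      stop(metric, " undefined: zero cell(s) ",
           paste(names(cells)[cells == 0], collapse = ", "),
           " (zero_policy = 'strict')", call. = FALSE)
    }
    cells <- cells + 0.5
  }
  cells
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = (a d)/(b c), the odds of the event among the drug's reports divided
#' by the odds among all other reports. The interval is the Woolf/Wald
#' log-normal interval `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Under `zero_policy = "haldane"` 0.5 is added to every cell when any cell
#' is zero (Haldane-Anscombe), keeping rare-event estimates defined;
#' `"strict"` raises an error instead.
#'
#' @param t A [contingency_2x2()].
#' @param zero_policy `"haldane"` or `"strict"`.
#' @param conf_z Normal quantile for the interval (1.96 for 95%).
#' @return Tibble with `estimate`, `low`, `high`.
#' @export
ror_with_ci <- function(t, zero_policy = c("haldane", "strict"),
                        conf_z = 1.96) {
  zero_policy <- match.arg(zero_policy)
  k <- corrected_cells(t, zero_policy, "ROR")
  est <- (k[["a"]] * k[["d"]]) / (k[["b"]] * k[["c"]])
  se <- sqrt(sum(1 / k))
  tibble::tibble(estimate = est,
                 low = exp(log(est) - conf_z * se),
                 high = exp(log(est) + conf_z * se))
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' PRR = `[a/(a+b)] / [c/(c+d)]`, the proportion of the event among the
#' drug's reports relative to all other reports, with the log-normal interval
#' `exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. Zero cells are
#' handled as in [ror_with_ci()].
#'
#' @inheritParams ror_with_ci
#' @return Tibble with `estimate`, `low`, `high`.
#' @export
prr_with_ci <- function(t, zero_policy = c("haldane", "strict"),
                        conf_z = 1.96) {
  zero_policy <- match.arg(zero_policy)
  k <- corrected_cells(t, zero_policy, "PRR")
  est <- (k[["a"]] / (k[["a"]] + k[["b"]])) /
    (k[["c"]] / (k[["c"]] + k[["d"]]))
  se <- sqrt(1 / k[["a"]] - 1 / (k[["a"]] + k[["b"]]) +
               1 / k[["c"]] - 1 / (k[["c"]] + k[["d"]]))
  tibble::tibble(estimate = est,
                 low = exp(log(est) - conf_z * se),
                 high = exp(log(est) + conf_z * se))
}

#' Information Component with 95% credibility interval
#'
#' The Bayesian Information Component in its observed-versus-expected form
#' with +0.5 shrinkage: with expected count `E = (a+b)(a+c)/n`,
#' `IC = log2((a + 0.5)/(E + 0.5))`. The shrinkage term pulls sparse
#' estimates toward zero, which is what makes the IC well suited to small
#' report counts. Bounds use the standard credibility approximation
#' `IC_low = IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}` and
#' `IC_high = IC + 2.4 (a+0.5)^{-1/2} - 0.5 (a+0.5)^{-3/2}`. Significance is
#' conventionally declared when the lower bound exceeds zero.
#'
#' @param t A [contingency_2x2()] with `n > 0`.
#' @return Tibble with `estimate`, `low`, `high`, `expected`.
#' @export
ic_with_ci <- function(t) {
  if (t$n <= 0) stop("IC undefined for an empty universe", call. = FALSE)
  e <- (t$a + t$b) * (t$a + t$c) / t$n
  a5 <- t$a + 0.5
  ic <- log2(a5 / (e + 0.5))
  tibble::tibble(
    estimate = ic,
    low = ic - 3.3 * a5^(-0.5) - 2 * a5^(-1.5),
    high = ic + 2.4 * a5^(-0.5) - 0.5 * a5^(-1.5),
    expected = e
  )
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' Exact two-sided p-value from the hypergeometric distribution over all
#' tables with the observed margins: the sum of the probabilities of every
#' table no more probable than the observed one (with the conventional
#' `1 + 1e-7` relative guard against floating-point ties).
#'
#' @param t A [contingency_2x2()] with integer cells.
#' @return The p-value.
#' @export
fisher_exact <- function(t) {
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells != round(cells))) {
    stop("Fisher's exact test needs integer cells", call. = FALSE)
  }
  m <- t$a + t$b            # drug reports
  nn <- t$c + t$d           # other reports
  k <- t$a + t$c            # event reports
  if (t$n == 0) return(1)
  support <- max(0L, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(t$a, m, nn, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Chi-square test for a 2x2 table, with or without Yates' correction
#'
#' Pearson's chi-square statistic `sum((|O - E| - h)^2 / E)` over the four
#' cells, with `h = 0.5` under Yates' continuity correction (capped at
#' `|O - E|` so the correction never overshoots) and `h = 0` otherwise;
#' p-value from the chi-square distribution with 1 degree of freedom.
#'
#' @param t A [contingency_2x2()].
#' @param yates Apply the continuity correction?
#' @return Tibble with `statistic`, `p_value`, `yates`.
#' @export
chi_square <- function(t, yates = FALSE) {
  if (t$n <= 0) stop("chi-square undefined for an empty table", call. = FALSE)
  obs <- c(t$a, t$b, t$c, t$d)
  exp_ <- c((t$a + t$b) * (t$a + t$c), (t$a + t$b) * (t$b + t$d),
            (t$c + t$d) * (t$a + t$c), (t$c + t$d) * (t$b + t$d)) / t$n
  if (any(exp_ == 0)) {
    stop("chi-square undefined: zero expected cell (degenerate margin)",
         call. = FALSE)
  }
  dev <- abs(obs - exp_)
  h <- if (isTRUE(yates)) pmin(0.5, dev) else 0
  stat <- sum((dev - h)^2 / exp_)
  tibble::tibble(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 yates = isTRUE(yates))
}

#' Significance classification of a signal
#'
#' A ROR or PRR is significant at alpha = 0.05 when its 95% confidence
#' interval excludes 1.0; the IC is significant when its lower credibility
#' bound is above zero. Pure function of the interval bounds.
#'
#' @param ror_low,ror_high,prr_low,prr_high,ic_low Interval bounds.
#' @return Tibble of logical flags `significant_ror`, `significant_prr`,
#'   `significant_ic`.
#' @export
classify_significance <- function(ror_low, ror_high, prr_low, prr_high,
                                  ic_low) {
  tibble::tibble(
    significant_ror = ror_low > 1 | ror_high < 1,
    significant_prr = prr_low > 1 | prr_high < 1,
    significant_ic = ic_low > 0
  )
}

#' All disproportionality statistics for one table
#'
#' Convenience wrapper computing ROR, PRR and IC with 95% intervals,
#' Fisher's exact p, chi-square p with and without Yates' correction, and
#' the significance flags, as a single one-row tibble.
#'
#' @inheritParams ror_with_ci
#' @return One-row tibble with cells, metrics, bounds, p-values and flags.
#' @export
signal_stats <- function(t, zero_policy = c("haldane", "strict")) {
  zero_policy <- match.arg(zero_policy)
  ror_ci <- ror_with_ci(t, zero_policy)
  prr_ci <- prr_with_ci(t, zero_policy)
  ic_ci <- ic_with_ci(t)
  flags <- classify_significance(ror_ci$low, ror_ci$high,
                                 prr_ci$low, prr_ci$high, ic_ci$low)
  tibble::tibble(
    a = t$a, b = t$b, c = t$c, d = t$d, n = t$n,
    ror = ror_ci$estimate, ror_low = ror_ci$low, ror_high = ror_ci$high,
    prr = prr_ci$estimate, prr_low = prr_ci$low, prr_high = prr_ci$high,
    ic = ic_ci$estimate, ic_low = ic_ci$low, ic_high = ic_ci$high,
    fisher_p = fisher_exact(t),
    chi2_p = chi_square(t, yates = FALSE)$p_value,
    chi2_yates_p = chi_square(t, yates = TRUE)$p_value,
    degenerate = t$degenerate
  ) |> dplyr::bind_cols(flags)
}

#' Signal statistics for every drug query x term set
#'
#' Maps [build_table()] + [signal_stats()] over the cross of drug queries and
#' term sets, returning the long results table the pipeline writes out.
#'
#' @param universe A deduplicated, normalized [faers_universe()].
#' @param queries Named list of [drug_query()] objects.
#' @param sets Named list of [term_set()] objects.
#' @inheritParams ror_with_ci
#' @return Tibble with one row per drug x set, led by `drug` and `set`.
#' @export
analyze_signals <- function(universe, queries, sets,
                            zero_policy = c("haldane", "strict")) {
  zero_policy <- match.arg(zero_policy)
  rows <- list()
  for (qn in names(queries)) {
    for (sn in names(sets)) {
      t <- build_table(universe, queries[[qn]], sets[[sn]])
      rows[[paste(qn, sn)]] <- dplyr::bind_cols(
        tibble::tibble(drug = queries[[qn]]$canonical,
                       set = sets[[sn]]$name),
        signal_stats(t, zero_policy)
      )
    }
  }
  dplyr::bind_rows(rows)
}
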