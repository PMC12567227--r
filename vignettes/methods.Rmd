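---
title: "Methods: disproportionality screening of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem and the analysis unit

Spontaneous-report databases like FAERS collect unverified adverse-event
reports; they measure reporting, not incidence. The canonical question they
can answer is a disproportionality one: *is event X reported more often
with drug Y than with everything else?* `pvsignal` answers it for
stomatitis — oral mucosal inflammation, a recognized toxicity of
PI3K/AKT/mTOR-pathway inhibitors — across four breast-cancer kinase
inhibitors, but every component is generic over drugs, terms and windows.

The analysis unit is the *deduplicated report*. A report carries one or
more drug mentions (free-text names, route, dosage, reporting role), one or
more reaction preferred terms, and a receipt quarter. In memory a universe
is three tidy tables (demographics, drug, reaction) keyed by `primaryid`,
exactly the shape of the public quarterly files.

## Deduplication

Duplicate submissions inflate counts, so dedup precedes all counting. The
matching key is (primary ID, normalized drug name, route, dosage). Because
one report holds many drug mentions under a single primary ID, the key is
operationalized as a two-level rule: within a report, drug mentions with an
identical (name, route, dosage) triple collapse to one; across records, a
repeated primary ID is dropped, first occurrence winning. Missing route or
dosage compares equal to empty — on sparse fields any other convention
makes dedup nondeterministic. Both levels are logged separately so the
removal log sums exactly to the records removed.

Resubmitted *case versions* (same case ID, new primary ID) are a different
phenomenon and get a separate, configurable pass:
`case_version_resolution(mode = "latest")` keeps the highest primary ID
per case. Whether a published screen collapsed versions is usually
unstated; we default to `latest` (the conservative choice — one case, one
row) and expose `all` for sensitivity analysis.

## Term filters and the two counting conventions

Reaction matching is exact (case-insensitive, trimmed) on preferred terms.
Substring matching is deliberately rejected: preferred terms are a
controlled vocabulary, and a substring rule would capture e.g. "aphthous
stomatitis" — a term that does not even exist in FAERS indexing — or other
compounds the analyst never chose. Three filter strategies ship built in
(single term; SAMT, 3 terms; CTT, 11 terms; nested by construction);
per-drug OTT lists are configuration because registration-trial term lists
are label content that should be supplied, not hardcoded from memory.

Filter totals support two conventions. `sum_of_terms` adds per-term report
counts, so a report matching two terms counts twice; `unique_reports`
counts distinct matching reports. Published tables are often column sums
(`sum_of_terms`), while a contingency table must count each report once —
the package therefore defaults filter totals to `sum_of_terms` but always
builds 2×2 cells under `unique_reports`, and the pipeline reports both,
flagging in its manifest that the two can legitimately differ. This
mirrors a real inconsistency pattern in published count tables, where a
"total reports" row and the text's column sums need not agree.

Per-drug extraction windows (inclusive receipt quarters, e.g. alpelisib
2019Q2–2025Q1, its approval quarter through the snapshot) bound the
selected reports; out-of-window reports for the drug still belong to the
comparator side of the table, so cells always sum to N.

## The statistics

With cells a (drug ∧ event), b, c, d over N deduplicated reports:

* **ROR** = (a·d)/(b·c), interval exp(ln ROR ± z·√(1/a+1/b+1/c+1/d)),
  the Woolf log-normal interval.
* **PRR** = [a/(a+b)]/[c/(c+d)], interval
  exp(ln PRR ± z·√(1/a − 1/(a+b) + 1/c − 1/(c+d))).
* **IC** = log₂((a+½)/(E+½)) with E = (a+b)(a+c)/n, the
  observed-vs-expected Bayesian form with +0.5 shrinkage used in
  FAERS/VigiBase practice, with the standard credibility approximation
  IC ± {3.3, 2.4}·(a+½)^(−1/2) − {2, 0.5}·(a+½)^(−3/2). The IC variant is
  a genuine design choice (the literature names several); we use this one
  because it is the canonical large-database screen and record the formula
  in the run manifest so results are self-describing. At a = E the IC is
  exactly 0 at any magnitude; at a = 0 shrinkage bounds it at
  log₂(½/(E+½)) instead of diverging.

z is fixed at 1.96: all intervals are 95%. Significance is interval-based:
ROR/PRR significant when the interval excludes 1 (either side — protective
signals count), IC when its lower bound exceeds 0.

**Zero cells.** Default policy is Haldane–Anscombe: +0.5 on *every* cell,
applied *only* when some cell is zero, keeping rare-drug estimates (a
13-report drug, say) defined while leaving ordinary tables untouched.
`strict` turns zeros into an explicit error for analysts who prefer
refusal over correction.

**Tests.** Fisher's exact two-sided p sums hypergeometric probabilities of
all tables (fixed margins) no more probable than observed, with the
conventional 1+1e−7 relative guard against floating-point ties — the same
convention as `stats::fisher.test`, which the test suite uses as an
independent cross-check alongside a `choose()`-arithmetic enumeration
oracle. Chi-square uses Σ(|O−E|−h)²/E with h = 0.5 under Yates (capped at
|O−E| so the correction cannot overshoot), df = 1. Degenerate margins
(zero expected cells) are an error, not a silent NaN.

## The synthetic generator

`generate_reports()` emulates the structural features the pipeline must
survive: multi-drug reports (suspect + concomitants), brand-synonym
rendering with trademark glyphs and case noise, sparse route/dosage
strings, background reaction terms, uniform receipt quarters, and injected
duplicates on two channels (exact re-emission of a primary ID; case-version
resubmission under a new one). Events are planted at report level: a report
whose suspect drug is the target carries a filter term with probability p1,
others with p0, giving an analytic planted odds ratio
[p1(1−p0)]/[p0(1−p1)]. Concomitant mentions never include the target so the
planted OR is exact.

Defaults are the study conditions used throughout the tests: n = 50,000
reports (large enough that an everolimus-scale signal, OR = 30 at
p0 = 0.005, yields hundreds of exposed-event reports, yet a full pipeline
run stays around a second), duplicate rate 0.05, synonym swap rate 0.3,
quarters 2009Q2–2025Q1 (the widest built-in window). Duplicates are drawn
strictly after all base-report randomness, so under one seed the
deduplicated universe is identical to a duplicate-free generation — which
is what lets dedup be tested for *exactness* rather than approximate
counts.

What the generator does **not** emulate: demographics, reporter type,
narrative text, MedDRA hierarchy, correlated multi-drug exposure,
time-varying reporting rates, or the true FAERS name-noise distribution.
Passing recovery tests therefore shows the pipeline is correct and
calibrated under independence; it does not validate the epidemiology of
any real signal, where confounding by indication, polypharmacy and
stimulated reporting all operate.

## Test and calibration problem sizes

The suite's simulation scales are design choices balancing statistical
resolution against desk-scale runs: interval calibration uses 2,000
binomial tables (n₁ = 1,000 exposed / n₀ = 10,000 comparator at a 5%
background rate — large enough for the Wald interval's nominal coverage to
hold); planted-OR recovery and null false-positive rates use 100 seeds at
n = 50,000 per planted OR in {1, 3, 30}; Fisher oracle equivalence
enumerates all 4,096 tables with cells ≤ 7 plus 600 random tables with
margins up to 30. The acceptance script reruns lighter variants of the
same computations from a single command-line seed.

## Interfaces and other design decisions

The R API is the primary interface (this is an analysis package, not a
shell tool); `run_pipeline()` orchestrates everything and a thin Rscript
CLI under `inst/cli/` wraps generate/analyze/stats for shell use. The
reader supports the dollar-delimited ASCII dialect and CSV; the XML
distribution is out of scope. Drug role codes (suspect vs concomitant) are
carried but not filtered on by default — which roles a published screen
retained is rarely stated, so selection is by name match, with roles
available to the caller. Published headline estimates from a full
database snapshot are not reproducible from a desk build (the snapshot is
an external, versioned input); the package instead pins behavior to
published *count tables* plus property-based calibration, and leaves
mapping headline figures to specific filters to the user.
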