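write_lines_file <- function(lines, dir, name) {
  p <- file.path(dir, name)
  writeLines(lines, p)
  p
}

test_that("reader joins demo, drug and reaction records by report id", {
  d <- withr::local_tempdir()
  demo <- write_lines_file(c("primaryid$caseid$fda_dt",
                             "1001-1$1001$20200815"), d, "demo.txt")
  drug <- write_lines_file(c("primaryid$drugname$route$dose_vbm$role_cod",
                             "1001-1$PIQRAY$ORAL$300 MG$PS",
                             "1001-1$FULVESTRANT$$$C"), d, "drug.txt")
  reac <- write_lines_file(c("primaryid$pt", "1001-1$Stomatitis"), d, "reac.txt")
  u <- read_quarterly_files(demo, drug, reac, quiet = TRUE)
  expect_equal(total_reports(u), 1)
  expect_equal(nrow(u$drug), 2)
  expect_equal(nrow(u$reac), 1)
  expect_equal(u$demo$receipt_quarter, "2020Q3")
  expect_equal(u$drug$drugname, c("PIQRAY", "FULVESTRANT"))
})

test_that("empty demographics file yields an empty universe", {
  d <- withr::local_tempdir()
  demo <- write_lines_file("primaryid$caseid$fda_dt", d, "demo.txt")
  drug <- write_lines_file("primaryid$drugname$route$dose_vbm$role_cod",
                           d, "drug.txt")
  reac <- write_lines_file("primaryid$pt", d, "reac.txt")
  u <- read_quarterly_files(demo, drug, reac, quiet = TRUE)
  expect_equal(total_reports(u), 0)
  expect_equal(n_records(u), 0)
})

test_that("orphan drug/reaction records are dropped with a warning and logged", {
  d <- withr::local_tempdir()
  demo <- write_lines_file(c("primaryid$caseid$fda_dt",
                             "1$1$20210101"), d, "demo.txt")
  drug <- write_lines_file(c("primaryid$drugname$route$dose_vbm$role_cod",
                             "1$A$$$PS", "99$B$$$PS"), d, "drug.txt")
  reac <- write_lines_file(c("primaryid$pt", "99$rash"), d, "reac.txt")
  expect_warning(
    u <- read_quarterly_files(demo, drug, reac, quiet = TRUE),
    "orphan|reference no demographics")
  expect_equal(nrow(u$drug), 1)
  expect_equal(nrow(u$reac), 0)
  log <- attr(u, "read_log")
  expect_equal(log$orphaned, c(0L, 1L, 1L))
  expect_equal(log$read, c(1L, 2L, 1L))
})

test_that("missing files and malformed headers raise named errors", {
  d <- withr::local_tempdir()
  demo <- write_lines_file("primaryid$caseid$fda_dt", d, "demo.txt")
  reac <- write_lines_file("primaryid$pt", d, "reac.txt")
  expect_error(
    read_quarterly_files(demo, file.path(d, "nope.txt"), reac, quiet = TRUE),
    "nope.txt")
  bad <- write_lines_file("primaryid$name", d, "bad_drug.txt")
  expect_error(read_quarterly_files(demo, bad, reac, quiet = TRUE),
               "drugname")
})

test_that("write then read round-trips a synthetic universe in both dialects", {
  g <- generate_reports(synthetic_config(n_reports = 50, seed = 11,
                                         duplicate_rate = 0.1))
  for (dialect in c("faers", "csv")) {
    d <- withr::local_tempdir()
    paths <- write_quarterly_files(g$universe, d, dialect = dialect)
    expect_true(all(file.exists(paths)))
    u2 <- read_quarterly_files(paths[["demo"]], paths[["drug"]],
                               paths[["reac"]], dialect = dialect,
                               quiet = TRUE)
    expect_equal(u2$demo, g$universe$demo)
    expect_equal(u2$drug, g$universe$drug)
    expect_equal(u2$reac, g$universe$reac)
  }
})

test_that("writer row counts mirror the universe and empty universes give headers only", {
  u <- mk_universe(list(`10` = list(drugs = c("A", "B"),
                                    reacs = c("rash", "nausea", "pyrexia"))))
  d <- withr::local_tempdir()
  paths <- write_quarterly_files(u, d)
  expect_equal(length(readLines(paths[["demo"]])), 2) # header + 1
  expect_equal(length(readLines(paths[["drug"]])), 3)
  expect_equal(length(readLines(paths[["reac"]])), 4)

  empty <- faers_universe(
    tibble::tibble(primaryid = character(), caseid = character(),
                   receipt_quarter = character()),
    tibble::tibble(primaryid = character(), drugname = character(),
                   route = character(), dose = character(),
                   role = character()),
    tibble::tibble(primaryid = character(), pt = character()))
  paths <- write_quarterly_files(empty, withr::local_tempdir())
  expect_true(all(vapply(paths, function(p) length(readLines(p)) == 1L, TRUE)))
})

test_that("drug-name normalization strips glyphs, maps synonyms and is idempotent", {
  vocab <- c(PIQRAY = "ALPELISIB", VIJOICE = "ALPELISIB",
             IBRANCE = "PALBOCICLIB")
  expect_equal(normalize_drug_name("Piqray", vocab), "ALPELISIB")
  expect_equal(normalize_drug_name("ALPELISIB", vocab), "ALPELISIB")
  expect_equal(normalize_drug_name("  ibrance ®", vocab), "PALBOCICLIB")
  expect_equal(normalize_drug_name("unknown drug  x", vocab),
               "UNKNOWN DRUG X")
  # idempotence and case-insensitivity over every vocabulary entry
  for (syn in names(vocab)) {
    once <- normalize_drug_name(syn, vocab)
    expect_equal(normalize_drug_name(once, vocab), once)
    expect_equal(normalize_drug_name(tolower(syn), vocab),
                 normalize_drug_name(toupper(syn), vocab))
  }
})

test_that("quarter helpers parse, order and invert; bad labels error", {
  expect_true(quarter_index("2019Q2") < quarter_index("2025Q1"))
  expect_equal(quarter_label(quarter_index("2019Q4") + 1L), "2020Q1")
  expect_equal(quarter_seq("2024Q3", "2025Q1"),
               c("2024Q3", "2024Q4", "2025Q1"))
  expect_error(quarter_index("2019-Q2"), "malformed")
  expect_error(quarter_seq("2025Q1", "2024Q1"), "after")
})
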