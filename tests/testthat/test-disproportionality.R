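test_that("contingency cells partition the universe by drug and term match", {
  # 10 reports: 4 with the drug (2 matching), 6 without (1 matching)
  u <- mk_partition_universe(10, drug_ids = 1:4, event_ids = c(1, 2, 5))
  u <- normalize_drugs(u, character())
  t <- build_table(u, toy_query(), term_set("S", "stomatitis"))
  expect_equal(c(t$a, t$b, t$c, t$d), c(2, 2, 1, 5))
  expect_equal(t$n, 10)
  expect_false(t$degenerate)
})

test_that("contingency cells match a brute-force partition on random universes", {
  withr::with_seed(404, {
    for (rep in 1:5) {
      n <- sample(15:40, 1)
      drug_ids <- sample(n, sample(3:8, 1))
      event_ids <- sample(n, sample(2:10, 1))
      u <- normalize_drugs(mk_partition_universe(n, drug_ids, event_ids),
                           character())
      t <- build_table(u, toy_query(), term_set("S", "stomatitis"))
      # independent recount
      a <- length(intersect(drug_ids, event_ids))
      expect_equal(t$a, a)
      expect_equal(t$b, length(drug_ids) - a)
      expect_equal(t$c, length(setdiff(event_ids, drug_ids)))
      expect_equal(t$n, n)
    }
  })
})

test_that("degenerate tables are flagged and empty-event tables have a = c = 0", {
  u <- normalize_drugs(mk_partition_universe(8, 1:3, integer(0)), character())
  t <- build_table(u, toy_query(), term_set("S", "stomatitis"))
  expect_equal(c(t$a, t$c), c(0, 0))
  expect_equal(t$b + t$d, t$n)
  all_drug <- normalize_drugs(mk_partition_universe(5, 1:5, 1:2), character())
  t2 <- build_table(all_drug, toy_query(), term_set("S", "stomatitis"))
  expect_equal(c(t2$c, t2$d), c(0, 0))
  expect_true(t2$degenerate)
})

test_that("ROR is the cross-product ratio with a Woolf log-normal interval", {
  t <- contingency_2x2(10, 90, 100, 9900)
  r <- ror_with_ci(t)
  expect_equal(r$estimate, 11.0)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  expect_equal(r$low, exp(log(11) - 1.96 * se))
  expect_equal(r$high, exp(log(11) + 1.96 * se))
  for (k in c(1, 5, 50)) {
    sym <- ror_with_ci(contingency_2x2(k, k, k, k))
    expect_equal(sym$estimate, 1.0)
    expect_true(sym$low < 1 && sym$high > 1)
  }
})

test_that("zero cells follow the Haldane-Anscombe policy or error under strict", {
  t <- contingency_2x2(1, 0, 1, 1)
  expect_equal(ror_with_ci(t, "haldane")$estimate, 3.0) # (1.5*1.5)/(0.5*1.5)
  expect_error(ror_with_ci(t, "strict"), "zero cell")
  expect_error(prr_with_ci(t, "strict"), "zero cell")
  # non-degenerate tables are untouched by the policy
  t2 <- contingency_2x2(10, 90, 100, 9900)
  expect_equal(ror_with_ci(t2, "haldane"), ror_with_ci(t2, "strict"))
})

test_that("PRR is the proportion ratio and stays finite at a = 0", {
  t <- contingency_2x2(10, 90, 100, 9900)
  expect_equal(prr_with_ci(t)$estimate, 10.0)
  expect_equal(prr_with_ci(contingency_2x2(7, 7, 7, 7))$estimate, 1.0)
  p0 <- prr_with_ci(contingency_2x2(0, 50, 100, 9900), "haldane")
  expect_true(is.finite(p0$estimate) && p0$estimate < 1)
})

test_that("IC equals the shrunk log2 observed/expected with credibility bounds", {
  # a = E exactly -> IC = 0 regardless of magnitude
  for (k in c(2, 20, 200)) {
    t <- contingency_2x2(k, k, k, k) # E = 2k*2k/4k = k = a
    expect_equal(ic_with_ci(t)$estimate, 0)
  }
  # a = 3, E = 1: margins (a+b)(a+c)/n = 1 with n = 16, a+b = a+c = 4
  t <- contingency_2x2(3, 1, 1, 11)
  ic <- ic_with_ci(t)
  expect_equal(ic$expected, 1)
  expect_equal(ic$estimate, log2(3.5 / 1.5), tolerance = 1e-12)
  expect_equal(ic$estimate, 1.2224, tolerance = 1e-4)
  a5 <- 3.5
  expect_equal(ic$low, ic$estimate - 3.3 / sqrt(a5) - 2 * a5^(-1.5))
  expect_equal(ic$high, ic$estimate + 2.4 / sqrt(a5) - 0.5 * a5^(-1.5))
  expect_true(ic$low < ic$estimate && ic$estimate < ic$high)
})

test_that("IC shrinkage bounds the a = 0 estimate", {
  t <- contingency_2x2(0, 40, 10, 50) # E = 40 * 10 / 100 = 4
  ic <- ic_with_ci(t)
  e <- (t$a + t$b) * (t$a + t$c) / t$n
  expect_equal(ic$estimate, log2(0.5 / (e + 0.5)))
  expect_true(is.finite(ic$estimate) && ic$estimate < 0)
  # an unshrunk log2(eps/E) diverges; the shrunk value cannot
  expect_lt(abs(ic$estimate), log2((e + 0.5) / 0.5) + 1e-12)
})

test_that("Fisher p equals brute-force enumeration and the most probable table gives 1", {
  for (k in c(1, 4, 9)) {
    expect_equal(fisher_exact(contingency_2x2(k, k, k, k)), 1.0)
  }
  # (5,0,0,5): 6 tables with these margins, enumerated via choose()
  p <- fisher_exact(contingency_2x2(5, 0, 0, 5))
  expect_equal(p, oracle_fisher(5, 0, 0, 5), tolerance = 1e-14)
  expect_equal(p, 2 / choose(10, 5), tolerance = 1e-14)
  withr::with_seed(505, {
    for (rep in 1:50) {
      cells <- rpois(4, 5)
      t <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
      expect_equal(fisher_exact(t),
                   oracle_fisher(t$a, t$b, t$c, t$d), tolerance = 1e-12)
      if (t$n > 0 && !t$degenerate) {
        expect_equal(fisher_exact(t),
                     stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("chi-square matches hand arithmetic and Yates never increases it", {
  t <- contingency_2x2(10, 90, 100, 9900)
  obs <- c(10, 90, 100, 9900)
  expd <- c(100 * 110, 100 * 9990, 10000 * 110, 10000 * 9990) / 10100
  expect_equal(chi_square(t)$statistic, sum((obs - expd)^2 / expd))
  expect_equal(chi_square(contingency_2x2(3, 3, 3, 3))$statistic, 0)
  expect_equal(chi_square(contingency_2x2(3, 3, 3, 3))$p_value, 1)
  withr::with_seed(606, {
    for (rep in 1:20) {
      cells <- rpois(4, 8) + 1
      t <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
      m <- matrix(cells, 2, byrow = TRUE)
      expect_equal(chi_square(t, yates = FALSE)$statistic,
                   unname(suppressWarnings(
                     stats::chisq.test(m, correct = FALSE))$statistic))
      expect_equal(chi_square(t, yates = TRUE)$statistic,
                   unname(suppressWarnings(
                     stats::chisq.test(m, correct = TRUE))$statistic))
      expect_lte(chi_square(t, yates = TRUE)$statistic,
                 chi_square(t, yates = FALSE)$statistic + 1e-12)
    }
  })
  expect_error(chi_square(contingency_2x2(0, 0, 5, 5)), "degenerate|expected")
})

test_that("significance flags derive exactly from the interval bounds", {
  f <- classify_significance(29.61, 31.88, 29, 32, 0.5)
  expect_true(f$significant_ror && f$significant_prr && f$significant_ic)
  f2 <- classify_significance(0.8, 1.3, 0.8, 1.3, -0.1)
  expect_false(any(unlist(f2)))
  # protective signals (interval entirely below 1) are also significant
  expect_true(classify_significance(0.2, 0.8, 1, 2, 0)$significant_ror)
  expect_true(classify_significance(1, 2, 1, 2, 0.01)$significant_ic)
})

test_that("swapping drug and comparator rows inverts the ROR exactly", {
  withr::with_seed(707, {
    for (rep in 1:10) {
      cells <- rpois(4, 20) + 1
      t <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
      s <- contingency_2x2(cells[3], cells[4], cells[1], cells[2])
      expect_equal(ror_with_ci(t)$estimate * ror_with_ci(s)$estimate, 1,
                   tolerance = 1e-12)
    }
  })
})

test_that("ROR and PRR converge in the rare-event regime", {
  withr::with_seed(808, {
    for (rep in 1:10) {
      # event rates < 1% in both arms
      a <- rpois(1, 20) + 1; b <- 20000
      c_ <- rpois(1, 50) + 1; d <- 200000
      t <- contingency_2x2(a, b, c_, d)
      ror <- ror_with_ci(t)$estimate
      prr <- prr_with_ci(t)$estimate
      expect_gte(ror + 1e-12, prr) # b/(a+b) <= d/(c+d) here
      expect_equal(ror / prr, 1, tolerance = 0.01)
    }
  })
})

test_that("signal_stats assembles coherent one-row results", {
  t <- contingency_2x2(263, 1863, 103, 17771)
  s <- signal_stats(t)
  expect_equal(nrow(s), 1)
  expect_true(s$ror_low <= s$ror & s$ror <= s$ror_high)
  expect_true(s$prr_low <= s$prr & s$prr <= s$prr_high)
  expect_true(s$ic_low <= s$ic & s$ic <= s$ic_high)
  expect_true(all(unlist(s[c("fisher_p", "chi2_p", "chi2_yates_p")]) >= 0))
  expect_true(all(unlist(s[c("fisher_p", "chi2_p", "chi2_yates_p")]) <= 1))
  expect_true(s$significant_ror && s$significant_ic)
})
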