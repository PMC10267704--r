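test_that("carrier collapsing is dominant and drops missing genotypes", {
  k <- collapse_carriers(c(het = 9, hom_ref = 372), c(het = 2, hom_ref = 379))
  expect_equal(unclass(k)[c("case_carriers", "case_noncarriers",
                            "control_carriers", "control_noncarriers")],
               list(case_carriers = 9, case_noncarriers = 372,
                    control_carriers = 2, control_noncarriers = 379))
  expect_false(k$monomorphic)
  k2 <- collapse_carriers(c(het = 1, hom_alt = 1, hom_ref = 8, missing = 5),
                          c(hom_ref = 10))
  expect_equal(k2$case_carriers, 2)
  expect_equal(k2$case_noncarriers, 8)     # missing excluded
  k3 <- collapse_carriers(c(hom_ref = 380), c(hom_ref = 380))
  expect_true(k3$monomorphic)
  expect_identical(select_test(k3), "not_available")
  expect_error(collapse_carriers(c(heterozygote = 3), c(hom_ref = 1)),
               "unknown genotype")
})

test_that("test selection follows the minimum expected cell count", {
  # min expected carrier cell 11*381/762 = 5.5 -> chi-square
  expect_identical(select_test(9, 372, 2, 379), "chi_square")
  # min expected 5*380/760 = 2.5 -> fisher
  expect_identical(select_test(4, 376, 1, 379), "fisher")
  # zero cell but min expected 23*174/406 = 9.86 -> still chi-square
  expect_identical(select_test(0, 174, 23, 209), "chi_square")
  # zero carrier margin -> not available
  expect_identical(select_test(0, 380, 0, 380), "not_available")
})

test_that("chi-square p-values match the replication rows and base R", {
  expect_equal(round(chi_square_2x2(9, 372, 2, 379), 3), 0.034)
  expect_equal(round(chi_square_2x2(1, 379, 10, 365), 3), 0.006)
  expect_equal(chi_square_2x2(0, 174, 23, 209), 1.9e-5, tolerance = 0.01)
  # identical proportions give statistic 0, p 1
  expect_equal(chi_square_2x2(5, 95, 5, 95), 1)
  # zero margin degenerates to NA
  expect_true(is.na(chi_square_2x2(0, 0, 5, 5)))
  # cross-check against the independent base-R route (no correction)
  for (tab in list(c(9, 372, 2, 379), c(1, 379, 10, 365), c(12, 80, 4, 90))) {
    expect_equal(
      chi_square_2x2(tab[1], tab[2], tab[3], tab[4]),
      suppressWarnings(stats::chisq.test(matrix(tab, 2, byrow = TRUE),
                                         correct = FALSE))$p.value)
  }
})

test_that("chi-square is invariant under transposition and row swap", {
  set.seed(71)
  for (i in 1:25) {
    t4 <- rmultinom(1, 200, runif(4, 0.05, 1))[, 1]
    a <- t4[1]; b <- t4[2]; c_ <- t4[3]; d <- t4[4]
    p <- chi_square_2x2(a, b, c_, d)
    expect_equal(chi_square_2x2(a, c_, b, d), p)   # transpose
    expect_equal(chi_square_2x2(c_, d, a, b), p)   # swap rows
  }
})

test_that("fisher p-values match the replication rows and base R", {
  expect_equal(round(fisher_exact_2x2(4, 376, 1, 379), 3), 0.373)
  expect_equal(round(fisher_exact_2x2(6, 374, 2, 368), 3), 0.287)
  expect_equal(fisher_exact_2x2(2, 372, 1, 362), 1)
  # equal group compositions give p = 1
  expect_equal(fisher_exact_2x2(7, 93, 7, 93), 1)
  # degenerate tables return 1
  expect_equal(fisher_exact_2x2(0, 0, 3, 7), 1)
  set.seed(13)
  for (i in 1:40) {
    t4 <- rmultinom(1, sample(20:300, 1), runif(4, 0.02, 1))[, 1]
    expect_equal(
      fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4]),
      stats::fisher.test(matrix(t4, 2, byrow = TRUE))$p.value,
      tolerance = 1e-12)
  }
})

test_that("swapping case and control rows inverts the OR and preserves p", {
  set.seed(5)
  for (i in 1:20) {
    t4 <- rmultinom(1, 250, runif(4, 0.05, 1))[, 1] + 1  # no zero cells
    a <- t4[1]; b <- t4[2]; c_ <- t4[3]; d <- t4[4]
    o1 <- odds_ratio_woolf(a, b, c_, d)
    o2 <- odds_ratio_woolf(c_, d, a, b)
    expect_equal(o2$odds_ratio, 1 / o1$odds_ratio)
    expect_equal(o2$ci_low, 1 / o1$ci_high)
    expect_equal(o2$ci_high, 1 / o1$ci_low)
    expect_equal(fisher_exact_2x2(c_, d, a, b), fisher_exact_2x2(a, b, c_, d))
    expect_equal(chi_square_2x2(c_, d, a, b), chi_square_2x2(a, b, c_, d))
  }
})

test_that("one-sided fisher p is monotone in the case-carrier count", {
  p_prev <- Inf
  for (a in 0:12) {
    p <- fisher_exact_2x2(a, 381 - a, 2, 379, alternative = "greater")
    expect_lte(p, p_prev + 1e-15)
    p_prev <- p
  }
})

test_that("woolf intervals reproduce the replication odds ratios", {
  o <- odds_ratio_woolf(9, 372, 2, 379)
  expect_equal(o$odds_ratio, 4.585, tolerance = 1e-3)
  expect_equal(round(o$ci_low, 2), 0.98)
  expect_equal(round(o$ci_high, 2), 21.36)
  o2 <- odds_ratio_woolf(6, 374, 2, 368)
  expect_equal(round(o2$odds_ratio, 2), 2.95)
  expect_equal(round(o2$ci_low, 2), 0.59)
  expect_equal(round(o2$ci_high, 2), 14.72)
  # unit table: OR 1, CI symmetric about 1 on the log scale
  o3 <- odds_ratio_woolf(1, 1, 1, 1)
  expect_equal(o3$odds_ratio, 1)
  expect_equal(o3$ci_low * o3$ci_high, 1)
  # zero cell: no estimate rather than a corrected one
  o4 <- odds_ratio_woolf(0, 380, 2, 379)
  expect_true(all(is.na(unlist(o4))))
})

test_that("carrier case composition matches the headline percentages", {
  f <- carrier_case_fraction(9, 372, 2, 379)
  expect_equal(round(f$carrier_case_pct, 2), 81.82)
  expect_equal(round(f$noncarrier_case_pct, 2), 49.53)
  f2 <- carrier_case_fraction(0, 10, 5, 10)
  expect_equal(f2$carrier_case_pct, 0)
  expect_equal(f2$noncarrier_case_pct, 50)
  f3 <- carrier_case_fraction(5, 0, 5, 0)
  expect_equal(f3$carrier_case_pct, 50)
  expect_true(is.na(f3$noncarrier_case_pct))
})

test_that("the fixture replication table reproduces the printed statistics", {
  tab <- read_replication_table(fixture_path("replication_genotypes.tsv"))
  res <- associate_all(tab)
  sirpb1 <- res[res$gene == "SIRPB1", ]
  expect_identical(sirpb1$test_used, "chi_square")
  expect_equal(round(sirpb1$p_value, 3), 0.034)
  expect_equal(sirpb1$odds_ratio, 4.59, tolerance = 2e-3)
  expect_equal(round(sirpb1$ci_low, 2), 0.98)
  expect_equal(round(sirpb1$ci_high, 2), 21.36)
  expect_true(sirpb1$significant)
  expect_equal(round(sirpb1$carrier_case_pct, 2), 81.82)
  expect_equal(round(sirpb1$noncarrier_case_pct, 2), 49.53)

  tyk2 <- res[res$gene == "TYK2", ]
  expect_identical(tyk2$test_used, "chi_square")
  expect_equal(round(tyk2$p_value, 3), 0.006)
  expect_equal(round(tyk2$odds_ratio, 2), 0.10)

  vrk3 <- res[res$gene == "VRK3", ]
  expect_identical(vrk3$test_used, "fisher")
  expect_equal(round(vrk3$p_value, 3), 0.373)
  expect_equal(round(vrk3$odds_ratio, 2), 4.03)
  expect_equal(round(vrk3$ci_low, 2), 0.45)
  expect_equal(round(vrk3$ci_high, 2), 36.24)

  oas3 <- res[res$gene == "OAS3", ]
  expect_identical(oas3$test_used, "fisher")
  expect_equal(round(oas3$p_value, 3), 0.287)
  expect_equal(round(oas3$odds_ratio, 2), 2.95)

  cage1 <- res[res$gene == "CAGE1", ]
  expect_identical(cage1$test_used, "chi_square")
  expect_equal(cage1$p_value, 1.9e-5, tolerance = 0.01)
  expect_true(is.na(cage1$odds_ratio))            # zero cell
  expect_identical(cage1$reason, "zero_cell_or")

  a2ml1 <- res[res$gene == "A2ML1", ]
  expect_identical(a2ml1$test_used, "fisher")
  expect_equal(round(a2ml1$p_value, 3), 1)
  expect_equal(round(a2ml1$odds_ratio, 2), 1.95)

  # monomorphic rows degrade to not_available without aborting the batch
  mono <- res[res$gene %in% c("PCNXL2", "UBE2U", "LSP1", "NOD2"), ]
  expect_true(all(mono$test_used == "not_available"))
  expect_true(all(mono$reason == "monomorphic"))
  expect_true(all(is.na(mono$p_value)))
})

test_that("an empty tally table yields an empty result", {
  tab <- read_replication_table(fixture_path("replication_genotypes.tsv"))
  expect_equal(nrow(associate_all(tab[0, ])), 0L)
})

test_that("null simulated variants are significant at about the alpha level", {
  sim <- simulate_replication(replication_sim_config(
    n_cases = 381, n_controls = 381, control_carrier_freq = 0.1,
    true_odds_ratio = 1, n_variants = 1000, seed = 99L))
  res <- associate_all(sim$tallies)
  rate <- mean(res$significant)
  # binomial 3-sigma band around 0.05 for 1000 draws
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
  expect_true(all(res$test_used == "chi_square"))
})

test_that("carrier_assoc wraps a single table into a printable fit", {
  fit <- carrier_assoc(c(het = 9, hom_ref = 372), c(het = 2, hom_ref = 379))
  expect_s3_class(fit, "carrier_assoc")
  expect_true(fit$significant)
  out <- capture.output(print(fit))
  expect_true(any(grepl("OR = 4.58", out)))
  expect_true(any(grepl("chi_square", out)))
})
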