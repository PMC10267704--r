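#' Collapse genotype tallies to dominant-model carrier counts
#'
#' Under dominant-model collapsing a subject is a carrier when it holds at
#' least one alternate allele (`het` or `hom_alt`); non-carriers are
#' `hom_ref`; subjects with `missing` genotype are excluded from both counts,
#' so per-variant denominators reflect genotyping missingness.
#'
#' @param case,control Named numeric vectors of per-genotype subject counts
#'   (names among `hom_ref`, `het`, `hom_alt`, `missing`).
#' @return Object of class `genotype_counts`: list with
#'   `case_carriers`, `case_noncarriers`, `control_carriers`,
#'   `control_noncarriers`, and `monomorphic` (TRUE when only one genotype
#'   class was detected across both groups, in which case no test applies).
#' @examples
#' collapse_carriers(c(het = 9, hom_ref = 372), c(het = 2, hom_ref = 379))
#' @export
collapse_carriers <- function(case, control) {
  get <- function(x, nm) if (nm %in% names(x)) as.numeric(x[[nm]]) else 0
  bad <- setdiff(union(names(case), names(control)), genotype_classes())
  if (length(bad)) {
    stop("unknown genotype class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(c(case, control) < 0)) stop("counts must be >= 0", call. = FALSE)
  carriers <- function(x) get(x, "het") + get(x, "hom_alt")
  present <- vapply(c("hom_ref", "het", "hom_alt"), function(g) {
    get(case, g) + get(control, g) > 0
  }, logical(1L))
  structure(list(
    case_carriers = carriers(case),
    case_noncarriers = get(case, "hom_ref"),
    control_carriers = carriers(control),
    control_noncarriers = get(control, "hom_ref"),
    monomorphic = sum(present) <= 1L
  ), class = "genotype_counts")
}

unpack_counts <- function(a, b, c, d) {
  if (inherits(a, "genotype_counts")) {
    list(a = a$case_carriers, b = a$case_noncarriers,
         c = a$control_carriers, d = a$control_noncarriers,
         monomorphic = a$monomorphic)
  } else {
    stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
    list(a = a, b = b, c = c, d = d, monomorphic = NULL)
  }
}

#' Choose the 2x2 test from expected cell counts
#'
#' Selects Fisher's exact test when any expected cell count under
#' independence is below `min_expected` (default 5), and the Pearson
#' chi-square test otherwise. Returns `"not_available"` when a table margin
#' is zero (the variant is monomorphic in the collapsed data, or one group
#' is empty).
#'
#' @param a,b,c,d Case carriers, case non-carriers, control carriers,
#'   control non-carriers (vectorized), or a single `genotype_counts` object
#'   as `a`.
#' @param min_expected Expected-count threshold for the exact test.
#' @return Character vector in `c("chi_square", "fisher", "not_available")`.
#' @export
select_test <- function(a, b = NULL, c = NULL, d = NULL, min_expected = 5) {
  x <- unpack_counts(a, b, c, d)
  mono <- if (is.null(x$monomorphic)) FALSE else x$monomorphic
  with(x, {
    N <- a + b + c + d
    min_margin <- pmin(a + b, c + d, a + c, b + d)
    min_exp <- pmin(a + b, c + d) * pmin(a + c, b + d) / N
    out <- ifelse(min_exp < min_expected, "fisher", "chi_square")
    out[N == 0 | min_margin == 0 | mono] <- "not_available"
    out
  })
}

#' Pearson chi-square test for a 2x2 table
#'
#' Computes the Pearson statistic `N (ad - bc)^2 / (r1 r2 c1 c2)` without
#' continuity correction and refers it to the chi-square distribution with
#' one degree of freedom (upper tail). The statistic is invariant under
#' transposition of the table and under swapping the two rows.
#'
#' @inheritParams select_test
#' @return Numeric vector of p-values; `NA` where a margin is zero.
#' @examples
#' chi_square_2x2(9, 372, 2, 379) # ~0.034
#' @export
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- unpack_counts(a, b, c, d)
  with(x, {
    N <- a + b + c + d
    denom <- (a + b) * (c + d) * (a + c) * (b + d)
    stat <- ifelse(denom > 0, N * (a * d - b * c)^2 / denom, NA_real_)
    stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  })
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summation of the hypergeometric probabilities (at
#' fixed margins) of all tables no more probable than the observed one; the
#' conventional relative tolerance of 1e-7 guards the comparison against
#' floating-point ties. The one-sided alternative `"greater"` sums the upper
#' tail of carrier excess in cases. Degenerate tables (a zero margin) give
#' p = 1.
#'
#' @inheritParams select_test
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return Numeric vector of p-values.
#' @examples
#' fisher_exact_2x2(4, 376, 1, 379) # ~0.373
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  x <- unpack_counts(a, b, c, d)
  n <- length(x$a)
  vapply(seq_len(n), function(i) {
    a_ <- x$a[i]; b_ <- x$b[i]; c_ <- x$c[i]; d_ <- x$d[i]
    r1 <- a_ + b_; c1 <- a_ + c_; c2 <- b_ + d_
    if (r1 == 0 || c_ + d_ == 0 || c1 == 0 || c2 == 0) return(1)
    support <- max(0, r1 - c2):min(r1, c1)
    probs <- stats::dhyper(support, c1, c2, r1)
    if (alternative == "greater") {
      sum(probs[support >= a_])
    } else {
      p_obs <- stats::dhyper(a_, c1, c2, r1)
      min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
    }
  }, numeric(1L))
}

#' Odds ratio with Woolf confidence interval
#'
#' The odds ratio is `ad / bc`; the Woolf interval exponentiates
#' `log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d)` with `z` the standard
#' normal quantile for `conf_level`. Any zero cell yields `NA` for all three
#' values (no haldane-style continuity correction is applied).
#'
#' @inheritParams select_test
#' @param conf_level Confidence level (default 0.95, z = 1.96).
#' @return Data frame with columns `odds_ratio`, `ci_low`, `ci_high`.
#' @examples
#' odds_ratio_woolf(9, 372, 2, 379) # OR 4.59, CI 0.98-21.36
#' @export
odds_ratio_woolf <- function(a, b = NULL, c = NULL, d = NULL,
                             conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1)
  x <- unpack_counts(a, b, c, d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  with(x, {
    ok <- a > 0 & b > 0 & c > 0 & d > 0
    or <- ifelse(ok, (a * d) / (b * c), NA_real_)
    se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
    data.frame(odds_ratio = or,
               ci_low = exp(log(or) - z * se),
               ci_high = exp(log(or) + z * se))
  })
}

#' Case composition of carriers and non-carriers
#'
#' Among carriers, the percentage who are cases (`100 a / (a + c)`), and
#' among non-carriers, the percentage who are cases (`100 b / (b + d)`).
#' For an enriched risk allele the first exceeds the second.
#'
#' @inheritParams select_test
#' @return Data frame with columns `carrier_case_pct`,
#'   `noncarrier_case_pct`; `NA` where the stratum is empty.
#' @examples
#' carrier_case_fraction(9, 372, 2, 379) # 81.82 vs 49.53
#' @export
carrier_case_fraction <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- unpack_counts(a, b, c, d)
  with(x, data.frame(
    carrier_case_pct = ifelse(a + c > 0, 100 * a / (a + c), NA_real_),
    noncarrier_case_pct = ifelse(b + d > 0, 100 * b / (b + d), NA_real_)
  ))
}

#' Carrier-collapsed association for one variant
#'
#' Fits the dominant-model 2x2 association for a single variant: collapses
#' genotype tallies to carrier counts, selects the test by expected cell
#' counts, and computes p-value, odds ratio with Woolf confidence interval,
#' and carrier case composition.
#'
#' @param case,control Named per-genotype subject counts, as for
#'   [collapse_carriers()], or a `genotype_counts` object as `case`.
#' @param alpha Significance level for the `significant` flag (default 0.05;
#'   no multiple-testing correction is applied here).
#' @param conf_level Confidence level for the Woolf interval.
#' @param min_expected Expected-count threshold of [select_test()].
#' @return Object of class `carrier_assoc`.
#' @examples
#' carrier_assoc(c(het = 9, hom_ref = 372), c(het = 2, hom_ref = 379))
#' @export
carrier_assoc <- function(case, control = NULL, alpha = 0.05,
                          conf_level = 0.95, min_expected = 5) {
  counts <- if (inherits(case, "genotype_counts")) case
            else collapse_carriers(case, control)
  test <- select_test(counts, min_expected = min_expected)
  p <- switch(test,
    chi_square = chi_square_2x2(counts),
    fisher = fisher_exact_2x2(counts),
    not_available = NA_real_)
  or <- odds_ratio_woolf(counts, conf_level = conf_level)
  frac <- carrier_case_fraction(counts)
  structure(list(
    counts = counts, test_used = test, p_value = p,
    odds_ratio = or$odds_ratio, ci_low = or$ci_low, ci_high = or$ci_high,
    carrier_case_pct = frac$carrier_case_pct,
    noncarrier_case_pct = frac$noncarrier_case_pct,
    significant = !is.na(p) && p < alpha,
    alpha = alpha, conf_level = conf_level
  ), class = "carrier_assoc")
}

#' @export
print.carrier_assoc <- function(x, ...) {
  k <- x$counts
  cat("Dominant-model carrier association (carrier vs. wild type)\n")
  cat(sprintf("  cases:    %d/%d carriers (%.2f%%)\n", k$case_carriers,
              k$case_carriers + k$case_noncarriers,
              100 * k$case_carriers / max(1, k$case_carriers + k$case_noncarriers)))
  cat(sprintf("  controls: %d/%d carriers (%.2f%%)\n", k$control_carriers,
              k$control_carriers + k$control_noncarriers,
              100 * k$control_carriers /
                max(1, k$control_carriers + k$control_noncarriers)))
  if (x$test_used == "not_available") {
    cat("  test: not available (monomorphic or empty margin)\n")
  } else {
    cat(sprintf("  test: %s, p = %.4g%s\n", x$test_used, x$p_value,
                if (x$significant) sprintf(" (< %g)", x$alpha) else ""))
    if (!is.na(x$odds_ratio)) {
      cat(sprintf("  OR = %.2f, %d%% CI %.2f-%.2f\n", x$odds_ratio,
                  round(100 * x$conf_level), x$ci_low, x$ci_high))
    } else {
      cat("  OR not estimable (zero cell)\n")
    }
  }
  invisible(x)
}

#' Association analysis of a replication genotype table
#'
#' Runs [carrier_assoc()] for every variant of a replication tally table
#' (long format, see [read_replication_table()]). Row-level failures degrade
#' to `test_used = "not_available"` with a reason code; the batch never
#' aborts. The significance flag uses the raw p-value at `alpha` (the
#' replication design tests a fixed candidate list without multiple-testing
#' correction); Bonferroni- and BH-adjusted p-values are emitted alongside
#' for reference.
#'
#' @param tallies Long data frame with columns `variant_id`, `group`,
#'   `genotype`, `count` and optionally `gene`, `rsid`.
#' @param alpha Significance level for the raw-p flag (default 0.05).
#' @param conf_level Woolf interval confidence level (default 0.95).
#' @param min_expected Expected-count threshold of [select_test()].
#' @return Data frame of class `assoc_table`, one row per variant: counts,
#'   `test_used`, `p_value`, `odds_ratio`, `ci_low`, `ci_high`, carrier case
#'   composition, `significant`, `p_bonferroni`, `p_bh`, `reason`.
#' @export
associate_all <- function(tallies, alpha = 0.05, conf_level = 0.95,
                          min_expected = 5) {
  need <- c("variant_id", "group", "genotype", "count")
  stopifnot(all(need %in% names(tallies)))
  vids <- unique(tallies$variant_id)
  if (length(vids) == 0L) {
    out <- data.frame(variant_id = character(), gene = character(),
                      rsid = character(), case_carriers = numeric(),
                      case_total = numeric(), control_carriers = numeric(),
                      control_total = numeric(), genotype_label = character(),
                      carrier_case_pct = numeric(),
                      noncarrier_case_pct = numeric(), test_used = character(),
                      p_value = numeric(), odds_ratio = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      significant = logical(), p_bonferroni = numeric(),
                      p_bh = numeric(), reason = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("assoc_table", "data.frame")
    return(out)
  }
  fv <- factor(tallies$variant_id, levels = vids)
  cell <- function(grp, gts) {
    keep <- tallies$group == grp & tallies$genotype %in% gts
    as.numeric(tapply(tallies$count[keep], fv[keep], sum, default = 0))
  }
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  a <- zero_na(cell("case", c("het", "hom_alt")))
  b <- zero_na(cell("case", "hom_ref"))
  c_ <- zero_na(cell("control", c("het", "hom_alt")))
  d <- zero_na(cell("control", "hom_ref"))

  # monomorphic: only one genotype class detected across both groups
  n_classes <- Reduce(`+`, lapply(c("hom_ref", "het", "hom_alt"), function(g) {
    (zero_na(cell("case", g)) + zero_na(cell("control", g))) > 0
  }))
  mono <- n_classes <= 1L

  test <- select_test(a, b, c_, d, min_expected = min_expected)
  test[mono] <- "not_available"
  p <- rep(NA_real_, length(vids))
  chi <- test == "chi_square"
  p[chi] <- chi_square_2x2(a[chi], b[chi], c_[chi], d[chi])
  fis <- test == "fisher"
  p[fis] <- fisher_exact_2x2(a[fis], b[fis], c_[fis], d[fis])
  or <- odds_ratio_woolf(a, b, c_, d, conf_level = conf_level)
  or[test == "not_available", ] <- NA_real_
  frac <- carrier_case_fraction(a, b, c_, d)

  reason <- rep(NA_character_, length(vids))
  reason[mono] <- "monomorphic"
  reason[!mono & test == "not_available"] <- "zero_margin"
  reason[test != "not_available" & is.na(or$odds_ratio)] <- "zero_cell_or"

  first_of <- function(col) {
    if (!col %in% names(tallies)) return(rep(NA_character_, length(vids)))
    as.character(tapply(as.character(tallies[[col]]), fv, function(x) x[1L]))
  }
  out <- data.frame(
    variant_id = vids, gene = first_of("gene"), rsid = first_of("rsid"),
    case_carriers = a, case_total = a + b,
    control_carriers = c_, control_total = c_ + d,
    genotype_label = "carrier vs. wild type",
    carrier_case_pct = frac$carrier_case_pct,
    noncarrier_case_pct = frac$noncarrier_case_pct,
    test_used = test, p_value = p,
    odds_ratio = or$odds_ratio, ci_low = or$ci_low, ci_high = or$ci_high,
    significant = !is.na(p) & p < alpha,
    p_bonferroni = stats::p.adjust(p, method = "bonferroni"),
    p_bh = stats::p.adjust(p, method = "BH"),
    reason = reason,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' @export
print.assoc_table <- function(x, digits = 3, max_rows = 20L, ...) {
  cat("Carrier-collapsed replication association: ", nrow(x), " variant(s), ",
      sum(x$significant), " significant at raw p\n", sep = "")
  show <- utils::head(as.data.frame(x)[, c("variant_id", "gene",
                                           "case_carriers", "case_total",
                                           "control_carriers", "control_total",
                                           "test_used", "p_value",
                                           "odds_ratio", "ci_low", "ci_high")],
                      max_rows)
  print(show, digits = digits, row.names = FALSE)
  if (nrow(x) > max_rows) cat("... ", nrow(x) - max_rows, " more row(s)\n")
  invisible(x)
}

#' Write an association table to TSV
#' @param x An `assoc_table` from [associate_all()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_assoc_table <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}
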