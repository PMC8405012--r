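test_that("KS normality gate behaves under null and alternative", {
  normal_p <- sapply(1:50, function(s) {
    set.seed(s); ks_normality(rnorm(1000), n_sim = 400)$p_value
  })
  expect_gte(mean(normal_p > 0.05), 0.90)

  expo_p <- sapply(1:50, function(s) {
    set.seed(s); ks_normality(rexp(1000), n_sim = 400)$p_value
  })
  expect_gte(mean(expo_p < 0.05), 0.95)

  cst <- ks_normality(rep(5, 100))
  expect_false(cst$normal)
  expect_equal(cst$flag, "inconclusive")
  expect_false(ks_normality(c(1, 2, 3))$normal)
})

test_that("compare_continuous gates on normality and handles edge cases", {
  set.seed(1)
  a <- rnorm(100)
  cc <- compare_continuous(a, a)
  expect_equal(cc$p_value, 1, tolerance = 1e-8)

  # 1-sd separation at n = 100: decisive
  set.seed(2)
  cc2 <- compare_continuous(rnorm(100, 0), rnorm(100, 1), "sep")
  expect_lt(cc2$p_value, 0.001)
  expect_true(cc2$test_used %in% c("t", "mann_whitney"))

  # skewed data routes to Mann-Whitney with median (IQR) summaries
  set.seed(3)
  cc3 <- compare_continuous(rexp(200), rexp(200))
  expect_equal(cc3$test_used, "mann_whitney")
  expect_gt(cc3$p_value, 0.05)

  # ties only
  cc4 <- compare_continuous(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_gt(cc4$p_value, 0.9)

  # degenerate equal constants
  cc5 <- compare_continuous(rep(3, 5), rep(3, 5))
  expect_equal(cc5$p_value, 1)
  expect_equal(cc5$flag, "degenerate")

  # two-sided p unchanged under group swap
  set.seed(4)
  x <- rnorm(60); y <- rnorm(60, 0.4)
  expect_equal(compare_continuous(x, y)$p_value,
               compare_continuous(y, x)$p_value)
})

test_that("summary t-test reproduces printed group comparisons", {
  # age row of the two-group baseline table: prints 0.001
  res <- t_test_from_summary(65.8, 16.1, 276, 73.2, 14.8, 66)
  expect_equal(round(res$p_value, 3), 0.001)

  expect_equal(t_test_from_summary(5, 1, 10, 5, 1, 10)$p_value, 1)
  expect_equal(t_test_from_summary(5, 0, 10, 5, 0, 10)$statistic, 0)

  # doubling both n at fixed summaries strictly decreases p
  p1 <- t_test_from_summary(10, 4, 30, 11, 4, 30)$p_value
  p2 <- t_test_from_summary(10, 4, 60, 11, 4, 60)$p_value
  expect_lt(p2, p1)

  # Welch differs when variances are unequal
  expect_false(isTRUE(all.equal(
    t_test_from_summary(10, 2, 30, 11, 8, 20)$p_value,
    t_test_from_summary(10, 2, 30, 11, 8, 20, pooled = FALSE)$p_value)))
})

test_that("Yates chi-square matches the textbook formula", {
  set.seed(8)
  for (i in 1:500) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    res <- chi2_yates(tab)
    expect_equal(res$statistic, oracle_yates_stat(tab), tolerance = 1e-12)
    expect_equal(res$p_value, pchisq(oracle_yates_stat(tab), 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # perfectly proportional table: corrected statistic 0, p = 1
  prop <- chi2_yates(matrix(c(10, 20, 30, 60), 2, 2, byrow = TRUE))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  expect_error(chi2_yates(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)), "margins")
})

test_that("Fisher's exact test by enumeration", {
  expect_equal(fisher_exact(matrix(c(1, 9, 9, 1), 2, 2, byrow = TRUE))$p_value,
               0.001093334, tolerance = 1e-6)
  # identical row proportions
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2, 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(4, 8, 2, 4), 2, 2, byrow = TRUE))$p_value, 1)
  # zero cells allowed
  expect_lt(fisher_exact(matrix(c(0, 10, 10, 0), 2, 2, byrow = TRUE))$p_value, 1e-4)

  # increasing off-diagonal imbalance never increases p
  ps <- sapply(0:5, function(k) {
    fisher_exact(matrix(c(5 - k, 5 + k, 5 + k, 5 - k), 2, 2, byrow = TRUE))$p_value
  })
  expect_true(all(diff(ps) <= 1e-12))

  # agreement with stats::fisher.test across random tables
  set.seed(5)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 8), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Fisher and Yates chi-square track each other on large balanced tables", {
  # the continuity-corrected chi-square approximates the exact test; at
  # expected counts >= 20 the two can still differ by several hundredths in
  # the mid-p region (the correction is conservative there), so the
  # agreement is asserted as a max band plus a tight typical-case band
  set.seed(6)
  diffs <- c()
  while (length(diffs) < 200) {
    tab <- matrix(rpois(4, 60) + 30, 2, 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 20)) next
    diffs <- c(diffs, abs(fisher_exact(tab)$p_value - chi2_yates(tab)$p_value))
  }
  expect_lt(max(diffs), 0.1)
  expect_lt(median(diffs), 0.03)
  # and they never disagree about clear significance calls
  set.seed(66)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 60) + 30, 2, 2)
    f <- fisher_exact(tab)$p_value
    y <- chi2_yates(tab)$p_value
    if (f < 0.01) expect_lt(y, 0.05)
    if (f > 0.2) expect_gt(y, 0.05)
  }
})

test_that("median imputation fills and logs", {
  d <- data.frame(id = 1:4, outcome = c(0, 1, 0, 1),
                  x = c(1, 2, NA, 4), g = c("a", "a", NA, "b"))
  out <- median_impute(d, max_missing_frac = 0.5)
  expect_equal(out$x[3], 2)       # median of 1, 2, 4
  expect_equal(out$g[3], "a")     # mode
  log <- attr(out, "imputation_log")
  expect_equal(sum(log$n_imputed), 2)

  # identity on complete data
  d2 <- data.frame(id = 1:3, outcome = c(0, 1, 0), x = 1:3)
  expect_equal(median_impute(d2)$x, 1:3)
  expect_equal(nrow(attr(median_impute(d2), "imputation_log")), 0)

  # three planted missing cells in a cohort-sized table -> exactly 3 logged
  set.seed(10)
  big <- data.frame(id = 1:342, outcome = rbinom(342, 1, 0.2),
                    a = rnorm(342), b = rnorm(342), c = rnorm(342))
  big$a[5] <- NA; big$b[100] <- NA; big$c[342] <- NA
  out3 <- median_impute(big)
  expect_equal(sum(attr(out3, "imputation_log")$n_imputed), 3)
  expect_false(anyNA(out3[, c("a", "b", "c")]))

  expect_error(median_impute(data.frame(id = 1, outcome = 0, x = NA_real_)),
               "entirely missing")
  d$x[1:3] <- NA
  expect_error(median_impute(d, max_missing_frac = 0.003), "cap")
})

test_that("baseline_table picks tests by type and detects planted contrast", {
  set.seed(11)
  n <- 300
  y <- rbinom(n, 1, 0.3)
  d <- data.frame(id = seq_len(n), outcome = y,
                  signal = rnorm(n, mean = y),          # planted difference
                  null1 = rnorm(n), null2 = rnorm(n),
                  flag = rbinom(n, 1, 0.4),
                  rare = rbinom(n, 1, 0.02))
  tab <- baseline_table(d)
  expect_lt(tab$p_value[tab$variable == "signal"], 0.05)
  expect_gt(min(tab$p_value[tab$variable %in% c("null1", "null2")]), 0.001)
  expect_equal(tab$test_used[tab$variable == "flag"], "chi2_yates")
  expect_equal(tab$test_used[tab$variable == "rare"], "fisher")
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))

  # empty variable list -> empty table
  expect_equal(nrow(baseline_table(d, vars = character(0))), 0)
  expect_error(baseline_table(data.frame(outcome = rep(1, 10), x = rnorm(10))),
               "both classes")
})

test_that("p-value formatting follows the 3-decimal convention", {
  expect_equal(hrnv:::fmt_p(0.0004), "<0.001")
  expect_equal(hrnv:::fmt_p(0.0006), "0.001")
  expect_equal(hrnv:::fmt_p(0.399), "0.399")
})
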