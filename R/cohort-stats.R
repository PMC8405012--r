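# Baseline two-group comparison machinery: normality-gated continuous tests,
# categorical tests with the expected-count rule, and median imputation.

#' Kolmogorov-Smirnov normality check with estimated parameters
#'
#' Lilliefors-style test: the KS statistic is computed against a normal with
#' the sample mean and SD, and its p-value is obtained by parametric Monte
#' Carlo (re-estimating the parameters in each simulated sample), since the
#' textbook KS null distribution is wrong when parameters are estimated.
#'
#' @param values Numeric vector (>= 5 non-missing values required for a
#'   conclusive result).
#' @param n_sim Monte Carlo replicates (default 2000).
#' @param seed Seed for the Monte Carlo draw (fixed default keeps the check
#'   deterministic).
#' @return List `statistic`, `p_value`, `normal` (p >= 0.05), `flag`
#'   (`"inconclusive"` => treated non-normal for too-few or constant values).
#' @export
ks_normality <- function(values, n_sim = 2000L, seed = 17L) {
  x <- values[!is.na(values)]
  if (length(x) < 5 || stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, normal = FALSE,
                flag = "inconclusive"))
  }
  n <- length(x)
  ks_stat <- function(z) {
    z <- sort((z - mean(z)) / stats::sd(z))
    cdf <- stats::pnorm(z)
    max(pmax(abs(cdf - (seq_len(n) - 1) / n), abs(cdf - seq_len(n) / n)))
  }
  D <- ks_stat(x)
  null_D <- local_seed(seed, {
    vapply(seq_len(n_sim), function(i) ks_stat(stats::rnorm(n)), numeric(1))
  })
  p <- (1 + sum(null_D >= D)) / (n_sim + 1)
  list(statistic = D, p_value = p, normal = p >= 0.05, flag = NA_character_)
}

#' Compare a continuous variable between two groups
#'
#' Gate on normality of both groups ([ks_normality()]): a pooled two-tailed
#' Student t-test when both pass, otherwise a Mann-Whitney U test with normal
#' approximation (midranks for ties). Summaries follow the gate: mean (SD)
#' when normal, median (IQR) otherwise.
#'
#' @param a_values,b_values Numeric vectors (>= 2 non-missing each).
#' @param variable Label carried into the result.
#' @return A `"group_comparison"` list: `variable`, `test_used` (`"t"` or
#'   `"mann_whitney"`), `statistic`, `p_value`, `summary_a`, `summary_b`,
#'   `flag`.
#' @export
compare_continuous <- function(a_values, b_values, variable = "x") {
  a <- a_values[!is.na(a_values)]
  b <- b_values[!is.na(b_values)]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 non-missing values", call. = FALSE)
  }
  flag <- NA_character_
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    return(structure(list(variable = variable, test_used = "t",
                          statistic = 0, p_value = 1,
                          summary_a = sprintf("%.1f (0.0)", mean(a)),
                          summary_b = sprintf("%.1f (0.0)", mean(b)),
                          flag = "degenerate"),
                     class = "group_comparison"))
  }
  normal <- ks_normality(a)$normal && ks_normality(b)$normal
  if (normal) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    test_used <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
    fmt <- function(v) sprintf("%.1f (%.1f)", mean(v), stats::sd(v))
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    test_used <- "mann_whitney"; statistic <- unname(wt$statistic); p <- wt$p.value
    fmt <- function(v) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
    }
  }
  structure(list(variable = variable, test_used = test_used,
                 statistic = statistic, p_value = p,
                 summary_a = fmt(a), summary_b = fmt(b), flag = flag),
            class = "group_comparison")
}

#' Two-sample t-test from printed summaries
#'
#' Reconstructs the test from group means, SDs and sizes, as needed to check
#' a published baseline table. Pooled-variance Student t by default; Welch
#' optional.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @param pooled Use the pooled-variance Student t (default) or Welch.
#' @return List `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' # age row of a two-group baseline table
#' t_test_from_summary(65.8, 16.1, 276, 73.2, 14.8, 66)$p_value
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                pooled = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2) {
    return(list(statistic = 0, df = n1 + n2 - 2, p_value = 1))
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- se^4 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

check_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  tab
}

#' Yates continuity-corrected chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of counts; both margins must be positive.
#' @return List `statistic`, `df` (= 1), `p_value`.
#' @export
chi2_yates <- function(table) {
  tab <- check_2x2(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins must be positive", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(res$statistic), df = 1,
       p_value = unname(res$p.value))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by full hypergeometric enumeration: the probabilities of
#' all tables with the observed margins that are no more probable than the
#' observed one are summed. Implemented directly from `dhyper` (zero cells
#' allowed).
#'
#' @param table 2x2 matrix of counts.
#' @return List `p_value`.
#' @export
fisher_exact <- function(table) {
  tab <- check_2x2(table)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  # relative tolerance guards against floating-point ties
  list(p_value = min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])))
}

#' Median / mode imputation of a cohort table
#'
#' Continuous missing values become the column median of the observed values;
#' categorical missing values become the mode (ties broken lexicographically).
#' Imputation is computed on the full table, mirroring a pre-split global
#' imputation; an imputation log is attached.
#'
#' @param cohort Data frame.
#' @param vars Columns to impute (default: all except `id`/`outcome`).
#' @param max_missing_frac Per-variable missingness cap (default 0.003, the
#'   "< 0.3%" regime the procedure is intended for); exceeding it errors.
#' @return The imputed data frame with attribute `"imputation_log"` (a
#'   data.frame: `variable`, `n_imputed`, `value`).
#' @export
median_impute <- function(cohort, vars = NULL, max_missing_frac = 0.003) {
  if (is.null(vars)) vars <- setdiff(names(cohort), c("id", "outcome"))
  log <- list()
  for (v in vars) {
    x <- cohort[[v]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (all(miss)) stop(sprintf("variable '%s' is entirely missing", v),
                        call. = FALSE)
    if (mean(miss) > max_missing_frac) {
      stop(sprintf("variable '%s' has %.1f%% missing, above the %.1f%% cap",
                   v, 100 * mean(miss), 100 * max_missing_frac), call. = FALSE)
    }
    if (is.numeric(x)) {
      val <- stats::median(x[!miss])
    } else {
      tab <- sort(table(x[!miss]), decreasing = TRUE)
      val <- names(tab)[tab == max(tab)][1]
    }
    cohort[[v]][miss] <- val
    log[[length(log) + 1L]] <- data.frame(variable = v,
                                          n_imputed = sum(miss),
                                          value = as.character(val))
  }
  attr(cohort, "imputation_log") <-
    if (length(log)) do.call(rbind, log)
    else data.frame(variable = character(0), n_imputed = integer(0),
                    value = character(0))
  cohort
}

#' Baseline comparison table
#'
#' One row per variable comparing the two outcome groups: continuous
#' variables through [compare_continuous()]; binary/categorical variables as
#' 2x2 tables using the expected-count rule (Fisher's exact test when any
#' expected count is below 5, Yates-corrected chi-square otherwise).
#'
#' @param cohort Data frame with a binary `outcome` column (both classes
#'   present) and the variables to compare.
#' @param vars Variables to tabulate (default: all except `id`/`outcome`).
#' @param outcome Name of the outcome column.
#' @return Data frame: `variable`, `test_used`, `statistic`, `p_value`,
#'   `p_formatted` (3 decimals, `"<0.001"` below 0.0005), `summary_a`
#'   (outcome-negative), `summary_b` (outcome-positive).
#' @export
baseline_table <- function(cohort, vars = NULL, outcome = "outcome") {
  y <- cohort[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("outcome must have both classes", call. = FALSE)
  }
  if (is.null(vars)) vars <- setdiff(names(cohort), c("id", outcome))
  empty <- data.frame(variable = character(0), test_used = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      p_formatted = character(0), summary_a = character(0),
                      summary_b = character(0))
  if (!length(vars)) return(empty)
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2) {
      gc <- compare_continuous(x[y == 0], x[y == 1], variable = v)
      data.frame(variable = v, test_used = gc$test_used,
                 statistic = gc$statistic, p_value = gc$p_value,
                 p_formatted = fmt_p(gc$p_value),
                 summary_a = gc$summary_a, summary_b = gc$summary_b)
    } else {
      tab <- table(factor(x), factor(y, levels = c(0, 1)))
      if (nrow(tab) < 2) {
        return(data.frame(variable = v, test_used = "none",
                          statistic = NA_real_, p_value = NA_real_,
                          p_formatted = NA_character_,
                          summary_a = NA_character_, summary_b = NA_character_))
      }
      # collapse to 2 x 2 on the highest level for multi-level factors
      if (nrow(tab) > 2) {
        top <- rownames(tab)[which.max(rowSums(tab))]
        tab <- rbind(tab[top, ], colSums(tab[rownames(tab) != top, , drop = FALSE]))
      }
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        res <- fisher_exact(tab)
        test_used <- "fisher"; statistic <- NA_real_
      } else {
        res <- chi2_yates(tab)
        test_used <- "chi2_yates"; statistic <- res$statistic
      }
      npos <- tab[nrow(tab), ]  # count of the non-reference level per group
      tot <- colSums(tab)
      data.frame(variable = v, test_used = test_used, statistic = statistic,
                 p_value = res$p_value, p_formatted = fmt_p(res$p_value),
                 summary_a = sprintf("%d (%.1f%%)", npos[1], 100 * npos[1] / tot[1]),
                 summary_b = sprintf("%d (%.1f%%)", npos[2], 100 * npos[2] / tot[2]))
    }
  })
  do.call(rbind, rows)
}
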