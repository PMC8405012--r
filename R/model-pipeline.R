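# Variable-selection and modelling procedure: univariable logistic screen,
# Pearson-correlation collinearity pruning, and backward stepwise
# multivariable logistic regression with Wald-p elimination.

#' Fit a binary logistic regression and report odds ratios
#'
#' Maximum-likelihood fit (IRLS via `stats::glm`), reporting per-term
#' coefficients, standard errors, OR = exp(coef), Wald 95% CI and two-sided
#' Wald p-values. Separation and non-identifiable terms are flagged
#' unestimable rather than silently reported.
#'
#' @param design Data frame or matrix of predictors (no intercept column).
#' @param outcome Binary 0/1 vector with both classes present.
#' @return List: `coefficients` data.frame (`term`, `estimate`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p_value`, `estimable`), the fitted `model`, and
#'   `converged`.
#' @export
fit_logistic <- function(design, outcome) {
  X <- as.data.frame(design)
  y <- as.numeric(outcome)
  if (length(y) < 10) stop("need at least 10 observations", call. = FALSE)
  if (length(unique(y)) < 2) stop("outcome must have both classes", call. = FALSE)
  dat <- cbind(data.frame(.y = y), X)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial())
  )
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  all_terms <- c("(Intercept)", names(X))
  # map model terms back to predictor names (glm mangles nothing for plain
  # numeric columns, but aliased columns are dropped from the summary)
  est <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    p_value = co[, 4], row.names = NULL)
  est$estimable <- is.finite(est$estimate) & is.finite(est$se) &
    abs(est$estimate) < 15 & est$se < 1e3
  missing_terms <- setdiff(all_terms, est$term)
  if (length(missing_terms)) {
    est <- rbind(est, data.frame(term = missing_terms, estimate = NA_real_,
                                 se = NA_real_, p_value = NA_real_,
                                 estimable = FALSE))
  }
  est <- est[match(all_terms, est$term), ]
  est$or <- exp(est$estimate)
  est$ci_low <- exp(est$estimate - 1.96 * est$se)
  est$ci_high <- exp(est$estimate + 1.96 * est$se)
  est <- est[, c("term", "estimate", "se", "or", "ci_low", "ci_high",
                 "p_value", "estimable")]
  list(coefficients = est, model = fit, converged = fit$converged)
}

#' Univariable logistic screen
#'
#' Fits one single-predictor logistic regression per feature and flags which
#' pass the inclusion threshold (p < 0.2, the rule applied to HRV/HRnV
#' candidates). Per-variable failures are flagged and the screen continues.
#'
#' @param features Data frame of candidate predictors.
#' @param outcome Binary 0/1 vector.
#' @param threshold Screen p-value threshold (default 0.2).
#' @return Data frame of screen results: `variable`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `passes_screen`, `estimable`.
#' @export
univariable_screen <- function(features, outcome, threshold = 0.2) {
  features <- as.data.frame(features)
  rows <- lapply(names(features), function(v) {
    res <- tryCatch({
      f <- fit_logistic(features[, v, drop = FALSE], outcome)
      r <- f$coefficients[f$coefficients$term == v, ]
      data.frame(variable = v, odds_ratio = r$or, ci_low = r$ci_low,
                 ci_high = r$ci_high, p_value = r$p_value,
                 passes_screen = isTRUE(r$estimable & r$p_value < threshold),
                 estimable = r$estimable)
    }, error = function(e) {
      data.frame(variable = v, odds_ratio = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_,
                 passes_screen = FALSE, estimable = FALSE)
    })
    res
  })
  if (!length(rows)) {
    return(data.frame(variable = character(0), odds_ratio = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p_value = numeric(0), passes_screen = logical(0),
                      estimable = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collinearity pruning by pairwise Pearson correlation
#'
#' Repeatedly finds the most correlated remaining pair with `|r| >=
#' r_threshold` and drops the member with the larger univariable p-value
#' (ties: larger p first, then lexicographically later name) until no
#' collinear pair remains. Deterministic and order-invariant up to the
#' documented tie-break.
#'
#' @param features Data frame of candidate predictors.
#' @param screen Result of [univariable_screen()] covering all columns.
#' @param r_threshold Absolute-correlation threshold (default 0.8; the
#'   original analysis does not state one).
#' @return List `retained` (character), `eliminated` (data.frame `variable`,
#'   `partner`, `r`, `p_dropped`).
#' @export
collinearity_prune <- function(features, screen, r_threshold = 0.8) {
  features <- as.data.frame(features)
  pvals <- stats::setNames(screen$p_value, screen$variable)
  if (!all(names(features) %in% names(pvals))) {
    stop("screen results missing for some features", call. = FALSE)
  }
  keep <- names(features)
  log <- list()
  repeat {
    if (length(keep) < 2) break
    C <- suppressWarnings(stats::cor(features[, keep, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    diag(C) <- 0
    C[is.na(C)] <- 0
    if (max(abs(C)) < r_threshold) break
    idx <- which(abs(C) == max(abs(C)), arr.ind = TRUE)[1, ]
    pair <- sort(keep[idx])
    pp <- pvals[pair]
    # NA p (unestimable) is treated as the worst
    pp[is.na(pp)] <- Inf
    drop_var <- if (pp[1] > pp[2]) pair[1]
                else if (pp[2] > pp[1]) pair[2]
                else max(pair)  # tie: lexicographically later name goes
    log[[length(log) + 1L]] <- data.frame(
      variable = drop_var, partner = setdiff(pair, drop_var),
      r = C[idx[1], idx[2]], p_dropped = pvals[[drop_var]])
    keep <- setdiff(keep, drop_var)
  }
  list(retained = keep,
       eliminated = if (length(log)) do.call(rbind, log)
                    else data.frame(variable = character(0),
                                    partner = character(0),
                                    r = numeric(0), p_dropped = numeric(0)))
}

#' Backward stepwise logistic regression
#'
#' Fits the full model on all candidates, then repeatedly removes the single
#' variable with the largest Wald p-value at or above `p_remove` and refits;
#' eliminated variables never re-enter. Unestimable terms in the full model
#' are dropped first and logged. The ledger plus the retained set always
#' partitions the candidate set.
#'
#' @param candidates Data frame of candidate predictors.
#' @param outcome Binary 0/1 vector.
#' @param p_remove Removal endpoint (default 0.1).
#' @return A `"stepwise_trace"` list: `removed` (data.frame `variable`,
#'   `p_at_removal`, `step`), `retained` (character), `final` (coefficient
#'   table of the final model), `model` (the final glm fit).
#' @export
backward_stepwise <- function(candidates, outcome, p_remove = 0.1) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) >= length(outcome) / 2) {
    stop("candidate count must be below observations / 2", call. = FALSE)
  }
  current <- names(candidates)
  removed <- list()
  step <- 0L
  final_fit <- NULL
  repeat {
    if (!length(current)) break
    fit <- fit_logistic(candidates[, current, drop = FALSE], outcome)
    tab <- fit$coefficients
    tab <- tab[tab$term != "(Intercept)", ]
    bad <- tab$term[!tab$estimable]
    if (length(bad)) {
      step <- step + 1L
      for (b in sort(bad)) {
        removed[[length(removed) + 1L]] <-
          data.frame(variable = b, p_at_removal = NA_real_, step = step,
                     reason = "unestimable")
      }
      current <- setdiff(current, bad)
      next
    }
    worst <- which(tab$p_value == max(tab$p_value))
    if (tab$p_value[worst[1]] < p_remove) {
      final_fit <- fit
      break
    }
    # tie-break: lexicographically later name removed first
    drop_var <- max(tab$term[worst])
    step <- step + 1L
    removed[[length(removed) + 1L]] <-
      data.frame(variable = drop_var, p_at_removal = tab$p_value[tab$term == drop_var],
                 step = step, reason = "p_above_threshold")
    current <- setdiff(current, drop_var)
  }
  if (is.null(final_fit) && length(current)) {
    final_fit <- fit_logistic(candidates[, current, drop = FALSE], outcome)
  }
  structure(list(
    removed = if (length(removed)) do.call(rbind, removed)
              else data.frame(variable = character(0), p_at_removal = numeric(0),
                              step = integer(0), reason = character(0)),
    retained = current,
    final = if (!is.null(final_fit)) final_fit$coefficients else NULL,
    model = if (!is.null(final_fit)) final_fit$model else NULL
  ), class = "stepwise_trace")
}

#' Full HRnV model-building pipeline
#'
#' The study's procedure end to end: univariable screen of the HRV/HRnV
#' feature block at `screen_p`, addition of the clinical adjustment
#' covariates (entered as ordinary stepwise candidates, since the published
#' final model lacks several of them), collinearity pruning, and backward
#' stepwise elimination.
#'
#' @param cohort Data frame with `outcome`, the feature block and covariates.
#' @param feature_cols Names of the HRV/HRnV feature columns.
#' @param adjust_vars Clinical covariates added after the screen (default
#'   age, temperature, systolic BP, heart rate, GCS where present).
#' @param screen_p Univariable inclusion threshold for features (default 0.2).
#' @param collinearity_r Pruning threshold (default 0.8).
#' @param p_remove Stepwise endpoint (default 0.1).
#' @param force_vars Variables exempt from stepwise elimination (default
#'   none).
#' @return List: `screen`, `prune`, `trace` (a `"stepwise_trace"`),
#'   `candidates` (the pruned candidate set entering stepwise).
#' @export
build_hrnv_model <- function(cohort, feature_cols,
                             adjust_vars = intersect(
                               c("age", "temperature", "sbp", "heart_rate", "gcs"),
                               names(cohort)),
                             screen_p = 0.2, collinearity_r = 0.8,
                             p_remove = 0.1, force_vars = character(0)) {
  y <- cohort$outcome
  screen <- univariable_screen(cohort[, feature_cols, drop = FALSE], y,
                               threshold = screen_p)
  passed <- screen$variable[screen$passes_screen]
  cand_cols <- union(passed, adjust_vars)
  cand_screen <- univariable_screen(cohort[, cand_cols, drop = FALSE], y,
                                    threshold = screen_p)
  prune <- collinearity_prune(cohort[, cand_cols, drop = FALSE], cand_screen,
                              r_threshold = collinearity_r)
  cand <- prune$retained
  if (length(force_vars)) {
    free <- setdiff(cand, force_vars)
    trace <- backward_stepwise(cohort[, free, drop = FALSE], y, p_remove)
    # refit with forced variables added back
    kept <- union(trace$retained, intersect(force_vars, names(cohort)))
    fit <- fit_logistic(cohort[, kept, drop = FALSE], y)
    trace$retained <- kept
    trace$final <- fit$coefficients
    trace$model <- fit$model
  } else {
    trace <- backward_stepwise(cohort[, cand, drop = FALSE], y, p_remove)
  }
  list(screen = screen, prune = prune, trace = trace, candidates = cand)
}
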