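# Cross-validated ROC evaluation of fitted risk models, with DeLong /
# bootstrap AUC confidence intervals and published early-warning-score
# comparators (NEWS, MEWS, qSOFA).

#' Stratified k-fold assignment
#'
#' Folds are disjoint, sizes within 1 of n/k, and each class is dealt
#' round-robin so every fold carries both classes whenever n per class >= k
#' permits. Deterministic given the seed.
#'
#' @param outcome Binary 0/1 vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold labels (1..k) per observation.
#' @export
kfold_assign <- function(outcome, k = 10L, seed = 1L) {
  n <- length(outcome)
  if (n < 2 * k) stop("need n >= 2k observations", call. = FALSE)
  local_seed(seed, {
    ord <- c(sample(which(outcome == 1)), sample(which(outcome == 0)))
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    folds
  })
}

#' Out-of-fold predicted probabilities under k-fold cross-validation
#'
#' Each patient is scored exactly once, by a model whose training fold did
#' not contain them. By default the full model recipe (screen, prune,
#' stepwise) is re-run inside every training fold, so variable selection
#' cannot leak; `mode = "paper"` selects variables once on the full data and
#' only refits coefficients per fold, a reading the original wording also
#' permits.
#'
#' @param cohort Data frame with binary `outcome`.
#' @param recipe Either a function `function(train, test) -> numeric scores`
#'   or a list created by [hrnv_recipe()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold draw.
#' @param mode `"refit"` (leakage-free, default) or `"paper"`.
#' @return List: `scores` (per patient, out of fold), `folds` (assignment),
#'   `k`, `seed`.
#' @export
kfold_out_of_fold_scores <- function(cohort, recipe, k = 10L, seed = 1L,
                                     mode = c("refit", "paper")) {
  mode <- match.arg(mode)
  y <- cohort$outcome
  if (length(unique(y)) < 2) stop("outcome must have both classes", call. = FALSE)
  folds <- kfold_assign(y, k, seed)
  scorer <- if (is.function(recipe)) recipe else recipe_scorer(recipe, cohort, mode)
  scores <- rep(NA_real_, nrow(cohort))
  for (f in seq_len(k)) {
    train <- cohort[folds != f, , drop = FALSE]
    test <- cohort[folds == f, , drop = FALSE]
    scores[folds == f] <- scorer(train, test)
  }
  list(scores = scores, folds = folds, k = k, seed = seed)
}

#' A cross-validatable model recipe
#'
#' Bundles the selection settings of [build_hrnv_model()] so the whole
#' procedure can be re-run inside each training fold.
#'
#' @inheritParams build_hrnv_model
#' @return A list of class `"hrnv_recipe"`.
#' @export
hrnv_recipe <- function(feature_cols, adjust_vars = character(0),
                        screen_p = 0.2, collinearity_r = 0.8, p_remove = 0.1) {
  structure(list(feature_cols = feature_cols, adjust_vars = adjust_vars,
                 screen_p = screen_p, collinearity_r = collinearity_r,
                 p_remove = p_remove), class = "hrnv_recipe")
}

recipe_scorer <- function(recipe, cohort, mode) {
  stopifnot(inherits(recipe, "hrnv_recipe"))
  fixed_vars <- NULL
  if (mode == "paper") {
    full <- build_hrnv_model(cohort, recipe$feature_cols,
                             adjust_vars = recipe$adjust_vars,
                             screen_p = recipe$screen_p,
                             collinearity_r = recipe$collinearity_r,
                             p_remove = recipe$p_remove)
    fixed_vars <- full$trace$retained
  }
  function(train, test) {
    vars <- fixed_vars
    if (is.null(vars)) {
      m <- build_hrnv_model(train, recipe$feature_cols,
                            adjust_vars = recipe$adjust_vars,
                            screen_p = recipe$screen_p,
                            collinearity_r = recipe$collinearity_r,
                            p_remove = recipe$p_remove)
      vars <- m$trace$retained
    }
    if (!length(vars)) {
      # intercept-only model: constant risk
      return(rep(mean(train$outcome), nrow(test)))
    }
    fit <- fit_logistic(train[, vars, drop = FALSE], train$outcome)
    as.numeric(stats::predict(fit$model,
                              newdata = cbind(data.frame(.y = 0), test),
                              type = "response"))
  }
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Fraction of positive-negative pairs ordered correctly, ties counting one
#' half; identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC points
#'
#' @inheritParams auc
#' @return Data frame `threshold`, `fpr` (1 - specificity), `tpr`
#'   (sensitivity), monotone non-decreasing in both coordinates.
#' @export
roc_points <- function(scores, labels) {
  y <- as.numeric(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Confidence interval for the AUC
#'
#' DeLong's placement-variance interval by default, with a stratified
#' bootstrap (percentile, 2000 replicates) as an alternative and as the
#' automatic fallback when the DeLong variance degenerates.
#'
#' @inheritParams auc
#' @param method `"delong"` or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap draw.
#' @return List `auc`, `ci_low`, `ci_high`, `method`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   level = 0.95, n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  y <- as.numeric(labels)
  a <- auc(scores, y)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "delong") {
    pos <- scores[y == 1]; neg <- scores[y == 0]
    # placements: for each positive, fraction of negatives below (ties 1/2)
    v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), numeric(1))
    v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), numeric(1))
    va <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
    if (is.finite(va) && va > 0) {
      se <- sqrt(va)
      return(list(auc = a, ci_low = max(0, a - z * se),
                  ci_high = min(1, a + z * se), method = "delong"))
    }
    method <- "bootstrap"  # degenerate variance: fall back
  }
  boots <- local_seed(seed, {
    ipos <- which(y == 1); ineg <- which(y == 0)
    vapply(seq_len(n_boot), function(b) {
      i <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
      auc(scores[i], y[i])
    }, numeric(1))
  })
  q <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  list(auc = a, ci_low = max(0, q[1]), ci_high = min(1, q[2]),
       method = "bootstrap")
}

band_score <- function(x, breaks, points, clamp_warn = TRUE) {
  if (is.na(x)) return(NA_integer_)
  i <- findInterval(x, breaks, left.open = FALSE)
  points[i + 1L]
}

#' National Early Warning Score (NEWS)
#'
#' Published 2012 NEWS bands over respiratory rate, SpO2, supplemental
#' oxygen, temperature, systolic BP, heart rate and consciousness (AVPU;
#' mapped from GCS as alert iff GCS = 15). Missing fields contribute 0 and
#' flag the score partial; out-of-range vitals are clamped to the extreme
#' band with a warning.
#'
#' @param resp_rate Breaths/min.
#' @param spo2 Oxygen saturation, %.
#' @param supp_o2 Supplemental oxygen flag (0/1).
#' @param temperature Degrees C.
#' @param sbp Systolic blood pressure, mmHg.
#' @param heart_rate Beats/min.
#' @param gcs Glasgow Coma Scale, 3-15.
#' @return Integer score; attribute `"partial"` is TRUE if any field was
#'   missing.
#' @export
news_score <- function(resp_rate = NA, spo2 = NA, supp_o2 = NA,
                       temperature = NA, sbp = NA, heart_rate = NA,
                       gcs = NA) {
  check_range <- function(x, lo, hi, name) {
    if (!is.na(x) && (x < lo || x > hi)) {
      warning(sprintf("%s = %g outside plausible range [%g, %g]; clamped",
                      name, x, lo, hi), call. = FALSE)
      x <- min(max(x, lo), hi)
    }
    x
  }
  resp_rate <- check_range(resp_rate, 0, 80, "resp_rate")
  spo2 <- check_range(spo2, 0, 100, "spo2")
  temperature <- check_range(temperature, 25, 45, "temperature")
  sbp <- check_range(sbp, 20, 300, "sbp")
  heart_rate <- check_range(heart_rate, 0, 300, "heart_rate")
  comps <- c(
    band_score(resp_rate, c(9, 12, 21, 25), c(3L, 1L, 0L, 2L, 3L)),
    band_score(spo2, c(92, 94, 96), c(3L, 2L, 1L, 0L)),
    if (is.na(supp_o2)) NA_integer_ else if (supp_o2 > 0) 2L else 0L,
    band_score(temperature, c(35.1, 36.1, 38.1, 39.1), c(3L, 1L, 0L, 1L, 2L)),
    band_score(sbp, c(91, 101, 111, 220), c(3L, 2L, 1L, 0L, 3L)),
    band_score(heart_rate, c(41, 51, 91, 111, 131), c(3L, 1L, 0L, 1L, 2L, 3L)),
    if (is.na(gcs)) NA_integer_ else if (gcs < 15) 3L else 0L
  )
  structure(sum(comps, na.rm = TRUE), partial = anyNA(comps))
}

#' Modified Early Warning Score (MEWS)
#'
#' Published MEWS bands over systolic BP, heart rate, respiratory rate,
#' temperature and AVPU (mapped from GCS: 15 alert, 13-14 voice, 9-12 pain,
#' below 9 unresponsive).
#'
#' @inheritParams news_score
#' @return Integer score; attribute `"partial"` as in [news_score()].
#' @export
mews_score <- function(sbp = NA, heart_rate = NA, resp_rate = NA,
                       temperature = NA, gcs = NA) {
  comps <- c(
    band_score(sbp, c(71, 81, 101, 200), c(3L, 2L, 1L, 0L, 2L)),
    band_score(heart_rate, c(41, 51, 101, 111, 130), c(2L, 1L, 0L, 1L, 2L, 3L)),
    band_score(resp_rate, c(9, 15, 21, 30), c(2L, 0L, 1L, 2L, 3L)),
    band_score(temperature, c(35, 38.5), c(2L, 0L, 2L)),
    if (is.na(gcs)) NA_integer_
    else if (gcs == 15) 0L else if (gcs >= 13) 1L else if (gcs >= 9) 2L else 3L
  )
  structure(sum(comps, na.rm = TRUE), partial = anyNA(comps))
}

#' Quick SOFA (qSOFA)
#'
#' One point each for respiratory rate >= 22 /min, systolic BP <= 100 mmHg
#' and altered consciousness (GCS < 15); range 0-3.
#'
#' @inheritParams news_score
#' @return Integer score 0-3; attribute `"partial"` as in [news_score()].
#' @export
qsofa_score <- function(resp_rate = NA, sbp = NA, gcs = NA) {
  comps <- c(if (is.na(resp_rate)) NA_integer_ else as.integer(resp_rate >= 22),
             if (is.na(sbp)) NA_integer_ else as.integer(sbp <= 100),
             if (is.na(gcs)) NA_integer_ else as.integer(gcs < 15))
  structure(sum(comps, na.rm = TRUE), partial = anyNA(comps))
}

#' Compare model recipes and score baselines by cross-validated ROC
#'
#' Fitted-model entrants are evaluated by out-of-fold prediction on a shared
#' fold assignment; lookup-score entrants (functions of a cohort row or
#' precomputed numeric columns) are scored directly. Entrants that fail are
#' excluded with a logged reason.
#'
#' @param cohort Data frame with binary `outcome`.
#' @param entrants Named list; each element an [hrnv_recipe()], a scoring
#'   `function(cohort) -> numeric`, or a column name of a precomputed score.
#' @param k Folds for fitted models (default 10).
#' @param seed Seed shared by all entrants.
#' @return List: `summary` data.frame (`entrant`, `auc`, `ci_low`, `ci_high`,
#'   `method`), `roc` (list of ROC point tables), `scores`, `errors`.
#' @export
compare_models <- function(cohort, entrants, k = 10L, seed = 1L) {
  y <- cohort$outcome
  res <- list(); rocs <- list(); all_scores <- list(); errors <- list()
  for (nm in names(entrants)) {
    ent <- entrants[[nm]]
    scores <- tryCatch({
      if (inherits(ent, "hrnv_recipe") || is.function(ent)) {
        if (inherits(ent, "hrnv_recipe")) {
          kfold_out_of_fold_scores(cohort, ent, k, seed)$scores
        } else {
          ent(cohort)
        }
      } else if (is.character(ent) && ent %in% names(cohort)) {
        cohort[[ent]]
      } else {
        stop("unrecognised entrant")
      }
    }, error = function(e) {
      errors[[nm]] <<- conditionMessage(e)
      NULL
    })
    if (is.null(scores)) next
    ci <- auc_ci(scores, y, seed = child_seed(seed, match(nm, names(entrants))))
    res[[nm]] <- data.frame(entrant = nm, auc = ci$auc, ci_low = ci$ci_low,
                            ci_high = ci$ci_high, method = ci$method)
    rocs[[nm]] <- roc_points(scores, y)
    all_scores[[nm]] <- scores
  }
  summary <- do.call(rbind, res)
  rownames(summary) <- NULL
  summary <- summary[order(-summary$auc), ]
  list(summary = summary, roc = rocs, scores = all_scores, errors = errors)
}
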