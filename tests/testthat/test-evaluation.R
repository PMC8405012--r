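test_that("stratified k-fold structure is valid and deterministic", {
  co <- generate_cohort(cohort_spec(342, 0.19, seed = 41))
  f <- kfold_assign(co$outcome, k = 10, seed = 1)
  sizes <- as.vector(table(f))
  expect_true(all(sizes %in% c(34, 35)))
  expect_equal(sum(sizes), 342)
  # every fold has both classes
  expect_true(all(sapply(1:10, function(k) length(unique(co$outcome[f == k])) == 2)))
  expect_identical(f, kfold_assign(co$outcome, 10, seed = 1))
  expect_false(identical(f, kfold_assign(co$outcome, 10, seed = 2)))
  expect_error(kfold_assign(rbinom(15, 1, 0.5), k = 10), "2k")
})

test_that("out-of-fold scores never come from a model trained on the patient", {
  co <- generate_cohort(cohort_spec(200, 0.25, n_features = 3,
                                    feature_effects = c(feat_01 = 0.8),
                                    seed = 42))
  seen <- list()
  probe <- function(train, test) {
    # record which patients trained the model scoring these test rows
    for (id in test$id) seen[[id]] <<- train$id
    rep(0.5, nrow(test))
  }
  res <- kfold_out_of_fold_scores(co, probe, k = 5, seed = 3)
  expect_false(anyNA(res$scores))
  for (id in co$id) expect_false(id %in% seen[[id]])
  # each patient scored exactly once
  expect_equal(sort(names(seen)), sort(co$id))
})

test_that("AUC is the Mann-Whitney pair-ordering fraction", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  # ties count one half
  expect_equal(auc(c(1, 1), c(0, 1)), 0.5)
  set.seed(43)
  expect_lt(abs(auc(runif(1000), rbinom(1000, 1, 0.5)) - 0.5), 0.05)
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC equals the trapezoidal area under the ROC points", {
  trap <- function(rp) {
    sum(diff(rp$fpr) * (head(rp$tpr, -1) + tail(rp$tpr, -1)) / 2)
  }
  set.seed(44)
  for (i in 1:20) {
    n <- 80
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, y), 1)  # includes ties
    rp <- roc_points(s, y)
    expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))
    expect_equal(auc(s, y), trap(rp), tolerance = 1e-10)
  }
})

test_that("AUC confidence intervals: DeLong vs bootstrap", {
  set.seed(45)
  y <- rep(c(1, 0), c(65, 277))
  s <- c(rnorm(65, 1.05), rnorm(277, 0))  # AUC ~ 0.77 at study-like n
  d <- auc_ci(s, y, method = "delong")
  b <- auc_ci(s, y, method = "bootstrap", seed = 9)
  expect_equal(d$auc, b$auc)
  expect_lt(abs(d$ci_low - b$ci_low), 0.02)
  expect_lt(abs(d$ci_high - b$ci_high), 0.02)
  expect_true(d$ci_low <= d$auc && d$auc <= d$ci_high)

  # smaller n widens the interval
  set.seed(46)
  y2 <- rep(c(1, 0), c(20, 80))
  s2 <- c(rnorm(20, 1.05), rnorm(80, 0))
  d2 <- auc_ci(s2, y2, method = "delong")
  expect_gt(d2$ci_high - d2$ci_low, d$ci_high - d$ci_low)

  # perfect separation: bounds capped at 1, degenerate variance falls back
  yp <- rep(c(0, 1), each = 20)
  sp <- c(rnorm(20, -4), rnorm(20, 4))
  p <- auc_ci(sp, yp)
  expect_lte(p$ci_high, 1)
  expect_equal(p$auc, 1)
})

test_that("early-warning calculators reproduce the published band tables", {
  # textbook-normal vitals score zero on all three (MEWS's zero band for
  # respiratory rate is 9-14 in the published table, so its baseline uses 12)
  expect_equal(as.integer(news_score(16, 98, 0, 37, 120, 70, 15)), 0L)
  expect_equal(as.integer(mews_score(120, 70, 12, 37, 15)), 0L)
  expect_equal(as.integer(qsofa_score(16, 120, 15)), 0L)

  # qSOFA: all three criteria met; SBP boundary at exactly 100 scores
  expect_equal(as.integer(qsofa_score(25, 90, 14)), 3L)
  expect_equal(as.integer(qsofa_score(16, 100, 15)), 1L)
  expect_equal(as.integer(qsofa_score(22, 101, 15)), 1L)

  # exhaustive NEWS band boundaries, one component varied from zero baseline
  news1 <- function(...) as.integer(news_score(...))
  base <- list(resp_rate = 16, spo2 = 98, supp_o2 = 0, temperature = 37,
               sbp = 120, heart_rate = 70, gcs = 15)
  news_at <- function(field, value) {
    args <- base; args[[field]] <- value
    do.call(news1, args)
  }
  rr_bands <- rbind(c(8, 3), c(9, 1), c(11, 1), c(12, 0), c(20, 0),
                    c(21, 2), c(24, 2), c(25, 3))
  for (i in seq_len(nrow(rr_bands))) {
    expect_equal(news_at("resp_rate", rr_bands[i, 1]), rr_bands[i, 2])
  }
  spo2_bands <- rbind(c(91, 3), c(92, 2), c(93, 2), c(94, 1), c(95, 1), c(96, 0))
  for (i in seq_len(nrow(spo2_bands))) {
    expect_equal(news_at("spo2", spo2_bands[i, 1]), spo2_bands[i, 2])
  }
  temp_bands <- rbind(c(35.0, 3), c(35.1, 1), c(36.0, 1), c(36.1, 0),
                      c(38.0, 0), c(38.1, 1), c(39.0, 1), c(39.1, 2))
  for (i in seq_len(nrow(temp_bands))) {
    expect_equal(news_at("temperature", temp_bands[i, 1]), temp_bands[i, 2])
  }
  sbp_bands <- rbind(c(90, 3), c(91, 2), c(100, 2), c(101, 1), c(110, 1),
                     c(111, 0), c(219, 0), c(220, 3))
  for (i in seq_len(nrow(sbp_bands))) {
    expect_equal(news_at("sbp", sbp_bands[i, 1]), sbp_bands[i, 2])
  }
  hr_bands <- rbind(c(40, 3), c(41, 1), c(50, 1), c(51, 0), c(90, 0),
                    c(91, 1), c(110, 1), c(111, 2), c(130, 2), c(131, 3))
  for (i in seq_len(nrow(hr_bands))) {
    expect_equal(news_at("heart_rate", hr_bands[i, 1]), hr_bands[i, 2])
  }
  expect_equal(news_at("supp_o2", 1), 2L)
  expect_equal(news_at("gcs", 14), 3L)

  # MEWS band boundaries
  mews1 <- function(...) as.integer(mews_score(...))
  mbase <- list(sbp = 120, heart_rate = 70, resp_rate = 12, temperature = 37,
                gcs = 15)
  mews_at <- function(field, value) {
    args <- mbase; args[[field]] <- value
    do.call(mews1, args)
  }
  expect_equal(mews_at("sbp", 70), 3L)
  expect_equal(mews_at("sbp", 71), 2L)
  expect_equal(mews_at("sbp", 81), 1L)
  expect_equal(mews_at("sbp", 101), 0L)
  expect_equal(mews_at("sbp", 200), 2L)
  expect_equal(mews_at("heart_rate", 40), 2L)
  expect_equal(mews_at("heart_rate", 41), 1L)
  expect_equal(mews_at("heart_rate", 51), 0L)
  expect_equal(mews_at("heart_rate", 101), 1L)
  expect_equal(mews_at("heart_rate", 111), 2L)
  expect_equal(mews_at("heart_rate", 130), 3L)
  expect_equal(mews_at("resp_rate", 8), 2L)
  expect_equal(mews_at("resp_rate", 9), 0L)
  expect_equal(mews_at("resp_rate", 15), 1L)
  expect_equal(mews_at("resp_rate", 21), 2L)
  expect_equal(mews_at("resp_rate", 30), 3L)
  expect_equal(mews_at("temperature", 34.9), 2L)
  expect_equal(mews_at("temperature", 35), 0L)
  expect_equal(mews_at("temperature", 38.5), 2L)
  expect_equal(mews_at("gcs", 14), 1L)
  expect_equal(mews_at("gcs", 10), 2L)
  expect_equal(mews_at("gcs", 8), 3L)

  # missing fields flag the score partial; out-of-range vitals warn
  p <- news_score(resp_rate = 16)
  expect_true(attr(p, "partial"))
  expect_warning(news_score(16, 98, 0, 37, 500, 70, 15), "clamped")
})

test_that("compare_models ranks entrants on a shared evaluation", {
  co <- generate_cohort(cohort_spec(800, 0.19, seed = 51))
  co$news <- mapply(function(r, s, o, t, b, h, g) as.integer(news_score(r, s, o, t, b, h, g)),
                    co$resp_rate, co$spo2, co$supp_o2, co$temperature,
                    co$sbp, co$heart_rate, co$gcs)
  feature_cols <- sprintf("feat_%02d", 1:25)
  vitals <- c("age", "temperature", "resp_rate", "spo2", "sbp", "heart_rate", "gcs")
  res <- compare_models(co, list(
    hrnv = hrnv_recipe(feature_cols, adjust_vars = vitals),
    vitals_only = hrnv_recipe(vitals),
    news = "news"
  ), k = 5, seed = 4)
  expect_setequal(res$summary$entrant, c("hrnv", "vitals_only", "news"))
  # features carry signal beyond the vitals by construction
  a <- function(e) res$summary$auc[res$summary$entrant == e]
  expect_gt(a("hrnv"), a("vitals_only"))
  expect_gt(a("hrnv"), 0.65)
  # deterministic given seed
  res2 <- compare_models(co, list(news = "news"), k = 5, seed = 4)
  expect_equal(res2$summary$auc, a("news"))

  # failing entrant excluded with a reason
  res3 <- compare_models(co, list(bad = "no_such_column", news = "news"),
                         k = 5, seed = 4)
  expect_equal(nrow(res3$summary), 1)
  expect_true("bad" %in% names(res3$errors))
})

test_that("zero-signal cohorts evaluate near chance", {
  co0 <- generate_cohort(cohort_spec(700, 0.2,
                                     feature_effects = setNames(numeric(0), character(0)),
                                     covariate_effects = setNames(numeric(0), character(0)),
                                     seed = 52))
  res <- kfold_out_of_fold_scores(
    co0, hrnv_recipe(sprintf("feat_%02d", 1:25)), k = 10, seed = 5)
  expect_lt(abs(auc(res$scores, co0$outcome) - 0.5), 0.08)
})
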