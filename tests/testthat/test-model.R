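test_that("label scheme halves stages and excludes the final stage", {
  lab7 <- make_labels(7)
  expect_identical(lab7$label, c(rep("normal", 4), "abnormal", "abnormal", NA))
  expect_equal(lab7$severity[1], 0)
  expect_equal(lab7$severity[6], 0.8)  # final retained stage

  lab2 <- make_labels(2)
  expect_false(attr(lab2, "usable"))
  expect_error(make_labels(1), "at least 2")

  for (L in 5:9) {
    lab <- make_labels(L)
    expect_equal(lab$severity[L - 1], 0.8)
    expect_true(all(diff(lab$severity) >= 0))
    expect_true(is.na(lab$label[L]))
  }
})

test_that("nested CV is near-perfect on separable classes and leak-free", {
  tab <- synthetic_table(20, 12, 5, seed = 1, separation = 6)
  rep <- nested_cv_svm(tab, seed = 1)
  expect_gte(rep$mean[["auc"]], 0.99)
  expect_gte(rep$mean[["accuracy"]], 98)
  expect_equal(nrow(rep$folds), 10)
  expect_true(all(rep$folds$chosen_C %in% 2^seq(-6, 8, 2)))
})

test_that("permuted labels drive AUC to chance", {
  aucs <- vapply(1:5, function(seed) {
    tab <- synthetic_table(20, 12, 5, seed = seed, separation = 6)
    set.seed(seed)
    for (s in unique(tab$subject_id)) {
      i <- which(tab$subject_id == s)
      tab$label[i] <- sample(tab$label[i])
    }
    suppressWarnings(nested_cv_svm(tab, seed = seed,
                                   C_grid = 1)$mean[["auc"]])
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("row duplication leaves fold metrics unchanged", {
  tab <- synthetic_table(15, 8, 4, seed = 3, separation = 2)
  r1 <- nested_cv_svm(tab, seed = 5, C_grid = c(0.1, 1))
  tab2 <- rbind(tab, tab)
  r2 <- nested_cv_svm(tab2, seed = 5, C_grid = c(0.1, 1))
  expect_equal(r1$folds$auc, r2$folds$auc, tolerance = 1e-6)
  expect_equal(r1$folds$accuracy, r2$folds$accuracy, tolerance = 1e-6)
})

test_that("one-point C grid reduces to plain cross-validation", {
  tab <- synthetic_table(12, 8, 4, seed = 4, separation = 3)
  r <- nested_cv_svm(tab, seed = 2, C_grid = 1)
  expect_true(all(r$folds$chosen_C == 1))
  expect_equal(unname(r$mean["auc"]), mean(r$folds$auc))
})

test_that("Mann-Whitney comparison matches exact tail probabilities", {
  mk_rep <- function(aucs) {
    structure(list(folds = data.frame(fold = seq_along(aucs), auc = aucs,
                                      accuracy = aucs * 100)),
              class = "cv_report")
  }
  same <- mk_rep(c(0.8, 0.81, 0.82, 0.83, 0.84, 0.85, 0.86, 0.87, 0.88, 0.89))
  out <- suppressWarnings(compare_feature_sets(same, same))
  expect_equal(out$p_value[1], 1, tolerance = 1e-9)
  expect_false(any(out$significant))

  lo <- mk_rep(seq(0.60, 0.69, by = 0.01))
  hi <- mk_rep(seq(0.80, 0.89, by = 0.01))
  out2 <- compare_feature_sets(hi, lo)
  expect_equal(out2$U[1], 100)  # complete separation
  expect_equal(out2$p_value[1], 2 / choose(20, 10), tolerance = 1e-7)
  expect_true(all(out2$significant))

  # one tied pair among otherwise separated folds: still significant
  lo2 <- mk_rep(c(seq(0.60, 0.68, by = 0.01), 0.80))
  out3 <- suppressWarnings(compare_feature_sets(hi, lo2))
  expect_lt(out3$p_value[1], 0.01)
  expect_error(compare_feature_sets(mk_rep(c(1, 2)), mk_rep(c(1, 2))), "folds")
})

test_that("reduced-feature curve reuses the ranking deterministically", {
  tab <- synthetic_table(15, 10, 12, seed = 6, separation = 2)
  ranked <- sprintf("f%03d", 1:12)
  curve <- reduced_featureset_curve(tab, ranked, sizes = c(2, 10), seed = 3)
  full <- nested_cv_svm(tab, ranked[1:10], seed = 3)
  expect_identical(curve$top10$folds, full$folds)
  expect_length(reduced_featureset_curve(tab, ranked, sizes = 2, seed = 1), 1)
})

test_that("severity regression recovers linear structure and collapses on noise", {
  tab <- synthetic_table(15, 10, 3, seed = 7)
  lv <- rep(c(0, 0.2, 0.4, 0.6, 0.8), length.out = nrow(tab))
  tab$severity <- lv
  # exact linear severity: predictions equal actual at all levels
  tab$f001 <- 2 * lv - 1
  out <- fit_severity_regression(tab, c("f001", "f002", "f003"))
  expect_equal(out$by_level$predicted, out$by_level$severity, tolerance = 1e-9)

  # pure-noise features: every level predicted near the grand mean
  set.seed(8)
  tab$f001 <- rnorm(nrow(tab)); tab$f002 <- rnorm(nrow(tab)); tab$f003 <- rnorm(nrow(tab))
  out2 <- fit_severity_regression(tab, c("f001", "f002", "f003"))
  expect_true(all(abs(out2$by_level$predicted - 0.4) < 0.1))

  # planted monotone features: slope in [0.5, 1], monotone predictions
  tabm <- synthetic_table(20, 10, 3, seed = 9)
  lv <- rep(c(0, 0.2, 0.4, 0.6, 0.8), length.out = nrow(tabm))
  tabm$severity <- lv
  set.seed(10)
  tabm$f001 <- lv + rnorm(nrow(tabm), 0, 0.2)
  tabm$f002 <- -2 * lv + rnorm(nrow(tabm), 0, 0.3)
  tabm$f003 <- rnorm(nrow(tabm))
  out3 <- fit_severity_regression(tabm, c("f001", "f002", "f003"))
  slope <- coef(lm(predicted ~ severity, data = out3$by_level))[2]
  expect_gte(slope, 0.5); expect_lte(slope, 1.0)
  expect_true(all(diff(out3$by_level$predicted) > 0))

  tabr <- tabm; tabr$f002 <- tabr$f001
  expect_error(fit_severity_regression(tabr, c("f001", "f002")), "rank")
})
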