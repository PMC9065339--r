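fast_xgb <- function(seed = 1L) {
  model_config("xgboost", params = list(nrounds = 60), seed = seed)
}

test_that("confusion counts enumerate the four cells", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L), ignore_attr = TRUE)
  all_ok <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(all_ok$FP + all_ok$FN, 0)
  all_pos <- confusion_counts(c(1, 0, 1), c(1, 1, 1))
  expect_equal(all_pos$TN + all_pos$FN, 0)
})

test_that("the worked confusion example reproduces all five metrics", {
  e <- eval_metrics(list(TP = 50, TN = 40, FP = 10, FN = 0))
  expect_equal(e$ACC, 0.9)
  expect_equal(e$SEN, 1.0)
  expect_equal(e$SPE, 0.8)
  expect_equal(round(e$PRE, 4), 0.8333)
  expect_equal(round(e$MCC, 4), 0.8165)
  expect_equal(e$MCC, 2000 / sqrt(6e6))
  perfect <- eval_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("ACC", "SEN", "SPE", "PRE", "MCC")]),
               rep(1, 5), ignore_attr = TRUE)
})

test_that("the literal specificity variant divides by TN + FN", {
  e <- eval_metrics(list(TP = 50, TN = 40, FP = 10, FN = 20),
                    spe_literal = TRUE)
  expect_equal(e$SPE, 40 / 60)
  e2 <- eval_metrics(list(TP = 50, TN = 40, FP = 10, FN = 20))
  expect_equal(e2$SPE, 40 / 50)
})

test_that("zero-denominator metrics are NaN with a warning, never 0", {
  w <- testthat::capture_warnings(
    e <- eval_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0)))
  expect_true(any(grepl("SEN", w)))
  expect_true(is.nan(e$SEN))
  expect_false(identical(e$SEN, 0))
})

test_that("metric formulas agree with direct arithmetic on random tables", {
  for (i in 1:200) {
    cc <- withr::with_seed(i, as.list(setNames(sample(0:60, 4, TRUE),
                                               c("TP", "TN", "FP", "FN"))))
    if (sum(unlist(cc)) == 0) next
    e <- suppressWarnings(eval_metrics(cc))
    with(cc, {
      expect_equal(e$ACC, (TP + TN) / (TP + TN + FP + FN), tolerance = 1e-12)
      if (TP + FN > 0) expect_equal(e$SEN, TP / (TP + FN), tolerance = 1e-12)
      if (TN + FP > 0) expect_equal(e$SPE, TN / (TN + FP), tolerance = 1e-12)
      if (TP + FP > 0) expect_equal(e$PRE, TP / (TP + FP), tolerance = 1e-12)
      den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
      if (den > 0) {
        expect_equal(e$MCC, (TP * TN - FP * FN) / den, tolerance = 1e-12)
      }
    })
  }
})

test_that("rank-based AUC equals pair-counting and pROC oracles", {
  for (i in 1:10) {
    n <- 20 + i * 10
    truth <- withr::with_seed(i, sample(0:1, n, TRUE))
    if (length(unique(truth)) < 2) next
    score <- withr::with_seed(i + 500, round(stats::runif(n), 2))  # ties
    expect_equal(auc_score(truth, score), oracle_auc(truth, score),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  truth <- rep(0:1, each = 50)
  score <- withr::with_seed(3, stats::rnorm(100) + truth)
  expect_equal(auc_score(truth, score),
               as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("tied scores give AUC 0.5 and score 0.5 classifies positive", {
  expect_equal(auc_score(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
  tbl <- make_classification_set(30, 30, effect_size = 3, seed = 1)
  fit <- train_classifier(tbl, fast_xgb())
  pr <- predict(fit, dplyr::mutate(tbl, label = NULL))
  expect_true(all(pr$pred == as.integer(pr$score >= 0.5)))
})

test_that("training is deterministic and separable data is memorised", {
  tbl <- make_classification_set(40, 40, effect_size = 3, seed = 2)
  f1 <- train_classifier(tbl, fast_xgb(seed = 9))
  f2 <- train_classifier(tbl, fast_xgb(seed = 9))
  expect_identical(predict(f1, tbl)$score, predict(f2, tbl)$score)
  expect_equal(predict(f1, tbl)$pred, tbl$label)
  e <- evaluate_independent(f1, tbl)
  expect_equal(e$AUC, 1.0)
})

test_that("single-class input and schema mismatches are errors", {
  tbl <- make_classification_set(10, 10, seed = 1)
  expect_error(train_classifier(dplyr::filter(tbl, label == 1),
                                fast_xgb()), "single class")
  fit <- train_classifier(tbl, fast_xgb())
  expect_error(predict(fit, dplyr::select(tbl, -pssm_A)), "pssm_A")
})

test_that("column order does not change predictions", {
  tbl <- make_classification_set(30, 30, effect_size = 2, seed = 5)
  fit <- train_classifier(tbl, fast_xgb())
  shuffled <- dplyr::select(tbl, dplyr::all_of(
    c("label", withr::with_seed(1, sample(feature_columns("all"))))))
  expect_equal(predict(fit, shuffled)$score, predict(fit, tbl)$score)
})

test_that("SVM and CART baselines train and score in [0, 1]", {
  tbl <- make_classification_set(40, 40, effect_size = 3, seed = 3)
  for (alg in c("svm", "cart")) {
    fit <- train_classifier(tbl, model_config(alg, seed = 1))
    pr <- predict(fit, tbl)
    expect_true(all(pr$score >= 0 & pr$score <= 1), label = alg)
    expect_gt(auc_score(tbl$label, pr$score), 0.9)
  }
})

test_that("pooled k-fold predictions cover each row exactly once", {
  tbl <- make_classification_set(30, 30, effect_size = 1, seed = 4)
  cv <- cross_validate(tbl, fast_xgb(), k = 5, seed = 2)
  expect_equal(nrow(cv$predictions), nrow(tbl))
  expect_false(anyNA(cv$predictions$score))
  expect_equal(cv$counts$TP + cv$counts$TN + cv$counts$FP + cv$counts$FN,
               nrow(tbl))
})

test_that("k = n cross-validation reduces to the jackknife", {
  tbl <- make_classification_set(30, 30, effect_size = 1.5, seed = 6)
  cfg <- fast_xgb(seed = 3)
  jk <- cross_validate(tbl, cfg, protocol = "jackknife")
  kn <- cross_validate(tbl, cfg, protocol = "kfold", k = nrow(tbl), seed = 1)
  expect_equal(sort(jk$predictions$score), sort(kn$predictions$score),
               tolerance = 1e-12)
  expect_equal(glance(jk)[, c("ACC", "AUC")], glance(kn)[, c("ACC", "AUC")],
               tolerance = 1e-12)
})

test_that("separable data scores near-perfect CV AUC; permuted labels near 0.5", {
  tbl <- make_classification_set(100, 100, effect_size = 3, seed = 7)
  cv <- cross_validate(tbl, fast_xgb(), k = 10, seed = 3)
  expect_gte(cv$AUC, 0.95)

  aucs <- vapply(1:15, function(s) {
    null_tbl <- make_classification_set(60, 60, effect_size = 0, seed = s)
    cross_validate(null_tbl, fast_xgb(seed = s), k = 5, seed = s)$AUC
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("grouped cross-validation keeps complexes intact", {
  tbl <- dplyr::bind_rows(lapply(1:6, function(i) {
    dplyr::mutate(make_classification_set(8, 8, effect_size = 1, seed = i),
                  structure_id = paste0("cx", i))
  }))
  cv <- cross_validate(tbl, fast_xgb(), k = 3, seed = 2,
                       group_by_complex = TRUE)
  expect_equal(nrow(cv$predictions), nrow(tbl))
})

test_that("independent evaluation refuses an empty test set", {
  tbl <- make_classification_set(20, 20, seed = 8)
  fit <- train_classifier(tbl, fast_xgb())
  expect_error(evaluate_independent(fit, tbl[0, ]), "empty")
})

test_that("tidy and glance expose the report as tibbles", {
  e <- eval_metrics(list(TP = 50, TN = 40, FP = 10, FN = 0))
  td <- generics::tidy(e)
  expect_equal(td$metric[1], "ACC")
  expect_equal(td$value[1], 0.9)
  gl <- generics::glance(e)
  expect_equal(gl$TP, 50)
  expect_equal(gl$protocol, "direct")
})
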