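test_that("an unpruned forest memorizes separable training data", {
  set.seed(1)
  X <- rbind(matrix(rnorm(100), 20, 5), matrix(rnorm(100) + 4, 20, 5))
  colnames(X) <- paste0("f", 1:5)
  y <- factor(rep(c("TERM", "PRETERM"), each = 20),
              levels = c("TERM", "PRETERM"))
  forest <- train_rf(X, y, rf_config(seed = 1))
  pr <- predict_rf(forest, X)
  expect_equal(confusion_metrics(y, pr$label)$ACC, 1.0)
  expect_error(train_rf(X, factor(rep("TERM", 40))), "single-class")
})

test_that("pure-noise labels give chance-level test accuracy", {
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    Xtr <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("f", 1:5)))
    ytr <- factor(sample(c("TERM", "PRETERM"), 100, TRUE),
                  levels = c("TERM", "PRETERM"))
    Xte <- matrix(rnorm(500 * 5), 500, 5, dimnames = list(NULL, paste0("f", 1:5)))
    yte <- factor(sample(c("TERM", "PRETERM"), 500, TRUE),
                  levels = c("TERM", "PRETERM"))
    pr <- predict_rf(train_rf(Xtr, ytr, rf_config(seed = s)), Xte)
    confusion_metrics(yte, pr$label)$ACC
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("training and prediction are deterministic given the seed", {
  ds <- make_feature_dataset(n_min = 15, n_maj = 25, p = 6)
  f1 <- train_rf(ds$features, ds$outcome, rf_config(seed = 7))
  f2 <- train_rf(ds$features, ds$outcome, rf_config(seed = 7))
  expect_identical(predict_rf(f1, ds$features)$score,
                   predict_rf(f2, ds$features)$score)
})

test_that("permutation importance finds a single informative feature", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(200 * 31), 200, 31,
                dimnames = list(NULL, paste0("f", 1:31)))
    y <- factor(ifelse(X[, 17] > 0, "PRETERM", "TERM"),
                levels = c("TERM", "PRETERM"))
    imp <- rank_importance(train_rf(X, y, rf_config(seed = s)))
    expect_equal(sum(imp), 100, tolerance = 0.01)
    expect_gte(imp["f17"], 50)
  }
})

test_that("no noise feature reaches a dominating importance share", {
  # with pure noise, clipped-normalized permutation importance is noisy
  # (the max share across 31 features fluctuates around ~25%), but no
  # feature ever approaches the dominating share a genuine signal earns
  for (s in 1:10) {
    set.seed(100 + s)
    X <- matrix(rnorm(150 * 31), 150, 31,
                dimnames = list(NULL, paste0("f", 1:31)))
    y <- factor(sample(c("TERM", "PRETERM"), 150, TRUE),
                levels = c("TERM", "PRETERM"))
    imp <- rank_importance(train_rf(X, y, rf_config(seed = s)))
    if (sum(imp) > 0) expect_lt(max(imp), 50)
  }
})

test_that("ROC/AUC: perfect and random scorers, and the U identity", {
  truth <- factor(rep(c("PRETERM", "TERM"), c(30, 70)),
                  levels = c("TERM", "PRETERM"))
  perfect <- ifelse(truth == "PRETERM", 1, 0)
  r <- roc_curve(truth, perfect)
  expect_equal(r$auc, 1.0)
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    roc_curve(factor(sample(c("PRETERM", "TERM"), 600, TRUE)),
              runif(600))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
  # AUC is the normalized Mann-Whitney U of the scores (ties included)
  set.seed(9)
  score <- round(runif(100), 1)           # deliberately tied scores
  truth2 <- factor(sample(c("PRETERM", "TERM"), 100, TRUE))
  pos <- score[truth2 == "PRETERM"]; neg <- score[truth2 != "PRETERM"]
  u <- unname(suppressWarnings(wilcox.test(pos, neg)$statistic))
  expect_equal(roc_curve(truth2, score)$auc,
               u / (length(pos) * length(neg)), tolerance = 1e-12)
  # cross-check against the reference ROC implementation
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = truth2, predictor = score, levels = c("TERM", "PRETERM"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_curve(truth2, score)$auc, proc_auc, tolerance = 1e-12)
})

test_that("cross-validation report satisfies its structural identities", {
  ds <- make_feature_dataset(n_min = 18, n_maj = 42, p = 8,
                             shift_cols = 1:3, shift = 2.5, seed = 2)
  rep6 <- cross_validate(ds, rf_config(seed = 3), folds = 6, seed = 4)
  expect_s3_class(rep6, "cv_report")
  expect_equal(nrow(rep6$per_fold), 6)
  with(rep6$per_fold, {
    expect_equal(ACC * (TP + TN + FP + FN), TP + TN)
    expect_equal(sensitivity, TP / (TP + FN))
    expect_equal(specificity, TN / (TN + FP))
  })
  # every record evaluated exactly once
  expect_equal(sum(with(rep6$per_fold, TP + TN + FP + FN)), 60)
  expect_equal(rep6$mean_ACC, mean(rep6$per_fold$ACC))
  expect_equal(sum(rep6$importance), 100, tolerance = 0.01)
  expect_true(all(rep6$per_fold$ACC >= 0 & rep6$per_fold$ACC <= 1))
  expect_true(rep6$auc >= 0 && rep6$auc <= 1)
  # strong effect on 8 features separates well
  expect_gte(rep6$mean_ACC, 0.8)
  # determinism of the whole CV loop
  rep6b <- cross_validate(ds, rf_config(seed = 3), folds = 6, seed = 4)
  expect_identical(rep6$per_fold, rep6b$per_fold)
  expect_identical(rep6$importance, rep6b$importance)
})

test_that("pre-split oversampling is flagged as leakage-prone", {
  ds <- make_feature_dataset(n_min = 12, n_maj = 36, p = 5, shift = 2)
  rep_pre <- cross_validate(ds, rf_config(seed = 1), folds = 4,
                            oversample = "pre_split",
                            adasyn_cfg = adasyn_config(seed = 2), seed = 5)
  expect_true(rep_pre$leakage_flag)
  # balanced pre-split: more rows evaluated than records
  expect_equal(sum(with(rep_pre$per_fold, TP + TN + FP + FN)), 72)
  rep_no <- cross_validate(ds, rf_config(seed = 1), folds = 4,
                           oversample = "none", seed = 5)
  expect_false(rep_no$leakage_flag)
  expect_equal(sum(with(rep_no$per_fold, TP + TN + FP + FN)), 48)
})

test_that("stratified folds require enough records per class", {
  ds <- make_feature_dataset(n_min = 4, n_maj = 30)
  expect_error(cross_validate(ds, rf_config(), folds = 6, seed = 1),
               "stratified")
})
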