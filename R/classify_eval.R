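# Random-forest classification under stratified six-fold cross-validation
# with vote-fraction scores, confusion-matrix metrics, pooled-score ROC/AUC
# and out-of-bag permutation feature importance. The forest itself is
# `ranger`; metric and ROC computation is in-package and cross-checked
# against pROC in the test suite.

#' Random-forest configuration
#'
#' Defaults replicate the study setting: 89 trees, depth limit 20, and at
#' most 29 candidate features per split (which with 31 features nearly
#' disables split-level feature subsampling; kept for fidelity).
#'
#' @param n_trees Number of trees.
#' @param max_depth Depth limit per tree.
#' @param max_features_per_split Candidate features drawn at each split.
#' @param seed Integer seed.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 89L, max_depth = 20L,
                      max_features_per_split = 29L, seed = 1L) {
  stopifnot(n_trees >= 1L, max_depth >= 1L, max_features_per_split >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 max_features_per_split = as.integer(max_features_per_split),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Train a random forest
#'
#' Majority-vote ensemble of depth-bounded trees with bootstrap
#' resampling; out-of-bag permutation importance and in-bag memberships
#' are recorded at training time. Deterministic given the seed.
#'
#' @param features Numeric matrix, rows = samples.
#' @param outcome Factor with both classes present (positive class
#'   `"PRETERM"` in the intended use).
#' @param cfg An [rf_config()].
#' @return List of class `ehg_forest` with elements `fit` (ranger object),
#'   `levels`, `positive`.
#' @export
train_rf <- function(features, outcome, cfg = rf_config()) {
  outcome <- droplevels(as.factor(outcome))
  if (nlevels(outcome) < 2L) stop("train_rf: single-class training set")
  df <- data.frame(.y = outcome, features, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = cfg$n_trees, max.depth = cfg$max_depth,
    mtry = min(cfg$max_features_per_split, ncol(features)),
    importance = "permutation", scale.permutation.importance = TRUE,
    keep.inbag = TRUE, seed = cfg$seed, num.threads = 1L)
  pos <- if ("PRETERM" %in% levels(outcome)) "PRETERM" else levels(outcome)[2]
  structure(list(fit = fit, levels = levels(outcome), positive = pos),
            class = "ehg_forest")
}

#' Vote-fraction scores and class predictions
#'
#' @param forest An `ehg_forest` from [train_rf()].
#' @param features Numeric matrix to score.
#' @return List with `score` (fraction of trees voting for the positive
#'   class) and `label` (majority-vote factor).
#' @export
predict_rf <- function(forest, features) {
  df <- data.frame(features, check.names = FALSE)
  pr <- stats::predict(forest$fit, data = df, predict.all = TRUE,
                       num.threads = 1L)$predictions
  pos_idx <- match(forest$positive, forest$levels)
  score <- rowMeans(pr == pos_idx)
  label <- factor(ifelse(score > 0.5, forest$positive,
                         setdiff(forest$levels, forest$positive)[1]),
                  levels = forest$levels)
  list(score = score, label = label)
}

#' Out-of-bag permutation feature importance, as percentages
#'
#' Per-feature accuracy drop when the feature is permuted on each tree's
#' out-of-bag samples (recorded during [train_rf()]; scaled by its
#' standard error across trees, the classic z-score form), clipped at
#' zero and normalized to sum to 100.
#'
#' @param forest An `ehg_forest`.
#' @return Named numeric vector summing to 100.
#' @export
rank_importance <- function(forest) {
  imp <- forest$fit$variable.importance
  if (is.null(imp)) stop("forest trained without importance recording")
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) return(imp)
  100 * imp / sum(imp)
}

#' Confusion-matrix classification metrics
#'
#' PRETERM is the positive class: sensitivity is the preterm detection
#' rate, specificity the term recognition rate.
#'
#' @param truth,pred Factors with the same levels.
#' @param positive Positive-class label.
#' @return List with `TP`, `FP`, `TN`, `FN`, `ACC`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(truth, pred, positive = "PRETERM") {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       ACC = (tp + tn) / length(truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NaN)
}

#' ROC curve and trapezoidal AUC from scores
#'
#' Sweeps all score thresholds and returns (FPR, TPR) points plus the
#' trapezoidal area. Equivalent to the rank statistic
#' `U / (n_pos * n_neg)` of the scores (an identity checked in the test
#' suite).
#'
#' @param truth Factor or character vector.
#' @param score Numeric scores, higher = more positive.
#' @param positive Positive-class label.
#' @return List with `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(truth, score, positive = "PRETERM") {
  is_pos <- truth == positive
  npos <- sum(is_pos); nneg <- sum(!is_pos)
  if (npos == 0L || nneg == 0L) stop("roc_curve: need both classes")
  ord <- order(score, decreasing = TRUE)
  lab <- is_pos[ord]; sc <- score[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)   # one point per threshold
  tpr <- c(0, tp[keep] / npos)
  fpr <- c(0, fp[keep] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

stratified_folds <- function(outcome, folds, seed) {
  set.seed(seed)
  fold <- integer(length(outcome))
  for (lv in levels(outcome)) {
    idx <- which(outcome == lv)
    if (length(idx) < folds) {
      stop("need >= ", folds, " records of class ", lv,
           " for stratified splitting")
    }
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validated random-forest evaluation
#'
#' Partitions the records into stratified folds, optionally ADASYN-balances
#' the training portion of each fold (`oversample = "within_fold"`, the
#' default, so no synthetic row ever reaches a test fold), trains a forest
#' per fold and evaluates on the held-out records. The report carries
#' per-fold and mean ACC/sensitivity/specificity, the ROC from pooled
#' out-of-fold vote fractions with its trapezoidal AUC, the mean of
#' per-fold AUCs, and the across-fold mean OOB permutation importance as
#' percentages. `oversample = "pre_split"` balances once before splitting
#' (synthetic rows then also appear in test folds; the report flags this
#' leakage-prone ordering), `"none"` disables balancing.
#'
#' @param data A [labeled_dataset()] for one contrast.
#' @param rf_cfg An [rf_config()].
#' @param folds Number of folds (default 6).
#' @param oversample `"within_fold"`, `"pre_split"` or `"none"`.
#' @param adasyn_cfg An [adasyn_config()].
#' @param seed Seed for fold assignment (per-fold forests derive their
#'   seeds from it).
#' @return List of class `cv_report`.
#' @export
cross_validate <- function(data, rf_cfg = rf_config(), folds = 6L,
                           oversample = c("within_fold", "pre_split", "none"),
                           adasyn_cfg = adasyn_config(), seed = 1L) {
  oversample <- match.arg(oversample)
  X <- data$features; y <- droplevels(data$outcome)
  is_synth <- rep(FALSE, nrow(X))
  if (oversample == "pre_split") {
    bal <- adasyn_oversample(data, adasyn_cfg)
    X <- bal$features; y <- droplevels(bal$outcome)
    is_synth <- bal$is_synthetic
  }
  fold <- stratified_folds(y, folds, seed)
  per_fold <- vector("list", folds)
  pooled_truth <- character(0); pooled_score <- numeric(0)
  imp <- matrix(0, folds, ncol(X), dimnames = list(NULL, colnames(X)))
  fold_auc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (oversample == "within_fold") {
      sub <- labeled_dataset(Xtr, data$group[tr], data$record_id[tr])
      cfg_f <- adasyn_cfg; cfg_f$seed <- adasyn_cfg$seed + f
      bal <- adasyn_oversample(sub, cfg_f)
      Xtr <- bal$features; ytr <- droplevels(bal$outcome)
    }
    cfg_rf <- rf_cfg; cfg_rf$seed <- rf_cfg$seed + f
    forest <- train_rf(Xtr, ytr, cfg_rf)
    pr <- predict_rf(forest, X[te, , drop = FALSE])
    if (nlevels(droplevels(y[te])) < 2L) {
      stop("fold ", f, " has a single class at evaluation")
    }
    m <- confusion_metrics(y[te], pr$label)
    per_fold[[f]] <- data.frame(fold = f, ACC = m$ACC,
                                sensitivity = m$sensitivity,
                                specificity = m$specificity,
                                TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN)
    fold_auc[f] <- roc_curve(y[te], pr$score)$auc
    pooled_truth <- c(pooled_truth, as.character(y[te]))
    pooled_score <- c(pooled_score, pr$score)
    imp[f, ] <- rank_importance(forest)
  }
  per_fold <- do.call(rbind, per_fold)
  roc <- roc_curve(pooled_truth, pooled_score)
  imp_mean <- colMeans(imp)
  imp_mean <- if (sum(imp_mean) > 0) 100 * imp_mean / sum(imp_mean) else imp_mean
  structure(list(
    per_fold = per_fold,
    mean_ACC = mean(per_fold$ACC),
    mean_sensitivity = mean(per_fold$sensitivity),
    mean_specificity = mean(per_fold$specificity),
    roc = roc[c("fpr", "tpr")],
    auc = roc$auc,
    auc_fold_mean = mean(fold_auc),
    importance = sort(imp_mean, decreasing = TRUE),
    oversample = oversample,
    leakage_flag = oversample == "pre_split",
    folds = folds, seed = seed,
    rf_cfg = rf_cfg, adasyn_cfg = adasyn_cfg),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d-fold, ACC %.3f, sens %.3f, spec %.3f, AUC %.3f (pooled) / %.3f (fold mean)>\n",
              x$folds, x$mean_ACC, x$mean_sensitivity, x$mean_specificity,
              x$auc, x$auc_fold_mean))
  if (x$leakage_flag) cat("  [pre-split oversampling: synthetic rows in test folds]\n")
  invisible(x)
}

#' Write a CV report to disk
#'
#' Writes `<stem>.json` (full report), `<stem>_folds.tsv`,
#' `<stem>_importance.tsv` and `<stem>_roc.csv`.
#'
#' @param report A `cv_report`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_cv_report <- function(report, stem) {
  jsonlite::write_json(list(
    mean_ACC = report$mean_ACC,
    mean_sensitivity = report$mean_sensitivity,
    mean_specificity = report$mean_specificity,
    auc_pooled = report$auc,
    auc_fold_mean = report$auc_fold_mean,
    per_fold = report$per_fold,
    importance = as.list(report$importance),
    oversample = report$oversample,
    leakage_flag = report$leakage_flag,
    folds = report$folds, seed = report$seed,
    rf_cfg = unclass(report$rf_cfg),
    adasyn_cfg = unclass(report$adasyn_cfg)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(report$per_fold, paste0(stem, "_folds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(feature = names(report$importance),
               importance_pct = as.numeric(report$importance)),
    paste0(stem, "_importance.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(fpr = report$roc$fpr, tpr = report$roc$tpr),
    paste0(stem, "_roc.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  invisible(stem)
}
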