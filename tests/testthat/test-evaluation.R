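# Confusion metrics against a hand oracle, rank-based AUC against the
# brute-force pair-counting oracle (and pROC), and the stratified
# cross-validation protocol.

test_that("confusion counts cross-tabulate with class 1 as positive", {
  expect_equal(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1)),
               tibble::tibble(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)
  expect_error(confusion_counts(c(1, 0), 1), "length mismatch")
})

test_that("metric formulas match the hand-evaluated oracle on random tables", {
  m <- classification_metrics(tibble::tibble(tp = 45, fn = 5, tn = 40, fp = 10))
  expect_equal(m$acc, 85)
  expect_equal(m$sen, 90)
  expect_equal(m$spec, 80)
  expect_equal(m$pr, 900 / 11)          # 81.8181..%
  expect_equal(m$mcc, 1750 / sqrt(50 * 55 * 50 * 45))  # 0.7035...

  set.seed(20)
  for (rep in 1:50) {
    tp <- sample(0:40, 1); fp <- sample(0:40, 1)
    tn <- sample(0:40, 1); fn <- sample(0:40, 1)
    if (tp + fp + tn + fn == 0) tp <- 1
    got <- classification_metrics(tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn))
    want <- oracle_metrics(tp, fp, tn, fn)
    expect_equal(got$acc, want$acc)
    expect_equal(got$sen, want$sen)
    expect_equal(got$spec, want$spec)
    expect_equal(got$pr, want$pr)
    expect_equal(got$mcc, want$mcc)
    expect_equal(got$mcc_pct, 100 * want$mcc)
  }
})

test_that("perfect and degenerate confusion tables hit the documented contracts", {
  perfect <- classification_metrics(tibble::tibble(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(unlist(perfect[, c("acc", "sen", "spec", "pr")]),
               c(acc = 100, sen = 100, spec = 100, pr = 100))
  expect_equal(perfect$mcc, 1)

  degen <- classification_metrics(tibble::tibble(tp = 0, fp = 0, tn = 50, fn = 50))
  expect_true(is.na(degen$pr))   # 0/0 precision: undefined, not silently 0
  expect_true(is.na(degen$mcc))
  expect_equal(degen$sen, 0)
})

test_that("ACC equals the sensitivity/specificity mixture identity on random counts", {
  set.seed(33)
  for (rep in 1:25) {
    tp <- sample(1:30, 1); fn <- sample(1:30, 1)
    tn <- sample(1:30, 1); fp <- sample(1:30, 1)
    m <- classification_metrics(tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn))
    p <- tp + fn; n <- tn + fp
    expect_equal(m$acc, (m$sen * p + m$spec * n) / (p + n))
  }
})

test_that("rank AUC equals the brute-force pair-counting oracle and pROC", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(60)
  y <- sample(c(0L, 1L), 200, replace = TRUE, prob = c(0.5, 0.5))
  y[1:2] <- c(0L, 1L)
  s <- round(runif(200), 2)  # rounding forces ties
  got <- roc_auc(y, s)
  expect_equal(got$auc, pairwise_auc(y, s), tolerance = 1e-12)
  expect_equal(got$auc, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                       direction = "<"))))
})

test_that("rank AUC equals trapezoidal integration of the ROC point list", {
  set.seed(61)
  for (rep in 1:5) {
    y <- sample(c(0L, 1L), 100, replace = TRUE)
    y[1:2] <- c(0L, 1L)
    s <- round(runif(100), 1)
    got <- roc_auc(y, s)
    roc <- got$roc
    trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
    expect_equal(got$auc, trap, tolerance = 1e-12)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  }
})

test_that("metrics are invariant to sample order", {
  set.seed(70)
  y <- sample(c(0L, 1L), 80, replace = TRUE); y[1:2] <- c(0L, 1L)
  p <- sample(c(0L, 1L), 80, replace = TRUE)
  s <- runif(80)
  perm <- sample(80)
  expect_equal(classification_metrics(confusion_counts(y, p)),
               classification_metrics(confusion_counts(y[perm], p[perm])))
  expect_equal(roc_auc(y, s)$auc, roc_auc(y[perm], s[perm])$auc)
})

test_that("stratified five-fold CV tests each sample once and balances classes", {
  d <- separable_features(n = 100, p = 4, seed = 44)
  cv <- cv_rotation_forest(d, k = 5, trees = 3, subsets = 2, seed = 10)
  expect_equal(nrow(cv$folds), 5)
  expect_setequal(cv$predictions$row, 1:100)
  expect_equal(unname(table(cv$predictions$fold)), rep(20L, 5), ignore_attr = TRUE)
  # stratification: each fold holds 10 of each class
  by_fold <- table(cv$predictions$fold, cv$predictions$label)
  expect_true(all(by_fold == 10))
  # a perfectly separable task is solved in every fold
  expect_equal(cv$folds$acc, rep(100, 5))
  expect_equal(cv$folds$auc, rep(1, 5))
})

test_that("cross-validation is reproducible under a fixed seed", {
  d <- separable_features(n = 40, p = 4, seed = 45)
  cv1 <- cv_rotation_forest(d, k = 4, trees = 2, subsets = 2, seed = 8)
  cv2 <- cv_rotation_forest(d, k = 4, trees = 2, subsets = 2, seed = 8)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$predictions, cv2$predictions)
})

test_that("summary rows are across-fold means with n-1 standard deviations", {
  d <- separable_features(n = 60, p = 4, seed = 46)
  d$d0001 <- rnorm(60)  # remove separability so folds vary
  cv <- cv_rotation_forest(d, k = 3, trees = 2, subsets = 2, seed = 9)
  acc_row <- cv$summary[cv$summary$metric == "acc", ]
  expect_equal(acc_row$mean, mean(cv$folds$acc))
  expect_equal(acc_row$sd, stats::sd(cv$folds$acc))
  gl <- glance(cv)
  expect_equal(gl$acc_mean, mean(cv$folds$acc))
  expect_equal(tidy(cv), cv$folds)
})

test_that("autoplot draws one ROC step curve per fold", {
  d <- separable_features(n = 40, p = 4, seed = 47)
  cv <- cv_rotation_forest(d, k = 2, trees = 2, subsets = 2, seed = 3)
  plt <- autoplot(cv)
  expect_s3_class(plt, "ggplot")
  built <- ggplot2::ggplot_build(plt)
  expect_gte(length(built$data), 2)
})
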