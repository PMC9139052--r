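# Evaluation: confusion counts, the five classification metrics
# (ACC, Sen, Spec, PR, MCC), rank-based ROC/AUC, and the stratified
# five-fold cross-validation protocol with per-fold and mean +/- sd
# reporting.

#' Confusion counts for binary predictions
#'
#' Class 1 is the positive (interacting) class. TP: true pairs predicted
#' interacting; FP: non-interacting pairs predicted interacting; TN:
#' non-interacting pairs correctly rejected; FN: true pairs missed.
#'
#' @param y_true,y_pred Equal-length vectors of labels in \{0, 1\}.
#' @return One-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    rlang::abort(sprintf("length mismatch: %d true labels vs %d predictions",
                         length(y_true), length(y_pred)))
  }
  if (length(y_true) < 1L) rlang::abort("need at least one sample")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    rlang::abort("labels must be 0 or 1")
  }
  tibble::tibble(
    tp = sum(y_true == 1L & y_pred == 1L),
    fp = sum(y_true == 0L & y_pred == 1L),
    tn = sum(y_true == 0L & y_pred == 0L),
    fn = sum(y_true == 1L & y_pred == 0L))
}

# 0/0 ratios are undefined and reported as NA, never silently 0.
safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, and precision as
#' percentages; the Matthews correlation coefficient on its natural
#' \[-1, 1\] scale (`mcc`) and, following the percent convention common in
#' PPI benchmark tables, multiplied by 100 (`mcc_pct`). The MCC denominator
#' is `sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`. Any metric whose denominator is
#' zero is `NA`.
#'
#' @param counts One-row tibble from [confusion_counts()] (or anything with
#'   `tp`, `fp`, `tn`, `fn` columns).
#' @return One-row tibble with columns `acc`, `sen`, `spec`, `pr` (all
#'   percent), `mcc`, `mcc_pct`.
#' @export
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1)))
classification_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)), nrow(counts) == 1L)
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  total <- tp + fp + tn + fn
  if (total < 1) rlang::abort("empty confusion table")
  mcc_den <- sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  tibble::tibble(
    acc = 100 * safe_ratio(tp + tn, total),
    sen = 100 * safe_ratio(tp, tp + fn),
    spec = 100 * safe_ratio(tn, tn + fp),
    pr = 100 * safe_ratio(tp, tp + fp),
    mcc = safe_ratio(tp * tn - fp * fn, mcc_den),
    mcc_pct = 100 * safe_ratio(tp * tn - fp * fn, mcc_den))
}

#' ROC curve and AUC by the rank method
#'
#' AUC is the probability that a randomly chosen positive outscores a
#' randomly chosen negative, computed from midranks (ties contribute 1/2),
#' which equals trapezoidal integration of the ROC curve.
#'
#' @param y_true Labels in \{0, 1\}; both classes must be present.
#' @param scores Numeric confidence for class 1, same length.
#' @return List with `auc` (scalar in \[0, 1\]) and `roc`, a tibble of
#'   `(fpr, tpr, threshold)` points from (0, 0) to (1, 1) at every distinct
#'   score threshold.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0L, 1L)),
            all(is.finite(scores)))
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    rlang::abort("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thresholds <- sort(unique(scores), decreasing = TRUE)
  roc <- purrr::map_dfr(thresholds, function(th) {
    pos <- scores >= th
    tibble::tibble(fpr = sum(pos & y_true == 0L) / n0,
                   tpr = sum(pos & y_true == 1L) / n1,
                   threshold = th)
  })
  roc <- dplyr::bind_rows(tibble::tibble(fpr = 0, tpr = 0, threshold = Inf), roc)
  list(auc = auc, roc = roc)
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin into k folds, so fold class proportions match the data.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation of a Rotation Forest
#'
#' Samples are split into `k` class-stratified folds; each fold is held out
#' once while a [rotation_forest()] is trained on the rest, and the five
#' classification metrics plus AUC are computed on the held-out fold. The
#' summary reports the across-fold mean and sample standard deviation
#' (n - 1 denominator) per metric.
#'
#' @param data Data frame with feature columns and the outcome.
#' @param k Number of folds (default 5).
#' @param outcome,features,trees,subsets,bootstrap_frac Passed to
#'   [rotation_forest()].
#' @param seed Integer seed; controls the fold split and, via per-fold
#'   derived seeds, every model fit.
#' @return A `ppi_cv` object: `folds` (per-fold metric tibble), `summary`
#'   (mean/sd per metric), `roc` (per-fold ROC points), `predictions`
#'   (held-out score and label per sample), and the configuration.
#' @export
cv_rotation_forest <- function(data, k = 5, outcome = "label", features = NULL,
                               trees = 30, subsets = 20, bootstrap_frac = 0.75,
                               seed = 1L) {
  stopifnot(is.data.frame(data), k >= 2, nrow(data) >= k)
  if (!outcome %in% names(data)) {
    rlang::abort(sprintf("outcome column '%s' not found; cross-validation needs labels", outcome))
  }
  y <- as.integer(data[[outcome]])
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) != 2L) {
    rlang::abort("outcome must contain both classes, coded 0/1")
  }

  set.seed(seed)
  fold_of <- stratified_folds(y, k)
  # independent per-fold seeds so each fold's fit is reproducible in isolation
  fold_seeds <- sample.int(.Machine$integer.max, k)

  fold_results <- purrr::map(seq_len(k), function(fold) {
    test_idx <- which(fold_of == fold)
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    fit <- rotation_forest(train, outcome = outcome, features = features,
                           trees = trees, subsets = subsets,
                           bootstrap_frac = bootstrap_frac,
                           seed = fold_seeds[[fold]])
    conf <- predict_confidence(fit, test)
    score1 <- conf[, "1"]
    pred <- fit$classes[apply(conf, 1L, which.max)]
    counts <- confusion_counts(y[test_idx], pred)
    roc <- roc_auc(y[test_idx], score1)
    list(metrics = dplyr::bind_cols(tibble::tibble(fold = fold), counts,
                                    classification_metrics(counts),
                                    tibble::tibble(auc = roc$auc)),
         roc = dplyr::mutate(roc$roc, fold = fold, .before = 1L),
         predictions = tibble::tibble(fold = fold, row = test_idx,
                                      label = y[test_idx], score = score1,
                                      predicted = pred))
  })

  folds <- purrr::map_dfr(fold_results, "metrics")
  metric_cols <- c("acc", "sen", "spec", "pr", "mcc", "mcc_pct", "auc")
  summary <- tidyr::pivot_longer(folds[, c("fold", metric_cols)],
                                 -"fold", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value)) |>
    dplyr::arrange(match(.data$metric, metric_cols))

  structure(
    list(folds = folds,
         summary = summary,
         roc = purrr::map_dfr(fold_results, "roc"),
         predictions = purrr::map_dfr(fold_results, "predictions"),
         config = list(k = k, trees = trees, subsets = subsets,
                       bootstrap_frac = bootstrap_frac, seed = seed,
                       n = nrow(data))),
    class = "ppi_cv")
}

#' @export
print.ppi_cv <- function(x, ...) {
  cat(sprintf("<ppi_cv> %d-fold cross-validation, n = %d, %d trees, seed %s\n",
              x$config$k, x$config$n, x$config$trees, x$config$seed))
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  cat(sprintf("  ACC %.2f +/- %.2f%%  Sen %.2f%%  Spec %.2f%%  PR %.2f%%  MCC %.2f%%  AUC %.4f\n",
              wide$mean_acc, wide$sd_acc, wide$mean_sen, wide$mean_spec,
              wide$mean_pr, wide$mean_mcc_pct, wide$mean_auc))
  invisible(x)
}

#' Per-fold metrics of a cross-validation run
#'
#' @param x A [cv_rotation_forest()] result.
#' @param ... Unused.
#' @return Tibble of per-fold confusion counts and metrics.
#' @method tidy ppi_cv
#' @export
tidy.ppi_cv <- function(x, ...) x$folds

#' One-row cross-validation summary
#'
#' @param x A [cv_rotation_forest()] result.
#' @param ... Unused.
#' @return One-row tibble of across-fold means and standard deviations per
#'   metric.
#' @method glance ppi_cv
#' @export
glance.ppi_cv <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"), names_glue = "{metric}_{.value}")
}

#' ROC curves of a cross-validation run
#'
#' One ROC curve per held-out fold, with the fold AUC in the legend.
#'
#' @param object A [cv_rotation_forest()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppi_cv
#' @export
autoplot.ppi_cv <- function(object, ...) {
  auc_lab <- sprintf("fold %d (AUC %.3f)", object$folds$fold, object$folds$auc)
  roc <- dplyr::mutate(object$roc, curve = auc_lab[.data$fold])
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$curve)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL,
                  title = sprintf("%d-fold cross-validated ROC", object$config$k)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
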