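# End-to-end orchestration: pair featurization, feature-table IO, the
# cross-validation report writer, and prediction tables. Every artifact
# written here embeds the seed and a hash of the run configuration so runs
# are auditable and byte-reproducible.

#' Featurize a list of protein pairs
#'
#' Computes the [pair_descriptor()] for every row of a pair table, looking
#' the two PSSMs up by id.
#'
#' @param pairs Tibble with columns `id_a`, `id_b` and optionally `label`
#'   (see [read_pair_table()]).
#' @param pssms Named list of [new_pssm()] objects covering every id in
#'   `pairs`.
#' @param pad_len,block_rows Passed to [pair_descriptor()].
#' @return Tibble, one row per pair in input order: `id_a`, `id_b`,
#'   `label` (if present), then feature columns `d0001`..`d0400` (at the
#'   defaults).
#' @export
extract_features <- function(pairs, pssms, pad_len = 512, block_rows = 10) {
  stopifnot(is.data.frame(pairs), all(c("id_a", "id_b") %in% names(pairs)))
  if (nrow(pairs) == 0L) rlang::abort("empty pair list")
  needed <- unique(c(pairs$id_a, pairs$id_b))
  missing <- setdiff(needed, names(pssms))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("no PSSM for id '%s' (%d ids missing in total)",
                         missing[[1L]], length(missing)))
  }
  feats <- purrr::map2(pairs$id_a, pairs$id_b, function(a, b) {
    pair_descriptor(pssms[[a]], pssms[[b]], pad_len, block_rows)
  })
  fmat <- do.call(rbind, feats)
  keep <- intersect(c("id_a", "id_b", "label"), names(pairs))
  dplyr::bind_cols(pairs[, keep, drop = FALSE], tibble::as_tibble(fmat))
}

# 32-bit polynomial rolling hash of a string, reported as 8 hex digits;
# used to stamp output artifacts with their configuration. Kept in doubles
# (exact below 2^53) since R's bitwise ops are 31-bit.
config_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

config_stamp <- function(config) {
  kv <- paste(names(config), vapply(config, function(v) paste(format(v), collapse = ","),
                                    character(1)),
              sep = "=", collapse = " ")
  sprintf("# dhtppi config_hash=%s seed=%s %s",
          config_hash(kv), config$seed %||% "NA", kv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a feature table
#'
#' Tab-separated feature table with a leading comment line embedding the
#' seed and a hash of the descriptor configuration; full-precision numeric
#' formatting so rewriting is byte-stable.
#'
#' @param features Tibble from [extract_features()].
#' @param path Output path.
#' @param config Named list recorded in the header stamp (should include
#'   `seed`).
#' @return `write_feature_table()`: `path`, invisibly;
#'   `read_feature_table()`: the feature tibble.
#' @export
write_feature_table <- function(features, path, config = list()) {
  stamp <- config_stamp(config)
  num <- vapply(features, is.numeric, logical(1)) &
    !vapply(features, is.integer, logical(1))
  out <- features
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  tibble::as_tibble(df)
}

#' Write a cross-validation report
#'
#' Mirrors the fold-table layout of PPI benchmark papers: one row per fold
#' with ACC/Sen/Spec/PR/MCC as percentages and AUC as a fraction, plus an
#' `Average` row formatted `mean ± sd`. ROC points are written alongside
#' for replotting. Both files carry the config/seed stamp.
#'
#' @param cv A [cv_rotation_forest()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`report`, `roc`).
#' @export
write_cv_report <- function(cv, dir) {
  stopifnot(inherits(cv, "ppi_cv"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- config_stamp(cv$config)

  fmt <- function(x, d = 2) formatC(x, digits = d, format = "f")
  folds <- cv$folds
  rows <- data.frame(
    Fold = as.character(folds$fold),
    `ACC (%)` = fmt(folds$acc), `Sen. (%)` = fmt(folds$sen),
    `Spec. (%)` = fmt(folds$spec), `PR (%)` = fmt(folds$pr),
    `MCC (%)` = fmt(folds$mcc_pct), AUC = fmt(folds$auc, 4),
    check.names = FALSE)
  s <- tidyr::pivot_wider(cv$summary, names_from = "metric",
                          values_from = c("mean", "sd"))
  avg <- data.frame(
    Fold = "Average",
    `ACC (%)` = sprintf("%s ± %s", fmt(s$mean_acc), fmt(s$sd_acc)),
    `Sen. (%)` = sprintf("%s ± %s", fmt(s$mean_sen), fmt(s$sd_sen)),
    `Spec. (%)` = sprintf("%s ± %s", fmt(s$mean_spec), fmt(s$sd_spec)),
    `PR (%)` = sprintf("%s ± %s", fmt(s$mean_pr), fmt(s$sd_pr)),
    `MCC (%)` = sprintf("%s ± %s", fmt(s$mean_mcc_pct), fmt(s$sd_mcc_pct)),
    AUC = sprintf("%s ± %s", fmt(s$mean_auc, 4), fmt(s$sd_auc, 4)),
    check.names = FALSE)

  report_path <- file.path(dir, "cv_report.tsv")
  con <- file(report_path, "w")
  writeLines(stamp, con)
  utils::write.table(rbind(rows, avg), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  roc_path <- file.path(dir, "roc_points.tsv")
  con <- file(roc_path, "w")
  writeLines(stamp, con)
  roc <- cv$roc
  roc$threshold <- sprintf("%.17g", roc$threshold)
  roc$fpr <- sprintf("%.17g", roc$fpr)
  roc$tpr <- sprintf("%.17g", roc$tpr)
  utils::write.table(roc, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  invisible(list(report = report_path, roc = roc_path))
}

#' Per-pair prediction table
#'
#' Applies a trained [rotation_forest()] to a feature table and returns the
#' predicted label with the class-1 (interacting) confidence from the mean
#' combination rule.
#'
#' @param model A [rotation_forest()] fit.
#' @param features Tibble from [extract_features()] (id columns optional).
#' @return Tibble with any id columns of the input plus `predicted` and
#'   `confidence_1`.
#' @export
predict_pairs <- function(model, features) {
  conf <- predict_confidence(model, features)
  pred <- model$classes[apply(conf, 1L, which.max)]
  keep <- intersect(c("id_a", "id_b", "label"), names(features))
  dplyr::bind_cols(features[, keep, drop = FALSE],
                   tibble::tibble(predicted = pred, confidence_1 = conf[, "1"]))
}
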