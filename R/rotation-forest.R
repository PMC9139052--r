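# Rotation Forest, implemented from scratch.
#
# Each of the L ensemble members gets its own random partition of the
# feature set into K subsets; per subset, PCA is fitted on a 75% bootstrap
# of the training rows restricted to that subset's columns, all principal
# components are retained, and the per-subset loadings are assembled into a
# block-diagonal n x n rotation matrix (rearranged to the original feature
# order). A CART decision tree is trained on the rotated data; prediction
# averages the trees' class posteriors (mean combination).

#' Randomly partition features into K subsets
#'
#' A random permutation of `1..n` is cut into `K` consecutive chunks of
#' size `floor(n / K)`; the last chunk absorbs any remainder. Chunks are
#' pairwise disjoint and jointly cover all features.
#'
#' @param n Number of features.
#' @param k Number of subsets, `1 <= k <= n`.
#' @return List of `k` integer index vectors.
#' @export
partition_features <- function(n, k) {
  stopifnot(n >= 1)
  if (k < 1 || k > n) rlang::abort(sprintf("`k` must be in [1, %d], got %s", n, k))
  perm <- sample.int(n)
  u <- n %/% k
  starts <- (seq_len(k) - 1L) * u + 1L
  ends <- c(starts[-1L] - 1L, n)
  purrr::map2(starts, ends, ~ perm[.x:.y])
}

# Orthonormal PCA basis of the columns of x (samples x p), all p components
# retained. Eigendecomposition of the sample covariance, so a full basis is
# returned even when some directions are degenerate (zero variance); if the
# whole block is constant the identity is substituted with a message. Sign
# convention: each component's largest-magnitude loading is positive.
pca_basis <- function(x) {
  p <- ncol(x)
  cv <- stats::cov(x)
  if (!all(is.finite(cv)) || max(abs(cv)) < .Machine$double.eps) {
    message(sprintf("degenerate (zero-variance) feature block of size %d: identity basis substituted", p))
    return(diag(p))
  }
  vec <- eigen(cv, symmetric = TRUE)$vectors
  for (j in seq_len(p)) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  vec
}

#' Fit one block-diagonal rotation matrix
#'
#' For each feature subset, `ceiling(bootstrap_frac * N)` training rows are
#' drawn with replacement (`bootstrap_frac = 1` means every row once,
#' unresampled), PCA is run on those rows restricted to the subset's
#' columns, and all components are kept. The per-subset loading blocks are
#' placed on the diagonal and rearranged to original feature order, so
#' `X %*% R` rotates each subset within its own subspace and
#' `t(R) %*% R` is the identity.
#'
#' @param x Numeric sample matrix (rows: samples, columns: features).
#' @param partition Feature partition from [partition_features()].
#' @param bootstrap_frac Fraction of rows in each per-subset bootstrap
#'   (default 0.75).
#' @return An `n x n` rotation matrix.
#' @export
fit_rotation <- function(x, partition, bootstrap_frac = 0.75) {
  stopifnot(is.matrix(x), is.numeric(x), is.list(partition))
  if (bootstrap_frac <= 0 || bootstrap_frac > 1) {
    rlang::abort("`bootstrap_frac` must be in (0, 1]")
  }
  n <- ncol(x)
  n_samp <- nrow(x)
  rot <- matrix(0, n, n)
  for (idx in partition) {
    rows <- if (bootstrap_frac == 1) {
      seq_len(n_samp)
    } else {
      sample.int(n_samp, size = ceiling(bootstrap_frac * n_samp), replace = TRUE)
    }
    rot[idx, idx] <- pca_basis(x[rows, idx, drop = FALSE])
  }
  rot
}

#' Fit a Rotation Forest classifier
#'
#' Tidyverse-friendly front end: takes a data frame whose feature columns
#' match `d[0-9]+` (or are given explicitly) plus a binary outcome column,
#' and fits `trees` independent (partition, rotation, CART tree) triples.
#'
#' @param data Data frame of features and the outcome.
#' @param outcome Name of the binary outcome column (default `"label"`).
#'   Classes are the sorted unique values; the first listed class wins
#'   posterior ties.
#' @param features Character vector of feature column names; default: all
#'   columns matching `^d[0-9]+$`.
#' @param trees Ensemble size L (default 30).
#' @param subsets Number of feature subsets K per tree (default 20; must
#'   not exceed the number of features).
#' @param bootstrap_frac Per-subset bootstrap fraction (default 0.75).
#' @param seed Integer seed controlling partitions and bootstraps.
#' @return A `rotation_forest` object with elements `trees`, `rotations`,
#'   `partitions`, `classes`, `feature_names`, and the call configuration.
#' @export
#' @examples
#' d <- tibble::tibble(d0001 = c(rnorm(20, -2), rnorm(20, 2)),
#'                     d0002 = rnorm(40),
#'                     label = rep(c(0, 1), each = 20))
#' fit <- rotation_forest(d, trees = 3, subsets = 2, seed = 1)
#' predict(fit, d)[1:3]
rotation_forest <- function(data, outcome = "label", features = NULL,
                            trees = 30, subsets = 20, bootstrap_frac = 0.75,
                            seed = 1L) {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) {
    rlang::abort(sprintf("outcome column '%s' not found", outcome))
  }
  if (is.null(features)) {
    features <- grep("^d[0-9]+$", names(data), value = TRUE)
  }
  if (length(features) == 0L) rlang::abort("no feature columns found")
  x <- as.matrix(data[, features, drop = FALSE])
  storage.mode(x) <- "double"
  y <- data[[outcome]]
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    rlang::abort(sprintf("outcome must have exactly 2 classes, found %d",
                         length(classes)))
  }
  if (subsets > ncol(x)) {
    rlang::abort(sprintf("`subsets` (%d) cannot exceed the number of features (%d)",
                         subsets, ncol(x)))
  }
  stopifnot(trees >= 1)
  yf <- factor(y, levels = classes)

  set.seed(seed)
  members <- purrr::map(seq_len(trees), function(i) {
    part <- partition_features(ncol(x), subsets)
    rot <- fit_rotation(x, part, bootstrap_frac)
    xr <- x %*% rot
    colnames(xr) <- paste0("r", seq_len(ncol(xr)))
    df <- as.data.frame(xr)
    df$.y <- yf
    tree <- rpart::rpart(
      .y ~ ., data = df, method = "class",
      control = rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                     xval = 0, maxdepth = 30))
    list(partition = part, rotation = rot, tree = tree)
  })

  structure(
    list(trees = purrr::map(members, "tree"),
         rotations = purrr::map(members, "rotation"),
         partitions = purrr::map(members, "partition"),
         classes = classes,
         feature_names = features,
         config = list(trees = trees, subsets = subsets,
                       bootstrap_frac = bootstrap_frac, seed = seed)),
    class = "rotation_forest")
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat(sprintf(
    "<rotation_forest> %d trees, %d feature subsets, %d features, classes {%s}, seed %s\n",
    length(x$trees), x$config$subsets, length(x$feature_names),
    paste(x$classes, collapse = ", "), x$config$seed))
  invisible(x)
}

extract_feature_matrix <- function(model, newdata) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(model$feature_names, names(newdata))
    if (length(missing) > 0L) {
      rlang::abort(sprintf(
        "newdata has %d of the model's %d features; missing e.g. %s",
        length(model$feature_names) - length(missing),
        length(model$feature_names), missing[[1L]]))
    }
    newdata <- as.matrix(newdata[, model$feature_names, drop = FALSE])
  }
  if (ncol(newdata) != length(model$feature_names)) {
    rlang::abort(sprintf("feature dimension mismatch: model expects %d, input has %d",
                         length(model$feature_names), ncol(newdata)))
  }
  storage.mode(newdata) <- "double"
  newdata
}

#' Class-confidence estimates from a Rotation Forest
#'
#' Mean combination: each tree scores the sample rotated by its own
#' rotation matrix, and the per-class posteriors are averaged over trees.
#' Every row is non-negative and sums to one.
#'
#' @param model A [rotation_forest()] fit.
#' @param newdata Data frame containing the model's feature columns, or a
#'   numeric matrix with matching column count.
#' @return Numeric matrix, one row per sample, one column per class (column
#'   names are the class labels).
#' @export
predict_confidence <- function(model, newdata) {
  stopifnot(inherits(model, "rotation_forest"))
  x <- extract_feature_matrix(model, newdata)
  acc <- matrix(0, nrow(x), 2L)
  for (i in seq_along(model$trees)) {
    xr <- x %*% model$rotations[[i]]
    colnames(xr) <- paste0("r", seq_len(ncol(xr)))
    acc <- acc + stats::predict(model$trees[[i]], as.data.frame(xr), type = "prob")
  }
  conf <- acc / length(model$trees)
  colnames(conf) <- as.character(model$classes)
  rownames(conf) <- NULL
  conf
}

#' Predict class labels with a Rotation Forest
#'
#' Assigns the class with the highest mean confidence; an exact 50/50 tie
#' goes to the first listed class (`model$classes[1]`).
#'
#' @param object A [rotation_forest()] fit.
#' @param newdata Data frame or matrix of features (see
#'   [predict_confidence()]).
#' @param type `"class"` (default) for hard labels, `"prob"` for the
#'   confidence matrix.
#' @param ... Unused.
#' @return Vector of class labels, or the confidence matrix.
#' @export
predict.rotation_forest <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  conf <- predict_confidence(object, newdata)
  if (type == "prob") return(conf)
  object$classes[apply(conf, 1L, which.max)]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-tree summary of a Rotation Forest
#'
#' @param x A [rotation_forest()] fit.
#' @param ... Unused.
#' @return Tibble with one row per ensemble member: tree index, number of
#'   leaves, and the rotation matrix's maximum orthonormality defect
#'   `max |R'R - I|`.
#' @method tidy rotation_forest
#' @export
tidy.rotation_forest <- function(x, ...) {
  tibble::tibble(
    tree = seq_along(x$trees),
    n_leaves = purrr::map_int(x$trees, ~ sum(.x$frame$var == "<leaf>")),
    rotation_defect = purrr::map_dbl(x$rotations, function(r) {
      max(abs(crossprod(r) - diag(ncol(r))))
    }))
}

#' One-row summary of a Rotation Forest
#'
#' @param x A [rotation_forest()] fit.
#' @param ... Unused.
#' @return One-row tibble: ensemble size, subsets, features, bootstrap
#'   fraction, seed.
#' @method glance rotation_forest
#' @export
glance.rotation_forest <- function(x, ...) {
  tibble::tibble(
    trees = length(x$trees),
    subsets = x$config$subsets,
    n_features = length(x$feature_names),
    bootstrap_frac = x$config$bootstrap_frac,
    seed = x$config$seed)
}

#' Save / load a Rotation Forest model
#'
#' Single-file persistence (RDS archive of rotations, tree structures,
#' classes and configuration including the seed). A loaded model produces
#' bit-identical predictions.
#'
#' @param model A [rotation_forest()] fit.
#' @param path File path.
#' @return `save_rotation_forest()`: `path`, invisibly;
#'   `load_rotation_forest()`: the model.
#' @export
save_rotation_forest <- function(model, path) {
  stopifnot(inherits(model, "rotation_forest"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_rotation_forest
#' @export
load_rotation_forest <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rotation_forest")) {
    rlang::abort(sprintf("%s does not contain a rotation_forest model", path))
  }
  model
}
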