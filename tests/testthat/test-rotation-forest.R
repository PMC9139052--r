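# Rotation Forest: feature partitioning, rotation-matrix orthonormality,
# the PCA oracle, mean-combination prediction, and persistence.

test_that("feature partitions are disjoint chunks covering all features", {
  set.seed(1)
  p <- partition_features(400, 20)
  expect_length(p, 20)
  expect_true(all(lengths(p) == 20))
  expect_setequal(unlist(p), 1:400)

  p2 <- partition_features(5, 2)
  expect_equal(sort(lengths(p2)), c(2L, 3L))
  expect_setequal(unlist(p2), 1:5)

  expect_equal(sort(partition_features(7, 1)[[1]]), 1:7)
  expect_error(partition_features(3, 4), "\\[1, 3\\]")
})

test_that("rotation matrices are orthonormal with all components retained", {
  set.seed(8)
  x <- matrix(rnorm(60 * 12), 60, 12)
  for (k in c(1, 3, 4)) {
    part <- partition_features(12, k)
    r <- fit_rotation(x, part)
    expect_lt(max(abs(crossprod(r) - diag(12))), 1e-9)
    # off-block entries are exactly zero
    for (gi in seq_along(part)) for (gj in seq_along(part)) {
      if (gi != gj) expect_true(all(r[part[[gi]], part[[gj]]] == 0))
    }
  }
  # single-feature groups give +/-1 blocks
  r1 <- fit_rotation(x[, 1:2], list(1L, 2L))
  expect_equal(abs(diag(r1)), c(1, 1))
})

test_that("identity partition with the full sample reproduces the principal axes", {
  set.seed(15)
  x <- matrix(rnorm(80 * 6), 80, 6) %*% diag(c(4, 3, 2, 1, 0.5, 0.2))
  r <- fit_rotation(x, list(1:6), bootstrap_frac = 1)
  oracle <- prcomp(x, center = TRUE, scale. = FALSE)$rotation
  for (j in 1:6) {
    # equal up to column sign
    expect_equal(min(max(abs(r[, j] - oracle[, j])),
                     max(abs(r[, j] + oracle[, j]))), 0, tolerance = 1e-8)
  }
})

test_that("degenerate zero-variance blocks fall back to an identity basis, never fail", {
  x <- cbind(matrix(rnorm(40), 20, 2), 0, 0)
  expect_message(r <- fit_rotation(x, list(1:2, 3:4), bootstrap_frac = 1),
                 "identity basis")
  expect_lt(max(abs(crossprod(r) - diag(4))), 1e-9)
  expect_equal(r[3:4, 3:4], diag(2))
})

test_that("rotation forest interpolates separable training data and is seed-deterministic", {
  d <- separable_features(n = 40, p = 4)
  fit <- rotation_forest(d, trees = 5, subsets = 2, seed = 3)
  expect_equal(predict(fit, d), d$label)

  fit2 <- rotation_forest(d, trees = 5, subsets = 2, seed = 3)
  newx <- separable_features(n = 30, p = 4, seed = 99)
  expect_identical(predict(fit, newx), predict(fit2, newx))
  expect_identical(predict_confidence(fit, newx), predict_confidence(fit2, newx))

  expect_error(rotation_forest(dplyr::mutate(d, label = 1L), trees = 2, subsets = 2),
               "2 classes")
  expect_error(rotation_forest(d, trees = 2, subsets = 99), "exceed")
})

test_that("a single-tree, single-subset forest equals one PCA-rotated tree", {
  d <- separable_features(n = 50, p = 3, seed = 12)
  fit <- rotation_forest(d, trees = 1, subsets = 1, bootstrap_frac = 1, seed = 5)

  # oracle: fit that simpler model directly (principal scores + one CART tree)
  x <- as.matrix(d[, 1:3])
  v <- prcomp(x, center = TRUE, scale. = FALSE)$rotation
  for (j in seq_len(ncol(v))) {  # same sign convention as the package
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  df <- as.data.frame(x %*% v)
  names(df) <- paste0("pc", seq_len(ncol(v)))
  df$.y <- factor(d$label)
  tree <- rpart::rpart(.y ~ ., df, method = "class",
                       control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                                      cp = 0, xval = 0))
  oracle_pred <- as.integer(as.character(predict(tree, df, type = "class")))
  expect_equal(predict(fit, d), oracle_pred)
})

test_that("mean-combination confidences are proper and drive argmax prediction", {
  d <- separable_features(n = 60, p = 5, seed = 2)
  fit <- rotation_forest(d, trees = 7, subsets = 2, seed = 9)
  newx <- separable_features(n = 100, p = 5, seed = 77)
  conf <- predict_confidence(fit, newx)
  expect_equal(unname(rowSums(conf)), rep(1, 100), tolerance = 1e-12)
  expect_true(all(conf >= 0))
  # recompute argmax independently, first class on ties
  expected <- fit$classes[ifelse(conf[, 1] >= conf[, 2], 1L, 2L)]
  expect_equal(predict(fit, newx), expected)
})

test_that("three hard votes of (1,0),(1,0),(0,1) average to confidence (2/3, 1/3)", {
  # arithmetic contract of the mean combination rule: assemble an ensemble
  # of deterministic hard-voting trees, two for class 0 and one for class 1
  make_tree <- function(labels) {
    df <- data.frame(r1 = c(-2, -1, 1, 2), .y = factor(labels, levels = 0:1))
    rpart::rpart(.y ~ ., df, method = "class",
                 control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                                cp = 0, xval = 0))
  }
  model <- structure(
    list(trees = list(make_tree(c(0, 0, 1, 1)), make_tree(c(0, 0, 1, 1)),
                      make_tree(c(1, 1, 0, 0))),
         rotations = rep(list(diag(1)), 3),
         partitions = rep(list(list(1L)), 3),
         classes = 0:1, feature_names = "d0001",
         config = list(trees = 3, subsets = 1, bootstrap_frac = 1, seed = 1)),
    class = "rotation_forest")
  conf <- predict_confidence(model, tibble::tibble(d0001 = -5))
  expect_equal(unname(conf[1, ]), c(2 / 3, 1 / 3))
  expect_equal(predict(model, tibble::tibble(d0001 = -5)), 0L)
  # unanimous ensemble equals any single tree's posterior
  model$trees[[3]] <- model$trees[[1]]
  expect_equal(unname(predict_confidence(model, tibble::tibble(d0001 = -5))[1, ]),
               c(1, 0))
})

test_that("models survive a save/load round-trip with bit-identical predictions", {
  d <- separable_features(n = 30, p = 4, seed = 4)
  fit <- rotation_forest(d, trees = 3, subsets = 2, seed = 11)
  f <- withr::local_tempfile(fileext = ".rds")
  save_rotation_forest(fit, f)
  reloaded <- load_rotation_forest(f)
  newx <- separable_features(n = 25, p = 4, seed = 13)
  expect_identical(predict_confidence(reloaded, newx), predict_confidence(fit, newx))
  expect_identical(predict(reloaded, newx), predict(fit, newx))
})

test_that("tidy and glance summarize the ensemble", {
  d <- separable_features(n = 30, p = 4, seed = 6)
  fit <- rotation_forest(d, trees = 4, subsets = 2, seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_true(all(td$rotation_defect < 1e-9))
  gl <- glance(fit)
  expect_equal(gl$trees, 4)
  expect_equal(gl$n_features, 4)
})
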