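test_that("rf importance isolates a determining feature and is reproducible", {
  set.seed(2)
  n <- 120
  X <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
                  f4 = rnorm(n))
  y <- as.integer(X$f1 > 0) + 1L
  res <- rf_importance(X, y, n_forests = 5, n_trees = 200, seed = 3)
  expect_equal(names(which.max(res$importance)), "f1")
  expect_true("f1" %in% res$prediction_set)
  expect_true(all(is.finite(res$importance)))
  # prediction set nests inside the interpretation set
  expect_true(all(res$prediction_set %in% res$interpretation_set))

  # pure-noise features stay inside the probe noise band
  expect_lt(max(res$importance[c("f2", "f3", "f4")]),
            max(res$importance["f1"]) / 10)

  # same seed, same sets
  res2 <- rf_importance(X, y, n_forests = 5, n_trees = 200, seed = 3)
  expect_identical(res$prediction_set, res2$prediction_set)
  expect_identical(res$importance, res2$importance)

  expect_error(rf_importance(X, rep(1, n), n_forests = 2, n_trees = 50),
               "constant")
})

test_that("across-k consolidation yields nested sets with recomputed thresholds", {
  feats <- paste0("f", 1:6)
  fake <- function(pred, imp) {
    structure(list(importance = setNames(imp, feats),
                   prediction_set = pred), class = "importance_result")
  }
  imp_by_k <- list(
    k2 = fake(c("f1", "f2"), c(5, 3, 0.1, 0.1, 0.1, 0.1)),
    k3 = fake(c("f1", "f2", "f3"), c(6, 2, 0.5, 0.1, 0.1, 0.1)),
    k4 = fake(c("f1", "f2"), c(4, 2.5, 0.2, 0.1, 0.1, 0.1)),
    k5 = fake(c("f1"), c(5, 1, 0.2, 0.1, 0.1, 0.1)))
  fs <- select_across_k(imp_by_k, min_levels = 3)
  # f1 selected at 4 levels, f2 at 3, f3 at 1
  expect_setequal(fs$large, c("f1", "f2"))
  expect_false("f3" %in% fs$large)
  expect_true(all(fs$small %in% fs$medium))
  expect_true(all(fs$medium %in% fs$large))
  expect_equal(unname(fs$selection_count["f2"]), 3L)

  # nesting holds on random importance tables
  set.seed(99)
  for (r in 1:100) {
    ks <- paste0("k", 2:6)
    tabs <- lapply(ks, function(k)
      fake(sample(feats, sample(0:4, 1)), runif(6)))
    names(tabs) <- ks
    fsr <- suppressWarnings(select_across_k(tabs, min_levels = 3))
    expect_true(all(fsr$small %in% fsr$medium))
    expect_true(all(fsr$medium %in% fsr$large))
  }
})

test_that("splits are unstratified, disjoint, exhaustive and reproducible", {
  for (fr in c(0.8, 0.5, 0.2)) {
    sp <- split_samples(103, fr, seed = 7)
    expect_length(sp$train, round(103 * fr))
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), 1:103)
  }
  expect_identical(split_samples(50, 0.8, seed = 3),
                   split_samples(50, 0.8, seed = 3))
  expect_error(split_samples(5, 0.8), "at least 10")
})

test_that("held-out projection equals the train-model matrix product", {
  blocks <- small_blocks()
  fm <- fit_feature_models(blocks, rows = 1:60)
  test_rows <- 61:70
  proj <- project_features(fm, blocks, test_rows)
  # eigen-image block: direct multiplication oracle
  direct <- sweep(blocks$pixels[test_rows, ], 2,
                  fm$models$eigen$center) %*% fm$models$eigen$loadings
  got <- as.matrix(proj[, paste0("EigenFruitPC",
                                 1:fm$models$eigen$n_components)])
  expect_equal(unname(got), unname(direct), tolerance = 1e-10)
  # training rows reproduce their training scores
  re <- project_features(fm, blocks, 1:5)
  expect_equal(as.matrix(re[, -1]), as.matrix(fm$features[1:5, -1]),
               tolerance = 1e-8)
  # percent variance comes from train eigenvalues only
  expect_length(fm$models$eigen$pct_var, fm$models$eigen$n_components)
  expect_equal(sum(fm$models$eigen$eigenvalues),
               sum(apply(blocks$pixels[1:60, ], 2, stats::var)),
               tolerance = 1e-6)
})

test_that("classifier pair separates Gaussian blobs and matches closed-form LDA", {
  set.seed(31)
  n <- 60
  X <- rbind(matrix(rnorm(n * 2, 0), n), matrix(rnorm(n * 2, 4), n))
  colnames(X) <- c("a", "b")
  y <- rep(1:2, each = n)
  pair <- train_classifiers(X, y)
  pr <- predict_classifiers(pair, X)
  expect_gte(mean(pr$lda == y), 0.99)
  expect_gte(mean(pr$svm == y), 0.99)

  # label permutation leaves accuracy unchanged
  pair2 <- train_classifiers(X, 3 - y)
  pr2 <- predict_classifiers(pair2, X)
  expect_equal(mean(pr2$lda == (3 - y)), mean(pr$lda == y))

  # isotropic 2-class LDA boundary is the midpoint hyperplane
  mu1 <- colMeans(X[y == 1, ]); mu2 <- colMeans(X[y == 2, ])
  mid <- (mu1 + mu2) / 2
  w <- MASS::ginv(stats::cov(rbind(scale(X[y == 1, ], scale = FALSE),
                                   scale(X[y == 2, ], scale = FALSE)))) %*%
    (mu2 - mu1)
  probe <- rbind(mid + 0.001 * c(w), mid - 0.001 * c(w))
  colnames(probe) <- colnames(X)
  pp <- predict_classifiers(pair, probe)
  expect_equal(as.integer(as.character(pp$lda)), c(2L, 1L))
})

test_that("classification metrics match hand arithmetic", {
  # confusion matrix [[40,10],[5,45]]
  truth <- rep(c(1, 2), c(50, 50))
  pred <- c(rep(1, 40), rep(2, 10), rep(1, 5), rep(2, 45))
  m <- classification_metrics(truth, pred)
  expect_equal(unname(m["accuracy"]), 0.85)
  # class-1 precision 40/45, recall 0.8, fpr 5/50
  lev <- sort(unique(truth))
  cm <- table(factor(truth, lev), factor(pred, lev))
  expect_equal(cm[1, 1] / sum(cm[, 1]), 40 / 45)
  expect_equal(unname(m["precision"]), (40 / 45 + 45 / 55) / 2)
  expect_equal(unname(m["recall"]), (0.8 + 0.9) / 2)
  expect_equal(unname(m["fpr"]), (5 / 50 + 10 / 50) / 2)

  # perfect predictions
  mp <- classification_metrics(truth, truth)
  expect_equal(unname(mp["accuracy"]), 1)
  expect_equal(unname(mp["fpr"]), 0)

  # absent class skipped with warning
  expect_warning(classification_metrics(c(1, 1), c(1, 2)), "absent")
})

test_that("random guessing on balanced classes sits near chance accuracy", {
  set.seed(55)
  accs <- replicate(10, {
    truth <- rep(1:2, each = 50)
    mean(sample(truth) == truth)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})
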