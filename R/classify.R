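# LDA / SVM classification of ordinal shape classes and the
# split -> cluster -> project -> classify -> evaluate protocol.

#' Train the LDA + SVM classifier pair
#'
#' Linear discriminant analysis with pooled covariance (MASS) and a
#' radial-basis support vector machine with cost 1 and gamma = 1/#features
#' (the reference implementation's defaults, one-vs-one for multi-class).
#' A singular pooled covariance is handled by adding ridge noise 1e-6 with
#' a warning.
#'
#' @param features training feature data.frame/matrix (restricted to a
#'   feature set).
#' @param labels training class labels (>= 2 classes, >= 2 samples each).
#' @return a `classifier_pair` list with `lda`, `svm`, `feature_names`.
#' @export
train_classifiers <- function(features, labels) {
  X <- feature_matrix(features)
  if (ncol(X) == 0) stop("empty feature set")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("need at least 2 samples per class")
  ld <- tryCatch(MASS::lda(X, grouping = y),
                 error = function(e) {
                   warning("singular pooled covariance; ridge 1e-6 applied")
                   Xr <- X + matrix(stats::rnorm(length(X), 0, 1e-6),
                                    nrow(X))
                   MASS::lda(Xr, grouping = y)
                 })
  sv <- e1071::svm(X, y, kernel = "radial", cost = 1,
                   gamma = 1 / ncol(X))
  structure(list(lda = ld, svm = sv, feature_names = colnames(X)),
            class = "classifier_pair")
}

#' Predict with a classifier pair
#'
#' @param pair a [train_classifiers()] result.
#' @param features feature table with at least the training columns.
#' @return list with factors `lda` and `svm`.
#' @export
predict_classifiers <- function(pair, features) {
  X <- feature_matrix(features)[, pair$feature_names, drop = FALSE]
  list(lda = stats::predict(pair$lda, X)$class,
       svm = stats::predict(pair$svm, X))
}

#' Classification metrics from predictions
#'
#' Accuracy plus macro-averaged one-vs-rest precision, recall and
#' false-positive rate. Classes absent from the test truth are skipped in
#' the macro averages with a warning.
#'
#' @param truth,predicted label vectors of equal length.
#' @return named numeric vector: accuracy, precision, recall, fpr.
#' @export
classification_metrics <- function(truth, predicted) {
  lev <- sort(unique(c(as.character(truth), as.character(predicted))))
  truth <- factor(truth, levels = lev)
  predicted <- factor(predicted, levels = lev)
  cm <- table(truth, predicted)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  present <- rowSums(cm) > 0
  if (!all(present))
    warning("classes absent from test set skipped in macro averages")
  per_class <- vapply(which(present), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- n - tp - fn - fp
    c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      recall = tp / (tp + fn),
      fpr = if (fp + tn > 0) fp / (fp + tn) else 0)
  }, numeric(3))
  c(accuracy = acc,
    precision = mean(per_class["precision", ]),
    recall = mean(per_class["recall", ]),
    fpr = mean(per_class["fpr", ]))
}

#' Split / cluster / project / classify / evaluate protocol
#'
#' One iteration: draw an unstratified train/test split; cluster the
#' training pixel vectors at k and order the clusters with PPKC; assign
#' test images to the nearest training centroid; refit all PCA feature
#' models on the training samples only and project the test samples in;
#' train LDA and SVM on the requested feature set; evaluate on the test
#' set. Metrics are averaged over `n_iterations` fresh iterations.
#'
#' @param blocks a [extract_feature_blocks()] result for all samples.
#' @param k number of shape classes.
#' @param feature_names character vector of feature columns to classify
#'   with (e.g. a set from [select_across_k()]), or `NULL` for all.
#' @param fraction_train training fraction (0.8, 0.5 or 0.2 in the
#'   standard protocol).
#' @param n_iterations iterations to average (default 10).
#' @param seed integer seed.
#' @param n_restarts k-means restarts per iteration.
#' @return an `evaluation_report`: list with `mean` (classifier x metric)
#'   and `iterations` (long data.frame of per-iteration metrics).
#' @export
evaluate_protocol <- function(blocks, k, feature_names = NULL,
                              fraction_train = 0.8, n_iterations = 10,
                              seed = 1, n_restarts = 10) {
  n <- length(blocks$sample_id)
  rows_out <- list()
  for (it in seq_len(n_iterations)) {
    sp <- split_samples(n, fraction_train, seed = seed + 17 * it)
    hist <- cluster_history(blocks$pixels[sp$train, , drop = FALSE],
                            k_range = 2:k, n_restarts = n_restarts,
                            seed = seed + 31 * it)
    orient <- blocks$linear[sp$train, "SI"]
    pk <- ppkc(hist, orient_stat = orient)
    y_train <- pk$ordinal_assignments[[paste0("k", k)]]
    rank_k <- pk$orders[[paste0("k", k)]]$rank
    test_raw <- assign_to_nearest(hist$centroids[[paste0("k", k)]],
                                  blocks$pixels[sp$test, , drop = FALSE])
    y_test <- rank_k[test_raw]
    fm <- fit_feature_models(blocks, rows = sp$train)
    f_train <- fm$features
    f_test <- project_features(fm, blocks, sp$test)
    cols <- if (is.null(feature_names))
      setdiff(names(f_train), "sample_id") else feature_names
    cols <- intersect(cols, names(f_train))
    pair <- train_classifiers(f_train[, cols, drop = FALSE], y_train)
    preds <- predict_classifiers(pair, f_test[, cols, drop = FALSE])
    for (clf in c("lda", "svm")) {
      m <- suppressWarnings(classification_metrics(y_test, preds[[clf]]))
      rows_out[[length(rows_out) + 1L]] <-
        data.frame(iteration = it, classifier = clf, t(m))
    }
  }
  long <- do.call(rbind, rows_out)
  mean_tab <- aggregate(long[, c("accuracy", "precision", "recall",
                                 "fpr")],
                        by = list(classifier = long$classifier), mean)
  structure(list(mean = mean_tab, iterations = long,
                 k = k, fraction_train = fraction_train),
            class = "evaluation_report")
}
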