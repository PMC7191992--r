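# Random-forest out-of-bag feature selection: permutation importance
# averaged over many forests, a probe-thresholded interpretation set, a
# greedy-forward prediction set, and the across-k consolidation into
# nested large / medium / small feature sets.

#' Permutation-importance feature selection for one k
#'
#' Fits `n_forests` random forests of `n_trees` trees each on the features
#' with the ordinal class labels as response and averages the permutation
#' out-of-bag importance. Shuffled copies of every feature are added as
#' noise probes; the interpretation set keeps features whose mean importance
#' exceeds the largest probe importance. The prediction set is built by
#' greedy forward addition in decreasing importance order, retaining a
#' feature only while the out-of-bag error decreases by more than its
#' standard deviation across replicate forests.
#'
#' @param features feature data.frame or matrix (a `sample_id` column is
#'   dropped).
#' @param labels class labels (>= 2 classes).
#' @param n_forests forests averaged for importance (default 100).
#' @param n_trees trees per forest (default 2000).
#' @param seed integer seed.
#' @param n_pred_reps replicate forests per greedy step (default 5).
#' @return an `importance_result`: list with `importance` (named mean OOB
#'   importance), `per_forest` matrix, `noise_threshold`,
#'   `interpretation_set`, `prediction_set`, `oob_path`.
#' @export
rf_importance <- function(features, labels, n_forests = 100, n_trees = 2000,
                          seed = 1, n_pred_reps = 5) {
  X <- feature_matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("labels are constant")
  set.seed(seed)
  d <- ncol(X)
  probe_names <- paste0(".probe_", colnames(X))
  imp <- matrix(0, n_forests, 2 * d,
                dimnames = list(NULL, c(colnames(X), probe_names)))
  for (f in seq_len(n_forests)) {
    probes <- apply(X, 2, sample)
    colnames(probes) <- probe_names
    dat <- data.frame(X, probes, check.names = FALSE)
    dat$.y <- y
    fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                          num.trees = n_trees, importance = "permutation",
                          seed = seed + f, num.threads = 1)
    imp[f, names(fit$variable.importance)] <- fit$variable.importance
  }
  mean_imp <- colMeans(imp)
  noise_thr <- max(mean_imp[probe_names])
  keep <- mean_imp[colnames(X)]
  interp <- names(keep)[keep > noise_thr]
  interp <- interp[order(-keep[interp])]
  # greedy forward prediction step
  pred <- character(0)
  oob_path <- numeric(0)
  err_best <- Inf; sd_best <- 0
  for (feat in interp) {
    cand <- c(pred, feat)
    errs <- vapply(seq_len(n_pred_reps), function(r) {
      dat <- data.frame(X[, cand, drop = FALSE], check.names = FALSE)
      dat$.y <- y
      ranger::ranger(dependent.variable.name = ".y", data = dat,
                     num.trees = max(200, n_trees %/% 4),
                     seed = seed + 1000 * r + length(cand),
                     num.threads = 1)$prediction.error
    }, numeric(1))
    if (mean(errs) < err_best - sd_best) {
      pred <- cand
      err_best <- mean(errs); sd_best <- stats::sd(errs)
      oob_path <- c(oob_path, err_best)
    }
  }
  structure(list(importance = keep, per_forest = imp[, colnames(X),
                                                     drop = FALSE],
                 noise_threshold = noise_thr,
                 interpretation_set = interp, prediction_set = pred,
                 oob_path = oob_path),
            class = "importance_result")
}

feature_matrix <- function(features) {
  if (is.data.frame(features))
    features <- features[, setdiff(names(features), "sample_id"),
                         drop = FALSE]
  as.matrix(features)
}

#' Consolidate per-k selections into nested feature sets
#'
#' The large set keeps features that entered the prediction set at
#' `min_levels` or more values of k. The medium set keeps large-set members
#' whose mean importance (across k) exceeds the median of all observed
#' per-feature-per-k importances; the small set further requires exceeding
#' their mean. Thresholds are recomputed from the data at hand, and the
#' sets are nested by construction.
#'
#' @param importance_by_k named list ("k2", "k3", ...) of
#'   [rf_importance()] results.
#' @param min_levels minimum number of k levels (default 3).
#' @return a `feature_sets` list with `large`, `medium`, `small`,
#'   `thresholds`, and `selection_count`.
#' @export
select_across_k <- function(importance_by_k, min_levels = 3) {
  all_feats <- names(importance_by_k[[1]]$importance)
  count <- setNames(rep(0L, length(all_feats)), all_feats)
  for (res in importance_by_k)
    count[res$prediction_set] <- count[res$prediction_set] + 1L
  large <- names(count)[count >= min_levels]
  pooled <- unlist(lapply(importance_by_k, function(r) r$importance))
  mean_imp <- rowMeans(vapply(importance_by_k,
                              function(r) r$importance[all_feats],
                              numeric(length(all_feats))))
  names(mean_imp) <- all_feats
  thr_med <- stats::median(pooled)
  thr_mean <- mean(pooled)
  medium <- large[mean_imp[large] > thr_med]
  small <- medium[mean_imp[medium] > thr_mean]
  if (!length(large)) warning("empty large feature set")
  structure(list(large = large, medium = medium, small = small,
                 thresholds = c(median = thr_med, mean = thr_mean,
                                min_levels = min_levels),
                 selection_count = count, mean_importance = mean_imp),
            class = "feature_sets")
}

#' Random train/test split without stratification
#'
#' @param n sample count (>= 10) or a vector of ids.
#' @param fraction_train training fraction (the protocol uses 0.8, 0.5,
#'   0.2).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_samples <- function(n, fraction_train, seed = 1) {
  ids <- if (length(n) == 1) seq_len(n) else seq_along(n)
  if (length(ids) < 10) stop("need at least 10 samples")
  set.seed(seed)
  n_train <- round(length(ids) * fraction_train)
  train <- sort(sample(ids, n_train))
  list(train = train, test = setdiff(ids, train))
}
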