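# k-means over flattened binary images, model-selection criteria, and
# nearest-centroid assignment of held-out samples.

#' k-means clustering of flattened images
#'
#' Lloyd's algorithm with Euclidean distance, best of `n_restarts` random
#' initializations by within-cluster sum of squares. Initial centers are
#' sampled without replacement from the data; a restart that collapses to an
#' empty cluster is reseeded from the point farthest from its center.
#'
#' @param vectors n x d numeric matrix (rows = samples).
#' @param k number of clusters (2 <= k <= n).
#' @param n_restarts random restarts (default 25).
#' @param seed integer seed; results are deterministic given it.
#' @param iter_max Lloyd iteration cap (default 300).
#' @return list with `assignments` (integer labels 1..k), `centroids`
#'   (k x d), `wss` (total within-cluster sum of squares).
#' @export
kmeans_images <- function(vectors, k, n_restarts = 25, seed = 1,
                          iter_max = 300) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < k) stop("fewer samples than clusters")
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- vectors[sample.int(n, k), , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(vectors, centers = init,
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) {
      # empty-cluster failure: replace the emptiest center with the point
      # farthest from its nearest center, then retry once
      d2 <- outer(rowSums(vectors^2), rowSums(init^2), "+") -
        2 * vectors %*% t(init)
      nearest <- apply(d2, 1, which.min)
      sizes <- tabulate(nearest, nbins = k)
      init[which.min(sizes), ] <- vectors[which.max(apply(d2, 1, min)), ]
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(vectors, centers = init,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit)) next
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  list(assignments = as.integer(best$cluster),
       centroids = unname(best$centers),
       wss = best$tot.withinss)
}

#' Cluster the same samples at every k in a range
#'
#' @inheritParams kmeans_images
#' @param k_range inclusive integer range, default 2:10.
#' @return a `cluster_history`: list with `k_range`, `assignments` (named
#'   list "k2".."kK" of label vectors), `centroids` (same naming), `wss`
#'   per k, and `n`.
#' @export
cluster_history <- function(vectors, k_range = 2:10, n_restarts = 25,
                            seed = 1, iter_max = 300) {
  vectors <- as.matrix(vectors)
  fits <- lapply(seq_along(k_range), function(i) {
    kmeans_images(vectors, k_range[i], n_restarts = n_restarts,
                  seed = seed + i, iter_max = iter_max)
  })
  names(fits) <- paste0("k", k_range)
  structure(list(
    k_range = k_range,
    assignments = lapply(fits, `[[`, "assignments"),
    centroids = lapply(fits, `[[`, "centroids"),
    wss = vapply(fits, `[[`, numeric(1), "wss"),
    n = nrow(vectors)), class = "cluster_history")
}

#' Model-selection criteria across k
#'
#' Reports, per k, the total within-cluster sum of squares (WSS), total sum
#' of squares (TSS), adjusted R-squared
#' \eqn{1 - (WSS/(n-k)) / (TSS/(n-1))}, and AIC/BIC from a spherical-Gaussian
#' surrogate: pooled variance \eqn{\hat\sigma^2 = WSS/(nd)}, log-likelihood
#' \eqn{\hat L = -(nd/2)(\ln(2\pi\hat\sigma^2) + 1)}, parameter count
#' \eqn{p = kd + 1}.
#'
#' @param history a [cluster_history()].
#' @param vectors the matrix the history was computed on.
#' @return data.frame with columns k, WSS, TSS, adjusted_R2, AIC, BIC.
#' @export
selection_criteria <- function(history, vectors) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors); d <- ncol(vectors)
  tss <- sum(scale(vectors, scale = FALSE)^2)
  out <- lapply(seq_along(history$k_range), function(i) {
    k <- history$k_range[i]
    wss <- history$wss[i]
    adj <- 1 - (wss / (n - k)) / (tss / (n - 1))
    sig2 <- wss / (n * d)
    ll <- if (sig2 > 0) -(n * d / 2) * (log(2 * pi * sig2) + 1) else Inf
    p <- k * d + 1
    data.frame(k = k, WSS = wss, TSS = tss, adjusted_R2 = adj,
               AIC = -2 * ll + 2 * p, BIC = -2 * ll + p * log(n))
  })
  do.call(rbind, out)
}

#' Assign new samples to the nearest centroid
#'
#' Euclidean nearest-centroid labels; an exact tie goes to the lowest label.
#'
#' @param centroids k x d matrix.
#' @param new_vectors m x d matrix.
#' @return integer labels of length m.
#' @export
assign_to_nearest <- function(centroids, new_vectors) {
  centroids <- as.matrix(centroids); new_vectors <- as.matrix(new_vectors)
  if (ncol(centroids) != ncol(new_vectors)) stop("dimension mismatch")
  cc <- rowSums(centroids^2)
  d2 <- outer(rowSums(new_vectors^2), cc, "+") -
    2 * new_vectors %*% t(centroids)
  apply(d2, 1, which.min)  # which.min takes the first (lowest label) on ties
}
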