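# Principal Progression of k Clusters (PPKC).
#
# k-means labels are nominal; PPKC orders them on an ordinal scale. For a
# focal k, each focal cluster is profiled by the proportions of its members
# that fall in every cluster of every smaller k (the ancestry-proportion
# matrix M). The covariance between the focal clusters' profiles is
# eigendecomposed and clusters are ranked by their elements on the leading
# eigenvector; only the rank matters, and an order and its reverse are
# equivalent.

#' Ancestry-proportion matrix for a focal k
#'
#' Rows are (level j, cluster c) pairs for j = 2..focal_k-1, c = 1..j; the
#' entry in column f is the share of focal-cluster-f members that belong to
#' level-j cluster c. The matrix has ((k^2 - k)/2 - 1) rows and each column
#' sums to focal_k - 2.
#'
#' @param history a [cluster_history()] covering 2..focal_k.
#' @param focal_k focal number of clusters (>= 3).
#' @return a `progression_matrix`: matrix M with a `row_index` attribute
#'   (data.frame level, cluster) and `focal_k` attribute.
#' @export
build_progression_matrix <- function(history, focal_k) {
  if (focal_k < 3) stop("focal_k must be >= 3")
  need <- paste0("k", 2:focal_k)
  if (!all(need %in% names(history$assignments)))
    stop("history lacks assignments for some k in 2..focal_k")
  focal <- history$assignments[[paste0("k", focal_k)]]
  sizes <- tabulate(focal, nbins = focal_k)
  if (any(sizes == 0)) stop(sprintf("empty cluster at k=%d", focal_k))
  rows <- list(); idx <- list()
  for (j in 2:(focal_k - 1)) {
    lab_j <- history$assignments[[paste0("k", j)]]
    for (c in seq_len(j)) {
      cnt <- vapply(seq_len(focal_k),
                    function(f) sum(focal == f & lab_j == c), numeric(1))
      rows[[length(rows) + 1L]] <- cnt / sizes
      idx[[length(idx) + 1L]] <- c(j, c)
    }
  }
  M <- do.call(rbind, rows)
  colnames(M) <- paste0("c", seq_len(focal_k))
  structure(M,
            row_index = do.call(rbind, lapply(idx, function(p)
              data.frame(level = p[1], cluster = p[2]))),
            focal_k = focal_k, class = c("progression_matrix", "matrix"))
}

#' Covariance of ancestry profiles
#'
#' Sample variance-covariance matrix between the columns of M (rows treated
#' as observations, divisor rows - 1).
#'
#' @param M a [build_progression_matrix()] result (or any numeric matrix).
#' @return symmetric k x k covariance matrix.
#' @export
progression_covariance <- function(M) {
  if (nrow(M) < 2) stop("need at least 2 rows to form a covariance")
  stats::cov(unclass(M))
}

#' Rank clusters on the leading eigenvector
#'
#' Eigendecomposes the profile covariance and ranks clusters by their
#' elements on the eigenvector of the largest eigenvalue. Only ranks are
#' kept; distances between elements carry no meaning, and an order and its
#' reverse are declared equivalent. Ties in eigenvector elements are broken
#' by cluster size (larger first) then by label.
#'
#' @param Sigma symmetric k x k covariance matrix.
#' @param sizes optional cluster sizes for tie-breaking.
#' @param tol relative tolerance for detecting a degenerate (repeated)
#'   leading eigenvalue.
#' @return a `cluster_order`: list with `focal_k`, `order` (cluster labels
#'   from one end of the progression to the other), `rank` (ordinal position
#'   of each original label), `leading_eigenvalue`, `eigvec`, `min_gap`
#'   (smallest spacing between consecutive sorted eigenvector elements,
#'   relative to their range).
#' @export
principal_order <- function(Sigma, sizes = NULL, tol = 1e-9) {
  Sigma <- as.matrix(Sigma)
  k <- nrow(Sigma)
  eg <- eigen(Sigma, symmetric = TRUE)
  if (k >= 2 && abs(eg$values[1] - eg$values[2]) <=
      tol * max(abs(eg$values[1]), 1))
    warning("degenerate progression: leading eigenvalue multiplicity > 1")
  v <- eg$vectors[, 1]
  # canonical sign: largest-magnitude element positive
  v <- v * sign(v[which.max(abs(v))])
  if (is.null(sizes)) sizes <- rep(1, k)
  ord <- order(v, -sizes, seq_len(k))
  rank <- integer(k); rank[ord] <- seq_len(k)
  rng <- diff(range(v))
  gaps <- diff(sort(v))
  structure(list(focal_k = k, order = ord, rank = rank,
                 leading_eigenvalue = eg$values[1], eigvec = v,
                 min_gap = if (rng > 0) min(gaps) / rng else 0),
            class = "cluster_order")
}

#' Equivalence of cluster orders up to reversal
#'
#' @param a,b `cluster_order` objects or plain rank vectors.
#' @return `TRUE` when the two orders agree exactly or after reversal.
#' @export
order_equivalent <- function(a, b) {
  ra <- if (inherits(a, "cluster_order")) a$rank else a
  rb <- if (inherits(b, "cluster_order")) b$rank else b
  identical(as.integer(ra), as.integer(rb)) ||
    identical(as.integer(ra), as.integer(length(rb) + 1L - rb))
}

# majority ancestor of each focal cluster at the previous k
majority_ancestor <- function(history, focal_k) {
  focal <- history$assignments[[paste0("k", focal_k)]]
  prev <- history$assignments[[paste0("k", focal_k - 1)]]
  vapply(seq_len(focal_k), function(f) {
    tab <- tabulate(prev[focal == f], nbins = focal_k - 1)
    which.max(tab)
  }, integer(1))
}

#' Run PPKC across a cluster history
#'
#' For each k >= 3 composes [build_progression_matrix()],
#' [progression_covariance()] and [principal_order()]. The k = 2 order is
#' arbitrary by construction and reported as the identity. Orientation is
#' chained for stability: at each k >= 4 the eigenvector sign giving
#' positive rank correlation with the order inherited from k - 1 (through
#' majority cluster ancestry) is chosen; at k = 3 (or when chaining is
#' uninformative) the orientation statistic `orient_stat`, a per-sample
#' value such as the bounding-box height/width ratio, puts the
#' highest-mean cluster first. Clusters whose eigenvector elements nearly
#' coincide (relative gap below `gap_tol`) are flagged as a convergence
#' diagnostic, the overfitting symptom where new clusters duplicate old
#' ones.
#'
#' @param history a [cluster_history()].
#' @param orient_stat optional numeric per-sample orientation statistic.
#' @param gap_tol relative eigenvector-gap threshold for the convergence
#'   flag (default 0.01).
#' @return a `ppkc_result`: list with `orders` (per k `cluster_order`),
#'   `ordinal_assignments` (per k, each sample's ordinal class 1..k), and
#'   `converged_pairs` flags per k.
#' @export
ppkc <- function(history, orient_stat = NULL, gap_tol = 0.01) {
  ks <- history$k_range
  orders <- list(); ordinal <- list(); flags <- list()
  prev_rank <- NULL; prev_k <- NULL
  for (k in ks) {
    lab <- history$assignments[[paste0("k", k)]]
    sizes <- tabulate(lab, nbins = k)
    if (k == 2) {
      # arbitrary; orient by the statistic when given, else by size
      r <- c(1L, 2L)
      if (!is.null(orient_stat)) {
        mu <- tapply(orient_stat, factor(lab, levels = 1:2), mean)
        if (!any(is.na(mu)) && mu[2] > mu[1]) r <- c(2L, 1L)
      }
      co <- structure(list(focal_k = 2L, order = order(r), rank = r,
                           leading_eigenvalue = NA_real_,
                           eigvec = rep(NA_real_, 2), min_gap = NA_real_,
                           arbitrary = TRUE), class = "cluster_order")
    } else {
      M <- build_progression_matrix(history, k)
      Sg <- progression_covariance(M)
      co <- principal_order(Sg, sizes = sizes)
      flip <- FALSE
      orient_by_stat <- function() {
        mu <- tapply(orient_stat, factor(lab, levels = seq_len(k)), mean)
        sp2 <- suppressWarnings(stats::cor(co$rank, as.numeric(mu),
                                           method = "spearman"))
        # highest-mean cluster first (rank 1)
        !is.na(sp2) && sp2 > 0
      }
      if (k == 3 && !is.null(orient_stat)) {
        flip <- orient_by_stat()
      } else {
        sp <- NA_real_
        if (k >= 4) {
          anc <- majority_ancestor(history, k)
          sp <- suppressWarnings(stats::cor(co$rank, prev_rank[anc],
                                            method = "spearman"))
        }
        if (!is.na(sp) && sp != 0) {
          flip <- sp < 0
        } else if (!is.null(orient_stat)) {
          flip <- orient_by_stat()
        }
      }
      if (flip) {
        co$rank <- k + 1L - co$rank
        co$order <- rev(co$order)
        co$eigvec <- -co$eigvec
      }
    }
    orders[[paste0("k", k)]] <- co
    ordinal[[paste0("k", k)]] <- co$rank[lab]
    flags[[paste0("k", k)]] <-
      if (k >= 3 && is.finite(co$min_gap)) co$min_gap < gap_tol else FALSE
    prev_rank <- co$rank; prev_k <- k
  }
  structure(list(orders = orders, ordinal_assignments = ordinal,
                 converged_pairs = flags),
            class = "ppkc_result")
}
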