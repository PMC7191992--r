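# Generalized Procrustes alignment of pseudo-landmark configurations and
# the per-landmark / latent-region feature blocks built on it.

center_scale_config <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  s <- sqrt(sum(Xc^2))
  if (s < .Machine$double.eps) stop("degenerate configuration")
  Xc / s
}

# optimal rotation (no reflection) aligning X onto Y
procrustes_rotation <- function(X, Y) {
  s <- svd(t(X) %*% Y)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes alignment
#'
#' Each configuration is translated to its centroid, scaled to unit
#' centroid size, then iteratively rotated to the evolving mean shape until
#' the mean changes by less than `tol` (at most `max_iter` passes).
#'
#' @param landmark_sets list of p x 2 matrices, or an n x p x 2 array.
#' @param tol convergence tolerance on the mean shape (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @return list with `aligned` (n x p x 2 array), `mean_shape` (p x 2),
#'   `iterations`.
#' @export
gpa_align <- function(landmark_sets, tol = 1e-8, max_iter = 100) {
  if (is.array(landmark_sets) && length(dim(landmark_sets)) == 3)
    landmark_sets <- lapply(seq_len(dim(landmark_sets)[1]),
                            function(i) landmark_sets[i, , ])
  n <- length(landmark_sets)
  p <- nrow(landmark_sets[[1]])
  if (any(vapply(landmark_sets, nrow, numeric(1)) != p))
    stop("unequal landmark counts")
  conf <- lapply(landmark_sets, center_scale_config)
  mean_shape <- conf[[1]]
  it <- 0
  repeat {
    it <- it + 1
    conf <- lapply(conf, function(X) X %*% procrustes_rotation(X, mean_shape))
    new_mean <- center_scale_config(Reduce(`+`, conf) / n)
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol || it >= max_iter) break
  }
  # the Procrustes mean is defined only up to rotation; canonicalize by
  # pointing landmark 1 (the tip-adjacent landmark) straight up so results
  # do not depend on sample order
  ang <- atan2(mean_shape[1, 1], -mean_shape[1, 2])
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  mean_shape <- mean_shape %*% R
  conf <- lapply(conf, function(X) X %*% R)
  aligned <- array(0, dim = c(n, p, 2))
  for (i in seq_len(n)) aligned[i, , ] <- conf[[i]]
  list(aligned = aligned, mean_shape = mean_shape, iterations = it)
}

#' Per-landmark principal components
#'
#' Each of the p landmarks is a bivariate feature across samples. After
#' centering each landmark's scatter, an independent 2-D PCA gives a PC1
#' score per sample and landmark; landmarks whose PC1 standard deviation
#' exceeds the median across landmarks are flagged as high-variance.
#'
#' @param aligned n x p x 2 array from [gpa_align()].
#' @return list with `pc1_scores` (n x p), `pc1_sd` (length p),
#'   `high_variance` (logical, p), `centers` (p x 2), `axes` (p x 2 leading
#'   eigenvectors).
#' @export
landmark_pca <- function(aligned) {
  n <- dim(aligned)[1]; p <- dim(aligned)[2]
  scores <- matrix(0, n, p)
  sds <- numeric(p)
  centers <- matrix(0, p, 2)
  axes <- matrix(0, p, 2)
  for (l in seq_len(p)) {
    pts <- aligned[, l, ]
    ctr <- colMeans(pts)
    S <- stats::cov(pts)
    eg <- eigen(S, symmetric = TRUE)
    v <- eg$vectors[, 1]
    v <- v * sign(v[which.max(abs(v))])
    scores[, l] <- sweep(pts, 2, ctr) %*% v
    sds[l] <- sqrt(max(eg$values[1], 0))
    centers[l, ] <- ctr
    axes[l, ] <- v
  }
  list(pc1_scores = scores, pc1_sd = sds,
       high_variance = sds > stats::median(sds),
       centers = centers, axes = axes)
}

# default landmark groupings for the four most variable outline regions
# (landmark 1 sits at the topmost point, i.e. adjacent to the tip)
region_landmarks <- function() {
  list(Tip = c(1:5, 48:50), Neck = 24:29,
       SideLeft = 11:15, SideRight = 38:43)
}

#' Latent region scores from per-landmark PC1 values
#'
#' A region's score is the unit-variance first principal component of the
#' PC1 scores of its landmark group; the composite Shape score is the
#' unit-variance first principal component of the four region scores. This
#' is a region-PCA construction of the latent tip / neck / side variables
#' (a factor-analytic variant would estimate the same constructs by SEM).
#'
#' @param pc1_scores n x 50 matrix from [landmark_pca()].
#' @param regions named list of landmark index vectors; defaults to the
#'   tip, neck and side groupings.
#' @return list with `scores` (n x 5 matrix: Tip, Neck, SideLeft,
#'   SideRight, Shape) and `loadings` (per-region weight vectors for
#'   projection).
#' @export
latent_region_scores <- function(pc1_scores, regions = region_landmarks()) {
  if (max(unlist(regions)) > ncol(pc1_scores)) stop("missing landmarks")
  n <- nrow(pc1_scores)
  region_score <- function(block) {
    m <- fit_pca(block, 1)
    s <- m$scores[, 1]
    sdv <- stats::sd(s)
    if (sdv < .Machine$double.eps) stop("no variance across samples")
    list(score = s / sdv, model = m, sd = sdv)
  }
  parts <- lapply(regions, function(ix)
    region_score(pc1_scores[, ix, drop = FALSE]))
  S4 <- do.call(cbind, lapply(parts, `[[`, "score"))
  colnames(S4) <- names(regions)
  shp <- region_score(S4)
  scores <- cbind(S4, Shape = shp$score)
  list(scores = scores,
       loadings = list(regions = regions,
                       models = lapply(parts, `[[`, "model"),
                       sds = vapply(parts, `[[`, numeric(1), "sd"),
                       shape_model = shp$model, shape_sd = shp$sd))
}
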