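# Shared PCA wrapper used by the EFA, eigen-image and biomass-profile
# blocks. Keeps the full eigenvalue spectrum (so variance is conserved) but
# only the requested number of loading columns.

#' Fit a mean-centered PCA
#'
#' Thin SVD-based PCA. Loadings are orthonormal columns; each loading's
#' largest-magnitude element is made positive so signs are reproducible.
#' Eigenvalues are the sample variances of the scores and the full spectrum
#' is retained, so their sum equals the total variance of the training
#' data.
#'
#' @param X n x d numeric matrix.
#' @param n_pcs number of components to keep (truncated, with a warning,
#'   when the rank cannot support it).
#' @return a `pca_model`: list with `center`, `loadings` (d x m),
#'   `eigenvalues` (full spectrum), `n_components`, `scores` (n x m),
#'   `pct_var` (percent variance per kept component).
#' @export
fit_pca <- function(X, n_pcs) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples for PCA")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  eig <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  m <- min(n_pcs, rank, n - 1, ncol(X))
  if (m < n_pcs)
    warning(sprintf("rank supports only %d of %d requested components",
                    m, n_pcs))
  if (m < 1) stop("degenerate input: no variance")
  L <- sv$v[, seq_len(m), drop = FALSE]
  flip <- vapply(seq_len(m), function(j) {
    sign(L[which.max(abs(L[, j])), j])
  }, numeric(1))
  L <- sweep(L, 2, flip, `*`)
  scores <- Xc %*% L
  structure(list(center = ctr, loadings = L, eigenvalues = eig,
                 n_components = m, scores = scores,
                 pct_var = 100 * eig[seq_len(m)] / sum(eig)),
            class = "pca_model")
}

#' Project new samples into a fitted PCA space
#'
#' Scores are `t(loadings) %*% (x - center)` using the training mean and
#' loadings only.
#'
#' @param model a [fit_pca()] result.
#' @param X m x d matrix of new samples.
#' @return m x n_components score matrix.
#' @export
project_pca <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) stop("dimension mismatch")
  sweep(X, 2, model$center) %*% model$loadings
}

#' Eigen-image PCA of flattened binary images
#'
#' PCA on the n x 10,000 pixel matrix; the leading components are the
#' eigen-images ("EigenFruit" components), with percent variance per
#' component reported.
#'
#' @param pixel_matrix n x d binary matrix from [pixel_matrix()].
#' @param n_pcs components to keep (default 20).
#' @return a `pca_model`.
#' @export
eigenfruit <- function(pixel_matrix, n_pcs = 20) {
  fit_pca(pixel_matrix, n_pcs)
}

#' Biomass profiles of a normalized image
#'
#' The horizontal profile counts foreground pixels in each of the 100 image
#' rows; the vertical profile counts them in each of the 100 columns.
#'
#' @param img a `normalized_image` or binary matrix.
#' @return list with integer vectors `horizontal` and `vertical`.
#' @export
biomass_profiles <- function(img) {
  px <- if (inherits(img, "normalized_image")) img$pixels else img
  list(horizontal = as.integer(rowSums(px)),
       vertical = as.integer(colSums(px)))
}

#' PCA of EFA coefficient tables
#'
#' @param coef_table samples x 20 matrix of EFA coefficients.
#' @param n_pcs components to keep (default 20).
#' @return list with `model` ([fit_pca()]) and `scores`.
#' @export
efa_pca <- function(coef_table, n_pcs = 20) {
  m <- fit_pca(coef_table, n_pcs)
  list(model = m, scores = m$scores)
}

#' PCA of biomass-profile matrices
#'
#' @param profile_matrix n x 100 matrix of row or column counts.
#' @param n_pcs components to keep (default 5).
#' @return list with `model` and `scores`.
#' @export
profile_pca <- function(profile_matrix, n_pcs = 5) {
  m <- fit_pca(profile_matrix, n_pcs)
  list(model = m, scores = m$scores)
}
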