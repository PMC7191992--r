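# Clone-mean broad-sense heritability:
#   H^2 = sigma2_G / (sigma2_G + sigma2_E / (h * r))
# with h the harmonic mean of observed harvests per genotype and r the
# harmonic mean of replicates per harvest. Quantitative traits use a REML
# linear mixed model (genotype random; harvest and block fixed); ordinal
# shape classes use a cumulative-logit mixed model with a genotype random
# intercept estimated by Gauss-Hermite quadrature.

#' Harmonic mean
#'
#' @param counts positive numbers.
#' @return n / sum(1/counts).
#' @export
harmonic_mean <- function(counts) {
  if (any(counts <= 0)) stop("harmonic mean requires positive counts")
  length(counts) / sum(1 / counts)
}

#' Replication summary of an experiment design
#'
#' `h` is the harmonic mean, over genotypes, of the number of distinct
#' harvests observed; `r` is the harmonic mean, over genotype-by-harvest
#' combinations, of the number of replicate plots.
#'
#' @param records data.frame with columns genotype, harvest, block (and
#'   optionally plot; genotype x harvest x block identifies a plot when
#'   absent).
#' @return list with `h` and `r`.
#' @export
design_summary <- function(records) {
  if (is.null(records$plot))
    records$plot <- paste(records$genotype, records$harvest, records$block,
                          sep = "_")
  per_gen <- tapply(records$harvest, records$genotype,
                    function(x) length(unique(x)))
  gh <- paste(records$genotype, records$harvest, sep = "\r")
  per_gh <- tapply(records$plot, gh, function(x) length(unique(x)))
  list(h = harmonic_mean(as.numeric(per_gen)),
       r = harmonic_mean(as.numeric(per_gh)))
}

#' Clone-mean broad-sense heritability
#'
#' @param sigma2_G genotypic variance (>= 0).
#' @param sigma2_E residual variance (>= 0; not both zero).
#' @param h harmonic mean of harvests per genotype.
#' @param r harmonic mean of replicates per harvest.
#' @return H^2 in [0, 1].
#' @export
h2_clone_mean <- function(sigma2_G, sigma2_E, h, r) {
  if (sigma2_G < 0 || sigma2_E < 0) stop("variances must be non-negative")
  if (sigma2_G == 0 && sigma2_E == 0) stop("H^2 undefined: no variance")
  sigma2_G / (sigma2_G + sigma2_E / (h * r))
}

#' REML variance components for a quantitative trait
#'
#' Fits `trait ~ harvest + block + (1 | genotype)` by REML. Fruit-level
#' subsamples are averaged to plot means first (the residual is the plot
#' error) unless `average_subsamples = FALSE`.
#'
#' @param trait numeric vector, one value per record row.
#' @param records data.frame with genotype, harvest, block (and plot).
#' @param average_subsamples collapse multiple fruit per plot to the plot
#'   mean (default TRUE).
#' @return a `variance_components` list: `sigma2_G`, `sigma2_E`, `method`,
#'   `converged`.
#' @export
fit_quantitative <- function(trait, records, average_subsamples = TRUE) {
  d <- data.frame(y = trait,
                  genotype = factor(records$genotype),
                  harvest = factor(records$harvest),
                  block = factor(records$block),
                  plot = if (is.null(records$plot))
                    paste(records$genotype, records$harvest, records$block,
                          sep = "_") else records$plot)
  d <- d[complete.cases(d), ]
  if (length(unique(d$genotype)) < 2) stop("need >= 2 genotypes")
  if (average_subsamples && anyDuplicated(d$plot)) {
    d <- aggregate(y ~ genotype + harvest + block + plot, data = d,
                   FUN = mean)
  }
  terms <- c(if (nlevels(droplevels(d$harvest)) > 1) "harvest",
             if (nlevels(droplevels(d$block)) > 1) "block")
  fml <- as.formula(paste("y ~", paste(c(terms, "(1 | genotype)"),
                                       collapse = " + ")))
  fit <- tryCatch(lme4::lmer(fml, data = d, REML = TRUE),
                  error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixed-model fit failed; components NA")
    return(structure(list(sigma2_G = NA_real_, sigma2_E = NA_real_,
                          method = "REML", converged = FALSE),
                     class = "variance_components"))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "genotype"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  conv <- length(fit@optinfo$conv$lme4) == 0
  if (!conv) warning("mixed model did not fully converge")
  structure(list(sigma2_G = s2g, sigma2_E = s2e, method = "REML",
                 converged = conv),
            class = "variance_components")
}

# ---- cumulative-logit mixed model ------------------------------------------

# Negative log-likelihood of a cumulative-logit model with a genotype
# random intercept, integrated by Gauss-Hermite quadrature. Thresholds are
# parametrized as (theta_1, log increments) to stay ordered.
clmm_negll <- function(par, y, gmap, X, n_cat, gh) {
  n_thr <- n_cat - 1L
  theta <- cumsum(c(par[1], exp(par[2:n_thr])))
  if (n_thr == 1) theta <- par[1]
  p_beta <- if (ncol(X)) par[n_thr + seq_len(ncol(X))] else numeric(0)
  log_sig <- par[length(par)]
  sig <- exp(log_sig)
  eta_fix <- if (ncol(X)) drop(X %*% p_beta) else rep(0, length(y))
  nodes <- gh$x * sqrt(2) * sig
  wts <- gh$w / sqrt(pi)
  # N x Q matrix of per-observation log-probabilities at each node
  eta <- outer(eta_fix, nodes, `+`)
  up <- matrix(1, length(y), length(nodes))
  lo <- matrix(0, length(y), length(nodes))
  not_top <- y < n_cat
  up[not_top, ] <- plogis(theta[y[not_top]] - eta[not_top, , drop = FALSE])
  not_bot <- y > 1L
  lo[not_bot, ] <- plogis(theta[y[not_bot] - 1L] -
                            eta[not_bot, , drop = FALSE])
  logpr <- log(pmax(up - lo, 1e-12))
  per_gen <- rowsum(logpr, gmap)           # G x Q joint log-likelihoods
  m <- apply(per_gen, 1, max)
  lik <- drop(exp(per_gen - m) %*% wts)    # scaled for stability
  -sum(log(pmax(lik, 1e-300)) + m)
}

#' Variance components for an ordinal trait
#'
#' Cumulative-logit mixed model (threshold model) with a genotype random
#' intercept and harvest/block fixed effects, fitted by maximum likelihood
#' with Gauss-Hermite quadrature. On the latent logistic scale the residual
#' variance is fixed at pi^2/3, the threshold-model convention recorded in
#' the output. With fewer than 3 categories represented, or if the
#' likelihood optimization fails, the fit falls back to a Gaussian REML
#' model on the integer scores (flagged in `method`).
#'
#' @param classes ordinal class labels (integers or ordered factor).
#' @param records design data.frame as in [fit_quantitative()].
#' @param n_quad quadrature nodes (default 15).
#' @param latent_residual use pi^2/3 as sigma2_E (default TRUE); otherwise
#'   callers may combine components on another scale.
#' @return a `variance_components` list with `sigma2_G`, `sigma2_E`,
#'   `method` ("clmm-GH" or "gaussian-fallback"), `converged`.
#' @export
fit_ordinal <- function(classes, records, n_quad = 15,
                        latent_residual = TRUE) {
  y <- as.integer(factor(classes, levels = sort(unique(classes))))
  n_cat <- max(y)
  small <- any(tabulate(y, n_cat) < 3)
  if (small) warning("fewer than 3 samples in some category")
  gaussian_fallback <- function() {
    vc <- fit_quantitative(as.numeric(y), records)
    vc$method <- "gaussian-fallback"
    vc
  }
  if (n_cat < 2) stop("ordinal trait is constant")
  gmap <- as.integer(factor(records$genotype))
  fd <- data.frame(harvest = factor(records$harvest),
                   block = factor(records$block))
  terms <- c(if (nlevels(fd$harvest) > 1) "harvest",
             if (nlevels(fd$block) > 1) "block")
  X <- if (length(terms)) {
    stats::model.matrix(as.formula(paste("~", paste(terms, collapse = "+"))),
                        fd)[, -1, drop = FALSE]
  } else matrix(0, nrow(fd), 0)
  gh <- gauss_hermite(n_quad)
  n_thr <- n_cat - 1L
  start <- c(qlogis(cumsum(tabulate(y, n_cat))[1:n_thr] / length(y))[1],
             if (n_thr > 1) rep(log(1), n_thr - 1),
             rep(0, ncol(X)), log(0.5))
  opt <- tryCatch(
    stats::optim(start, clmm_negll, y = y, gmap = gmap, X = X,
                 n_cat = n_cat, gh = gh, method = "BFGS",
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    warning("cumulative-logit fit failed; Gaussian fallback on scores")
    return(gaussian_fallback())
  }
  sig2 <- exp(opt$par[length(opt$par)])^2
  structure(list(sigma2_G = sig2,
                 sigma2_E = if (latent_residual) pi^2 / 3 else NA_real_,
                 method = "clmm-GH",
                 converged = opt$convergence == 0,
                 residual_convention = "latent logistic (pi^2/3)"),
            class = "variance_components")
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  eg <- eigen(J, symmetric = TRUE)
  list(x = eg$values, w = sqrt(pi) * eg$vectors[1, ]^2)
}

#' Heritability of every column of a feature table
#'
#' @param features feature data.frame (sample_id column aligned with
#'   `records` rows).
#' @param records design data.frame.
#' @return data.frame, one row per trait: sigma2_G, sigma2_E, h, r, H2,
#'   converged.
#' @export
h2_features <- function(features, records) {
  ds <- design_summary(records)
  traits <- setdiff(names(features), "sample_id")
  rows <- lapply(traits, function(tr) {
    vc <- tryCatch(fit_quantitative(features[[tr]], records),
                   error = function(e) NULL)
    if (is.null(vc) || is.na(vc$sigma2_G))
      return(data.frame(trait = tr, sigma2_G = NA, sigma2_E = NA,
                        h = ds$h, r = ds$r, H2 = NA, converged = FALSE))
    data.frame(trait = tr, sigma2_G = vc$sigma2_G, sigma2_E = vc$sigma2_E,
               h = ds$h, r = ds$r,
               H2 = h2_clone_mean(vc$sigma2_G, vc$sigma2_E, ds$h, ds$r),
               converged = vc$converged)
  })
  do.call(rbind, rows)
}

#' Heritability of ordinal shape classes across k
#'
#' @param ordinal_assignments named list ("k2", ...) of per-sample ordinal
#'   classes (as from [ppkc()]).
#' @param records design data.frame.
#' @param ... passed to [fit_ordinal()].
#' @return data.frame with one row per k.
#' @export
h2_classes <- function(ordinal_assignments, records, ...) {
  ds <- design_summary(records)
  rows <- lapply(names(ordinal_assignments), function(nm) {
    vc <- suppressWarnings(fit_ordinal(ordinal_assignments[[nm]],
                                       records, ...))
    data.frame(k = as.integer(sub("k", "", nm)),
               sigma2_G = vc$sigma2_G, sigma2_E = vc$sigma2_E,
               h = ds$h, r = ds$r,
               H2 = h2_clone_mean(vc$sigma2_G, vc$sigma2_E, ds$h, ds$r),
               method = vc$method, converged = vc$converged)
  })
  do.call(rbind, rows)
}
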