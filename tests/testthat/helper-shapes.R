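# Shared fixtures, all generated in code. Expensive populations are cached
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# analytic circle contour (radius 1), closed
circle_contour <- function(n = 360, r = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(x = r * sin(th), y = r * cos(th))
}

ellipse_contour <- function(n = 360, a = 1, b = 2) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(x = a * sin(th), y = b * cos(th))
}

# rendered disc mask of given pixel radius
disc_mask <- function(radius_px = 150) {
  rasterize_contour(circle_contour(720), size = 2 * radius_px + 1)
}

# small rendered berry population on a continuous elongation gradient,
# reused across test files
small_population <- function() {
  cached("small_pop", {
    d <- population_design(n_genotypes = 20, n_harvests = 2, n_blocks = 2,
                           sigma2_G = 0.15, sigma2_E = 0.01, seed = 101)
    simulate_population(d)
  })
}

small_blocks <- function() {
  cached("small_blocks", extract_feature_blocks(small_population()$images))
}

# construct a cluster history of contiguous quantile bins along a 1-D
# gradient, with labels optionally scrambled per level
gradient_history <- function(x, K, perm_seed = NULL) {
  ks <- 2:K
  if (!is.null(perm_seed)) set.seed(perm_seed)
  asn <- list()
  for (k in ks) {
    bins <- cut(x, breaks = stats::quantile(x, seq(0, 1, length.out = k + 1)),
                include.lowest = TRUE, labels = FALSE)
    p <- if (is.null(perm_seed)) seq_len(k) else sample(k)
    asn[[paste0("k", k)]] <- p[bins]
  }
  structure(list(k_range = ks, assignments = asn, centroids = NULL,
                 wss = rep(0, length(ks)), n = length(x)),
            class = "cluster_history")
}

# random (unstructured) history for invariance properties
random_history <- function(n, K, seed) {
  set.seed(seed)
  asn <- list()
  for (k in 2:K) {
    lab <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    asn[[paste0("k", k)]] <- sample(lab)
  }
  structure(list(k_range = 2:K, assignments = asn, centroids = NULL,
                 wss = rep(0, K - 1), n = n), class = "cluster_history")
}

# independent EFA oracle: trapezoid integration of the Fourier coefficient
# integrals over the densified piecewise-linear curve
efa_oracle <- function(pts, H = 5, sub = 400) {
  p <- pts[-nrow(pts), , drop = FALSE]
  n <- nrow(p)
  seg <- sqrt(rowSums((rbind(p[-1, ], p[1, ]) - p)^2))
  t0 <- c(0, cumsum(seg))
  Ttot <- t0[n + 1]
  ts <- xs <- ys <- numeric(0)
  for (i in seq_len(n)) {
    u <- seq(0, 1, length.out = sub + 1)[-(sub + 1)]
    nxt <- if (i == n) 1 else i + 1
    ts <- c(ts, t0[i] + u * seg[i])
    xs <- c(xs, p[i, 1] + u * (p[nxt, 1] - p[i, 1]))
    ys <- c(ys, p[i, 2] + u * (p[nxt, 2] - p[i, 2]))
  }
  ts <- c(ts, Ttot); xs <- c(xs, p[1, 1]); ys <- c(ys, p[1, 2])
  trap <- function(f) sum(diff(ts) * (utils::head(f, -1) +
                                        utils::tail(f, -1)) / 2)
  out <- vapply(seq_len(H), function(h) {
    w <- 2 * pi * h / Ttot
    c(A = 2 / Ttot * trap(xs * cos(w * ts)),
      B = 2 / Ttot * trap(xs * sin(w * ts)),
      C = 2 / Ttot * trap(ys * cos(w * ts)),
      D = 2 / Ttot * trap(ys * sin(w * ts)))
  }, numeric(4))
  out
}

# best-matching permutation accuracy between cluster labels and truth
match_accuracy <- function(labels, truth) {
  k <- max(labels, truth)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, mean(p[labels] == truth))
  best
}
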