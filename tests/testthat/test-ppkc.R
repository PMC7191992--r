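test_that("progression matrix matches a brute-force tally and its column sums", {
  # 12-sample hand-built assignment table, focal k = 4
  asn <- list(k2 = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2),
              k3 = c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3, 3, 3),
              k4 = c(1, 1, 2, 2, 3, 3, 4, 4, 4, 3, 1, 2))
  h <- structure(list(k_range = 2:4, assignments = asn, centroids = NULL,
                      wss = rep(0, 3), n = 12), class = "cluster_history")
  M <- build_progression_matrix(h, 4)
  expect_equal(dim(unclass(M)), c((16 - 4) / 2 - 1, 4))
  # brute-force tally oracle
  oracle <- matrix(0, 5, 4)
  ri <- 0
  for (j in 2:3) for (c in seq_len(j)) {
    ri <- ri + 1
    for (f in 1:4)
      oracle[ri, f] <- sum(asn$k4 == f & asn[[paste0("k", j)]] == c) /
        sum(asn$k4 == f)
  }
  expect_equal(unclass(M), oracle, ignore_attr = TRUE)
  expect_equal(unname(colSums(M)), rep(2, 4))

  # nested refinement: proportions of a superset are exactly 1
  asn2 <- list(k2 = c(1, 1, 1, 1, 2, 2), k3 = c(1, 1, 2, 2, 3, 3))
  h2 <- structure(list(k_range = 2:3, assignments = asn2, centroids = NULL,
                       wss = rep(0, 2), n = 6), class = "cluster_history")
  M2 <- build_progression_matrix(h2, 3)
  expect_equal(unname(unclass(M2)[1, ]), c(1, 1, 0))
  expect_equal(unname(unclass(M2)[2, ]), c(0, 0, 1))

  expect_error(build_progression_matrix(h, 2), ">= 3")
})

test_that("column sums equal k - 2 exactly across random histories", {
  for (s in 1:20) {
    h <- random_history(n = 40, K = 6, seed = s)
    for (k in 3:6) {
      M <- build_progression_matrix(h, k)
      expect_equal(unname(colSums(M)), rep(k - 2, k))
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(nrow(M), (k^2 - k) / 2 - 1)
    }
  }
})

test_that("progression covariance matches a two-pass oracle and is PSD", {
  set.seed(8)
  M <- matrix(runif(20), 5, 4)
  S <- progression_covariance(M)
  # independent two-pass covariance
  two_pass <- matrix(0, 4, 4)
  mu <- colMeans(M)
  for (i in 1:4) for (j in 1:4)
    two_pass[i, j] <- sum((M[, i] - mu[i]) * (M[, j] - mu[j])) / 4
  expect_equal(unname(S), two_pass)
  expect_equal(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-9))

  # identical columns give a constant covariance matrix
  Mc <- matrix(rep(runif(5), 3), 5, 3)
  Sc <- progression_covariance(Mc)
  expect_lt(diff(range(Sc)), 1e-12)
})

test_that("principal_order ranks by the leading eigenvector up to reversal", {
  co <- principal_order(diag(c(3, 1)))
  expect_true(order_equivalent(co, c(1L, 2L)))
  expect_true(order_equivalent(co, c(2L, 1L)))

  # a 1-D chain of clusters is recovered from its constructed covariance
  set.seed(3)
  x <- runif(200)
  h <- gradient_history(x, 4)
  M <- build_progression_matrix(h, 4)
  co4 <- principal_order(progression_covariance(M))
  expect_true(order_equivalent(co4, 1:4))

  # reversal equivalence holds for arbitrary symmetric matrices
  for (s in 1:10) {
    set.seed(s)
    A <- crossprod(matrix(rnorm(25), 5))
    co <- principal_order(A)
    expect_true(order_equivalent(co$rank, length(co$rank) + 1L - co$rank))
  }

  # repeated leading eigenvalue warns
  expect_warning(principal_order(diag(c(2, 2, 1))), "degenerate")
})

test_that("ppkc recovers constructed gradients exactly for k = 3..6", {
  set.seed(42)
  x <- runif(300)
  for (K in 3:6) {
    h <- gradient_history(x, K, perm_seed = K * 7)
    pk <- ppkc(h, orient_stat = x)
    ordc <- pk$ordinal_assignments[[paste0("k", K)]]
    bins <- cut(x, breaks = stats::quantile(x, seq(0, 1,
                                                   length.out = K + 1)),
                include.lowest = TRUE, labels = FALSE)
    per_bin <- as.integer(unlist(tapply(ordc, bins, unique)))
    expect_length(per_bin, K)
    expect_true(order_equivalent(per_bin, seq_len(K)),
                label = sprintf("gradient recovered at k=%d", K))
  }
})

test_that("ppkc is invariant to cluster-label permutation", {
  set.seed(13)
  x <- runif(150)
  h <- gradient_history(x, 5)
  base <- ppkc(h)
  for (s in 1:10) {
    hp <- gradient_history(x, 5, perm_seed = 100 + s)
    pk <- ppkc(hp)
    for (k in 3:5) {
      a <- base$ordinal_assignments[[paste0("k", k)]]
      b <- pk$ordinal_assignments[[paste0("k", k)]]
      expect_true(identical(a, b) || identical(a, max(b) + 1L - b),
                  label = sprintf("label invariance at k=%d seed=%d", k, s))
    }
  }
})

test_that("duplicated clusters trigger the convergence diagnostic", {
  set.seed(21)
  x <- runif(200)
  h <- gradient_history(x, 4)
  # split the last-level bins randomly (not along the gradient): the two
  # halves of a bin have identical ancestry profiles
  k5 <- h$assignments$k4
  top <- which(k5 == 4)
  k5[sample(top, length(top) %/% 2)] <- 5L
  h$assignments$k5 <- k5
  h$k_range <- 2:5
  pk <- ppkc(h, gap_tol = 0.01)
  expect_true(pk$converged_pairs$k5)
  co <- pk$orders$k5
  v <- sort(co$eigvec)
  expect_lt(min(diff(v)) / diff(range(v)), 0.01)
})
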