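test_that("trace_contour is closed, clockwise, and metrically accurate", {
  sq <- matrix(1L, 10, 10)
  ct <- trace_contour(sq)
  expect_equal(ct[1, ], ct[nrow(ct), ])
  p <- berryshape:::contour_perimeter(ct)
  expect_lt(abs(p - 40) / 40, 0.05)

  # disc: all contour radii within 2% of nominal
  d <- disc_mask(150)
  ctd <- trace_contour(d)
  ctr <- colMeans(ctd[-nrow(ctd), ])
  radii <- sqrt(rowSums(sweep(ctd[-nrow(ctd), ], 2, ctr)^2))
  expect_lt(max(abs(radii - 150)) / 150, 0.02)

  # starts at the topmost point
  expect_equal(unname(ctd[1, 2]), min(ctd[, 2]), tolerance = 1)

  # two components rejected
  two <- matrix(0L, 20, 20)
  two[2:5, 2:5] <- 1L; two[12:18, 12:18] <- 1L
  expect_error(trace_contour(two), "multiple components")
})

test_that("linear features reproduce analytic values on reference shapes", {
  d <- disc_mask(200)
  lf <- linear_features(d)
  expect_lt(abs(lf[["Circ"]] - 1), 0.01)
  expect_lt(abs(lf[["Round"]] - 1), 0.01)
  expect_lt(abs(lf[["AR"]] - 1), 0.01)
  expect_lt(abs(lf[["Solid"]] - 1), 0.01)
  expect_lt(abs(lf[["FAR"]] - 1), 0.02)
  expect_lt(abs(lf[["HW"]] - 0.5), 0.02)
  expect_equal(lf[["Skew"]], 0, tolerance = 0.01)

  sq <- matrix(1L, 300, 300)
  lfs <- linear_features(sq)
  expect_lt(abs(lfs[["Circ"]] - pi / 4) / (pi / 4), 0.02)
  expect_equal(lfs[["BAR"]], 1)
  expect_equal(lfs[["SI"]], 1)

  e <- rasterize_contour(ellipse_contour(720), size = 400)
  lfe <- linear_features(e)
  expect_lt(abs(lfe[["AR"]] - 2) / 2, 0.02)
  expect_lt(abs(lfe[["SI"]] - 2) / 2, 0.02)
  expect_lt(abs(lfe[["BAR"]] - 0.5) / 0.5, 0.02)
})

test_that("size-free descriptors are scale invariant within discretization", {
  ct <- berry_outline(e = 1.4, a1 = 0.22, a2 = 0.12, n_points = 300)
  small <- linear_features(rasterize_contour(ct, size = 120))
  large <- linear_features(rasterize_contour(ct, size = 360))
  for (f in c("Circ", "AR", "Round", "Solid", "FAR", "BAR", "SI", "HW"))
    expect_lt(abs(small[[f]] - large[[f]]) / abs(large[[f]]), 0.02,
              label = sprintf("scale invariance of %s", f))
})

test_that("elliptical Fourier coefficients match the integration oracle", {
  bean <- berry_outline(e = 1.4, a1 = 0.25, a2 = 0.15, n_points = 200)
  ef <- elliptical_fourier(bean, 5)
  orc <- efa_oracle(bean, 5, sub = 400)
  got <- rbind(ef$an, ef$bn, ef$cn, ef$dn)
  expect_lt(max(abs(got - orc[c("A", "B", "C", "D"), ])), 1e-8)

  # circle: single harmonic to machine precision
  circ <- berry_outline(e = 1, n_points = 256)
  efc <- elliptical_fourier(circ, 5)
  h1 <- sqrt(efc$bn[1]^2 + efc$cn[1]^2)
  rest <- max(abs(c(efc$an[-1], efc$bn[-1], efc$cn[-1], efc$dn[-1])))
  expect_lt(rest / h1, 1e-10)

  # 2:1 ellipse: first harmonic dominates (arc-length parametrization
  # leaves a small known remainder in higher harmonics)
  ell <- berry_outline(e = 2, n_points = 256)
  efe <- elliptical_fourier(ell, 5)
  e1 <- sum(c(efe$an[1], efe$bn[1], efe$cn[1], efe$dn[1])^2)
  ehi <- sum(c(efe$an[-1], efe$bn[-1], efe$cn[-1], efe$dn[-1])^2)
  expect_lt(ehi / e1, 0.01)

  # reconstruction error non-increasing in harmonic count
  lm <- pseudo_landmarks(structure(bean,
                                   class = c("shape_contour", "matrix")),
                         n = 200)
  ref <- rbind(lm, lm[1, ])
  errs <- vapply(1:5, function(H) {
    rec <- efa_reconstruct(ef, n_points = 200, n_harmonics = H)
    mean(sqrt(rowSums((rec[-201, ] - ref[-201, ])^2)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))

  expect_error(elliptical_fourier(bean[-nrow(bean), ]), "closed")
})

test_that("pca models satisfy their contracts and the SVD oracle", {
  set.seed(6)
  X <- matrix(rnorm(40 * 12), 40)
  m <- fit_pca(X, 12)
  # orthonormal loadings
  expect_lt(max(abs(crossprod(m$loadings) - diag(m$n_components))), 1e-8)
  # eigenvalues descending, conserve total variance
  expect_true(all(diff(m$eigenvalues) <= 1e-9))
  expect_equal(sum(m$eigenvalues), sum(apply(X, 2, stats::var)),
               tolerance = 1e-6)
  # score variances equal eigenvalues
  expect_equal(unname(apply(m$scores, 2, stats::var)),
               m$eigenvalues[1:m$n_components], tolerance = 1e-8)
  # SVD oracle up to sign
  sv <- svd(scale(X, scale = FALSE))
  for (j in 1:3) {
    a <- m$scores[, j]; b <- sv$u[, j] * sv$d[j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  # projection equals direct multiplication, training rows reproduce scores
  new <- matrix(rnorm(5 * 12), 5)
  expect_equal(project_pca(m, new),
               sweep(new, 2, colMeans(X)) %*% m$loadings)
  expect_equal(project_pca(m, X), m$scores, tolerance = 1e-10)

  # identical rows: degenerate input errors
  expect_error(fit_pca(matrix(1, 10, 4), 2), "degenerate")
  # rank-1 data: PC1 carries all variance
  r1 <- outer(rnorm(15), c(1, 2, 3))
  mr <- suppressWarnings(fit_pca(r1, 3))
  expect_equal(mr$pct_var[1], 100, tolerance = 1e-8)
})

test_that("pseudo-landmarks are equally spaced from the topmost point", {
  ct <- trace_contour(disc_mask(120))
  lm <- pseudo_landmarks(ct, 50)
  expect_equal(dim(lm), c(50, 2))
  # consecutive arc lengths equal within 1%
  seg <- sqrt(rowSums((rbind(lm[-1, ], lm[1, ]) - lm)^2))
  expect_lt((max(seg) - min(seg)) / mean(seg), 0.02)
  # landmark 1 near the topmost contour point
  expect_lt(abs(lm[1, 2] - min(ct[, 2])), 2)
  # circle: uniform angular spacing 7.2 degrees
  ctr <- colMeans(lm)
  ang <- atan2(lm[, 1] - ctr[1], -(lm[, 2] - ctr[2]))
  dd <- diff(sort(ang)) * 180 / pi
  expect_lt(max(abs(dd - 7.2)), 0.5)
})

test_that("gpa alignment removes rotation, translation and scale", {
  set.seed(12)
  base <- pseudo_landmarks(trace_contour(disc_mask(80)), 30)
  base[5, ] <- base[5, ] + c(8, -4)  # break rotational symmetry
  sets <- lapply(1:8, function(i) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    s <- runif(1, 0.5, 2)
    sweep(s * base %*% R, 2, runif(2, -20, 20), `+`)
  })
  g <- gpa_align(sets)
  for (i in 2:8)
    expect_lt(max(abs(g$aligned[i, , ] - g$aligned[1, , ])), 1e-6)

  # mean of two mirror images is mirror symmetric
  b2 <- pseudo_landmarks(trace_contour(
    rasterize_contour(berry_outline(1.3, 0.2, 0.1, 200), 150)), 40)
  mir <- cbind(-b2[, 1], b2[, 2])
  # reorder mirrored landmarks to run the same direction
  mir <- mir[c(1, 40:2), ]
  gm <- gpa_align(list(b2, mir))$mean_shape
  mm <- cbind(-gm[, 1], gm[, 2])[c(1, 40:2), ]
  expect_lt(max(abs(gm - mm)), 1e-6)

  # sample order invariance
  sets2 <- sets[c(3, 1, 2, 5, 4, 8, 7, 6)]
  g2 <- gpa_align(sets2)
  expect_lt(max(abs(g2$mean_shape - g$mean_shape)), 1e-6)

  expect_error(gpa_align(list(base, base[1:10, ])), "unequal")
})

test_that("per-landmark pca flags high-variance landmarks by the median rule", {
  set.seed(17)
  n <- 30; p <- 12
  arr <- array(rnorm(n * p * 2, sd = 0.01), dim = c(n, p, 2))
  # landmarks 1-3 vary strongly along a known axis
  dirs <- c(1, 2) / sqrt(5)
  amp <- rnorm(n, sd = 2)
  for (l in 1:3) {
    arr[, l, 1] <- arr[, l, 1] + amp * dirs[1]
    arr[, l, 2] <- arr[, l, 2] + amp * dirs[2]
  }
  lp <- landmark_pca(arr)
  expect_true(all(lp$high_variance[1:3]))
  expect_lte(sum(lp$high_variance), p / 2)
  # PC1 axis matches a covariance-eigen oracle
  S <- stats::cov(arr[, 1, ])
  v <- eigen(S, symmetric = TRUE)$vectors[, 1]
  dotp <- abs(sum(v * lp$axes[1, ]))
  expect_equal(dotp, 1, tolerance = 1e-8)
  # constant landmark: zero SD, never flagged
  arr[, p, 1] <- 0; arr[, p, 2] <- 0
  lp2 <- landmark_pca(arr)
  expect_equal(lp2$pc1_sd[p], 0)
  expect_false(lp2$high_variance[p])
})

test_that("latent region scores are unit variance and track neck amplitude", {
  set.seed(23)
  n <- 40
  a2s <- runif(n, 0, 0.35)
  imgs <- berryshape:::render_berries(rep(1.2, n), rep(0.1, n), a2s,
                                      sprintf("s%02d", 1:n))
  blocks <- extract_feature_blocks(imgs)
  g <- gpa_align(blocks$landmarks)
  lp <- landmark_pca(g$aligned)
  lat <- latent_region_scores(lp$pc1_scores)
  expect_equal(unname(apply(lat$scores, 2, stats::sd)), rep(1, 5),
               tolerance = 1e-8)
  expect_gte(abs(stats::cor(lat$scores[, "Neck"], a2s)), 0.8)
  # identical samples: no variance to analyze
  same <- lp$pc1_scores[rep(1, 10), ]
  expect_error(latent_region_scores(same))
})

test_that("biomass profiles count pixels by row and column", {
  px <- matrix(1L, 100, 100)
  bp <- biomass_profiles(px)
  expect_equal(bp$horizontal, rep(100L, 100))
  expect_equal(bp$vertical, rep(100L, 100))
  set.seed(2)
  px2 <- matrix(rbinom(10000, 1, 0.3), 100)
  bp2 <- biomass_profiles(px2)
  expect_equal(sum(bp2$horizontal), sum(px2))
  expect_equal(sum(bp2$vertical), sum(px2))
  bpt <- biomass_profiles(t(px2))
  expect_equal(bpt$horizontal, bp2$vertical)
  expect_equal(bpt$vertical, bp2$horizontal)
})

test_that("the assembled feature table has the documented registry", {
  blocks <- small_blocks()
  fm <- fit_feature_models(blocks)
  ft <- fm$features
  expect_equal(ncol(ft) - 1, 66)
  reg <- attr(ft, "registry")
  expect_equal(reg$enumerated, 66L)
  expect_equal(reg$of_record, 68L)
  expect_true(all(c("SI", "Circ", "BAR", "AR", "Round", "Solid", "FAR",
                    "HW", "Var", "Skew", "Kurt", "EFAPC1", "EFAPC20",
                    "Tip", "Neck", "SideLeft", "SideRight", "Shape",
                    "EigenFruitPC1", "EigenFruitPC20", "BioHPC1",
                    "BioHPC5", "BioVPC1", "BioVPC5") %in% names(ft)))
  expect_false(anyNA(ft))
  # correlation companion output
  fc <- feature_correlations(ft)
  expect_true(all(fc$r >= -1 & fc$r <= 1))
  expect_true(all(fc$p_bonferroni >= fc$p - 1e-15))
  # strongly elongation-varying data: eigen-image PC1 and vertical-profile
  # PC1 describe the same gradient
  r <- stats::cor(ft$EigenFruitPC1, ft$BioVPC1)
  expect_gt(abs(r), 0.5)
})
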