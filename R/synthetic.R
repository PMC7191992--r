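# Parametric berry shapes: a truncated cosine-series radius
#   r(theta) = 1 + a1 cos(theta) + a2 cos(2 theta)
# drawn in polar form and scaled anisotropically so elongation e controls the
# height/width ratio. a1 modulates the tip (theta = 0, top of the fruit), a2
# the neck/shoulder region. Three parameters span the visual prolate -> oblate
# gradient of real berries.

#' Closed outline of a parametric berry
#'
#' The contour is \eqn{(x, y) = (r(\theta)\sin\theta,\; e\, r(\theta)\cos\theta)}
#' with \eqn{r(\theta) = 1 + a_1\cos\theta + a_2\cos 2\theta}, sampled
#' clockwise from the top (\eqn{\theta = 0}) and closed (first point repeated
#' as last). The curve is centered on its analytic centroid.
#'
#' @param e elongation: height/width ratio of the base shape (> 0).
#' @param a1 tip amplitude (cos theta term).
#' @param a2 neck amplitude (cos 2 theta term); `|a1| + |a2| < 1` keeps the
#'   radius positive.
#' @param n_points number of distinct contour points (>= 20).
#' @return (n_points + 1) x 2 matrix of x, y coordinates, columns named.
#' @export
berry_outline <- function(e = 1, a1 = 0, a2 = 0, n_points = 200) {
  if (e <= 0) stop("elongation must be positive")
  theta <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  r <- 1 + a1 * cos(theta) + a2 * cos(2 * theta)
  if (any(r <= 0)) stop("self-intersecting shape")
  x <- r * sin(theta)
  y <- e * r * cos(theta)
  # centroid of the polygon (shoelace), subtracted so shapes are centered
  xs <- c(x, x[1]); ys <- c(y, y[1])
  cr <- xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)]
  A <- sum(cr) / 2
  cx <- sum((xs[-length(xs)] + xs[-1]) * cr) / (6 * A)
  cy <- sum((ys[-length(ys)] + ys[-1]) * cr) / (6 * A)
  out <- cbind(x = x - cx, y = y - cy)
  rbind(out, out[1, , drop = FALSE])
}

#' Rasterize a closed contour to a binary mask
#'
#' Pixels whose centers fall inside the polygon become foreground; the result
#' is cropped to the foreground bounding box. The contour is scaled so its
#' larger extent spans `size` pixels.
#'
#' @param contour closed 2-column matrix of x, y points.
#' @param size target extent of the larger dimension, in pixels.
#' @return a `binary_mask`.
#' @export
rasterize_contour <- function(contour, size = 200) {
  if (!is.matrix(contour) || ncol(contour) != 2 || nrow(contour) < 4)
    stop("degenerate contour")
  x <- contour[, 1]; y <- contour[, 2]
  rx <- diff(range(x)); ry <- diff(range(y))
  if (rx <= 0 || ry <= 0) stop("degenerate contour")
  sc <- (size - 1) / max(rx, ry)
  px <- (x - min(x)) * sc + 1
  py <- (y - min(y)) * sc + 1
  w <- ceiling(max(px)); h <- ceiling(max(py))
  # center the polygon in the pixel grid so mirror-symmetric contours see a
  # symmetric sampling of pixel centers
  px <- px + (w - max(px)) / 2
  py <- py + (h - max(py)) / 2
  grid <- expand.grid(gx = seq_len(w), gy = seq_len(h))
  inside <- pracma::inpolygon(grid$gx, grid$gy, px, py, boundary = TRUE)
  m <- matrix(0L, h, w)
  # image row 1 is the top: flip y so larger y in contour space is higher
  m[cbind(h - grid$gy[inside] + 1L, grid$gx[inside])] <- 1L
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  as_binary_mask(m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE])
}

#' Population design for the berry simulator
#'
#' @param n_genotypes,n_harvests,n_blocks,fruits_per_plot design counts.
#' @param sigma2_G genetic variance of the elongation gradient parameter.
#' @param sigma2_E residual (plot-level) variance of the gradient parameter.
#' @param harvest_effects,block_effects fixed offsets (length n_harvests /
#'   n_blocks; recycled zeros by default).
#' @param seed integer seed controlling every draw.
#' @return a `population_design` list.
#' @export
population_design <- function(n_genotypes, n_harvests = 2, n_blocks = 3,
                              fruits_per_plot = 1,
                              sigma2_G = 0.1, sigma2_E = 0.02,
                              harvest_effects = rep(0, n_harvests),
                              block_effects = rep(0, n_blocks),
                              seed = 1) {
  stopifnot(n_genotypes >= 1, n_harvests >= 1, n_blocks >= 1,
            fruits_per_plot >= 1, sigma2_G >= 0, sigma2_E >= 0)
  structure(list(n_genotypes = n_genotypes, n_harvests = n_harvests,
                 n_blocks = n_blocks, fruits_per_plot = fruits_per_plot,
                 sigma2_G = sigma2_G, sigma2_E = sigma2_E,
                 harvest_effects = harvest_effects,
                 block_effects = block_effects, seed = as.integer(seed)),
            class = "population_design")
}

#' Simulate a replicated berry population along the elongation gradient
#'
#' Per genotype a genetic effect g_i ~ N(0, sigma2_G) is drawn once; each
#' plot (genotype x harvest x block) receives an independent residual
#' ~ N(0, sigma2_E). A fruit's elongation is
#' `e_mid + g_i + harvest + block + residual`, clipped to `[0.4, 2.5]`
#' (clipped samples flagged). Tip and neck amplitudes vary mildly with a
#' small deterministic trend plus noise so non-elongation features carry
#' signal too.
#'
#' @param design a [population_design()].
#' @param gradient length-2 range of target elongation; its midpoint anchors
#'   the population mean.
#' @param render if `TRUE` (default) rasterize and normalize each fruit to a
#'   `normalized_image`; if `FALSE` only the truth table and records are
#'   returned (fast path for variance-component studies).
#' @param raster_px rasterization extent passed to [rasterize_contour()].
#' @param out_px side of the normalized raster.
#' @return list with `images` (or `NULL`), `records` (data.frame sample_id,
#'   genotype, harvest, block, plot) and `truth` (per-sample e, a1, a2,
#'   genetic effect, clipped flag).
#' @export
simulate_population <- function(design, gradient = c(0.7, 1.8),
                                render = TRUE, raster_px = 160,
                                out_px = 100) {
  stopifnot(inherits(design, "population_design"))
  n <- design$n_genotypes * design$n_harvests * design$n_blocks *
    design$fruits_per_plot
  if (n < 1) stop("empty design")
  set.seed(design$seed)
  e_mid <- mean(gradient)
  g <- rnorm(design$n_genotypes, 0, sqrt(design$sigma2_G))
  rec <- expand.grid(fruit = seq_len(design$fruits_per_plot),
                     block = seq_len(design$n_blocks),
                     harvest = seq_len(design$n_harvests),
                     genotype = seq_len(design$n_genotypes))
  rec <- rec[, c("genotype", "harvest", "block", "fruit")]
  plot_id <- paste(rec$genotype, rec$harvest, rec$block, sep = "_")
  up <- !duplicated(plot_id)
  resid_plot <- setNames(rnorm(sum(up), 0, sqrt(design$sigma2_E)),
                         plot_id[up])
  e_raw <- e_mid + g[rec$genotype] +
    design$harvest_effects[rec$harvest] +
    design$block_effects[rec$block] +
    resid_plot[plot_id]
  e <- pmin(pmax(e_raw, 0.4), 2.5)
  clipped <- e != e_raw
  # mild tip/neck variation correlated with nothing genetic by default
  a1 <- pmax(pmin(0.12 + rnorm(n, 0, 0.02), 0.35), -0.35)
  a2 <- pmax(pmin(0.08 + rnorm(n, 0, 0.02), 0.9 - abs(a1)), 0)
  sample_id <- sprintf("s%05d", seq_len(n))
  records <- data.frame(sample_id = sample_id,
                        genotype = sprintf("g%04d", rec$genotype),
                        harvest = sprintf("h%d", rec$harvest),
                        block = sprintf("b%d", rec$block),
                        plot = plot_id,
                        stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sample_id, e = e, e_raw = e_raw,
                      a1 = a1, a2 = a2,
                      g_effect = g[rec$genotype], clipped = clipped,
                      stringsAsFactors = FALSE)
  images <- NULL
  if (render) {
    images <- render_berries(e, a1, a2, sample_id, raster_px, out_px)
  }
  list(images = images, records = records, truth = truth)
}

render_berries <- function(e, a1, a2, ids, raster_px = 160, out_px = 100) {
  lapply(seq_along(e), function(i) {
    ct <- berry_outline(e = e[i], a1 = a1[i], a2 = a2[i], n_points = 180)
    normalize_mask(rasterize_contour(ct, size = raster_px),
                   source_id = ids[i], out_px = out_px, scale_px = NULL)
  })
}

#' Simulate well-separated ordinal shape classes
#'
#' Generates `n_per_class` berries at each of the `e_levels` elongations
#' (the four defaults span the prolate -> oblate gradient with wide
#' separation), with small within-class jitter on elongation, tip and neck.
#' This is the reference population for testing cluster recovery, ordinal
#' progression, and the classification protocol.
#'
#' @param n_per_class samples per class.
#' @param e_levels ordered elongation levels, one per class.
#' @param sd_within within-class elongation standard deviation.
#' @param seed integer seed.
#' @param raster_px,out_px rendering resolution.
#' @return list with `images`, `classes` (true ordinal class per sample,
#'   1 = most elongated level first in `e_levels`), and `truth`.
#' @export
simulate_shape_classes <- function(n_per_class = 125,
                                   e_levels = c(0.55, 0.95, 1.45, 2.1),
                                   sd_within = 0.04, seed = 1,
                                   raster_px = 160, out_px = 100) {
  set.seed(seed)
  n <- n_per_class * length(e_levels)
  cls <- rep(seq_along(e_levels), each = n_per_class)
  e <- pmax(e_levels[cls] + rnorm(n, 0, sd_within), 0.3)
  a1 <- pmin(pmax(0.12 + rnorm(n, 0, 0.015), -0.3), 0.3)
  a2 <- pmin(pmax(0.08 + rnorm(n, 0, 0.015), 0), 0.5)
  ids <- sprintf("c%d_%04d", cls, seq_len(n))
  images <- render_berries(e, a1, a2, ids, raster_px, out_px)
  list(images = images, classes = cls,
       truth = data.frame(sample_id = ids, class = cls, e = e, a1 = a1,
                          a2 = a2, stringsAsFactors = FALSE))
}
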