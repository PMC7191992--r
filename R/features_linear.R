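# Linear and geometric shape descriptors measured on the normalized raster
# and its traced outline.

polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# rotating-calipers Feret diameters over convex-hull vertices
feret_diameters <- function(pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  m <- nrow(hull)
  dmax <- 0
  for (i in seq_len(m - 1)) {
    d <- sqrt((hull[(i + 1):m, 1] - hull[i, 1])^2 +
                (hull[(i + 1):m, 2] - hull[i, 2])^2)
    dmax <- max(dmax, d)
  }
  # min Feret: the minimum width is attained perpendicular to a hull edge
  wmin <- Inf
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) next
    nrm <- c(-e[2], e[1]) / len
    proj <- hull %*% nrm
    wmin <- min(wmin, diff(range(proj)))
  }
  c(feret = dmax, min_feret = wmin)
}

#' Linear and geometric features of one fruit
#'
#' Computes the 11 scalar descriptors: shape index SI (bounding-box
#' height/width), circularity Circ = 4 pi A / P^2, bounding aspect ratio
#' BAR (width/height), best-fit-ellipse aspect ratio AR = major/minor,
#' roundness Round = 4 A / (pi major^2), solidity Solid = A / convex hull
#' area, Feret aspect ratio FAR = Feret/MinFeret, HW = height of the widest
#' row above the base divided by total height, and Var / Skew / Kurt, the
#' central moments of the marginal foreground distribution along the
#' horizontal axis (Kurt is excess kurtosis). The best-fit ellipse is the
#' ellipse with the same second-order pixel moments; its major axis is
#' 4 sqrt(lambda_1) of the pixel-coordinate covariance.
#'
#' @param img a `normalized_image` or binary matrix.
#' @param contour optional pre-traced [trace_contour()] result.
#' @return named numeric vector of length 11.
#' @export
linear_features <- function(img, contour = NULL) {
  px <- if (inherits(img, "normalized_image")) img$pixels else img
  if (is.null(contour)) contour <- trace_contour(px)
  pts <- unclass(contour)
  A <- sum(px)
  P <- contour_perimeter(contour)
  idx <- which(px == 1L, arr.ind = TRUE)  # [,1] row = y, [,2] col = x
  rows <- range(idx[, 1]); cols <- range(idx[, 2])
  height <- rows[2] - rows[1] + 1L
  width <- cols[2] - cols[1] + 1L
  # second-moment ellipse
  S <- stats::cov(idx[, c(2, 1)]) * (nrow(idx) - 1) / nrow(idx)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  major <- 4 * sqrt(max(ev[1], 0))
  minor <- 4 * sqrt(max(ev[2], 0))
  if (minor <= 0) stop("degenerate ellipse")
  hull_pts <- pts[-nrow(pts), , drop = FALSE]
  hull_area <- polygon_area(hull_pts[grDevices::chull(hull_pts), ,
                                     drop = FALSE])
  fd <- feret_diameters(hull_pts)
  # widest row, measured upward from the base (bottom of the fruit);
  # ties over a flat maximum are averaged so the statistic is stable
  rs <- rowSums(px)[rows[1]:rows[2]]
  widest <- mean(which(rs == max(rs))) + rows[1] - 1
  hw <- (rows[2] - widest) / (height - 1L)
  # marginal distribution over columns (horizontal axis)
  w <- colSums(px)
  p <- w / sum(w)
  xs <- seq_along(w)
  mu <- sum(p * xs)
  v <- sum(p * (xs - mu)^2)
  sk <- sum(p * (xs - mu)^3) / v^1.5
  ku <- sum(p * (xs - mu)^4) / v^2 - 3
  c(SI = height / width,
    Circ = 4 * pi * A / P^2,
    BAR = width / height,
    AR = major / minor,
    Round = 4 * A / (pi * major^2),
    Solid = A / hull_area,
    FAR = unname(fd["feret"] / fd["min_feret"]),
    HW = hw,
    Var = v, Skew = sk, Kurt = ku)
}
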