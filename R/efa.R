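# Elliptical Fourier analysis (Kuhl & Giardina) of closed outlines.
#
# Each harmonic h contributes four coefficients: A_h, B_h for x(t) and
# C_h, D_h for y(t), with t the cumulative chord length along the outline.

#' Elliptical Fourier coefficients of a closed contour
#'
#' Piecewise-linear (chord-length) Kuhl-Giardina formulation. Because inputs
#' are already scale- and orientation-normalized rasters, no first-harmonic
#' normalization is applied unless `normalize = TRUE`.
#'
#' @param contour closed 2-column matrix (first point = last). Resampling to
#'   at least 100 evenly spaced points is recommended upstream.
#' @param n_harmonics number of harmonics (default 5, giving 20
#'   coefficients).
#' @param normalize apply first-harmonic rotation/scale normalization.
#' @return an `efa_coefficients` object: list with matrices `an, bn, cn, dn`
#'   (length n_harmonics each), the DC terms `a0, c0`, and `total_length`.
#' @export
elliptical_fourier <- function(contour, n_harmonics = 5, normalize = FALSE) {
  pts <- unclass(contour)
  if (!all(pts[1, ] == pts[nrow(pts), ])) stop("contour must be closed")
  pts <- pts[-nrow(pts), , drop = FALSE]
  n <- nrow(pts)
  dx <- diff(c(pts[, 1], pts[1, 1]))
  dy <- diff(c(pts[, 2], pts[1, 2]))
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > .Machine$double.eps
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  T <- t1[length(t1)]
  an <- bn <- cn <- dn <- numeric(n_harmonics)
  for (h in seq_len(n_harmonics)) {
    w <- 2 * pi * h / T
    const <- T / (2 * pi^2 * h^2)
    an[h] <- const * sum(dx / dt * (cos(w * t1) - cos(w * t0)))
    bn[h] <- const * sum(dx / dt * (sin(w * t1) - sin(w * t0)))
    cn[h] <- const * sum(dy / dt * (cos(w * t1) - cos(w * t0)))
    dn[h] <- const * sum(dy / dt * (sin(w * t1) - sin(w * t0)))
  }
  # DC components
  xi <- cumsum(dx) - dx / 2
  a0 <- pts[1, 1] + sum(dt * xi) / T
  eta <- cumsum(dy) - dy / 2
  c0 <- pts[1, 2] + sum(dt * eta) / T
  out <- list(an = an, bn = bn, cn = cn, dn = dn, a0 = a0, c0 = c0,
              total_length = T, normalized = FALSE)
  class(out) <- "efa_coefficients"
  if (normalize) out <- efa_normalize(out)
  out
}

# First-harmonic (Kuhl) normalization: rotate to the first ellipse's major
# axis, start phase at its end, and scale by its semi-major length.
efa_normalize <- function(ef) {
  a1 <- ef$an[1]; b1 <- ef$bn[1]; c1 <- ef$cn[1]; d1 <- ef$dn[1]
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  ct <- cos(theta); st <- sin(theta)
  a1s <- a1 * ct + b1 * st
  c1s <- c1 * ct + d1 * st
  scale <- sqrt(a1s^2 + c1s^2)
  psi <- atan2(c1s, a1s)
  cp <- cos(psi); sp <- sin(psi)
  H <- length(ef$an)
  for (h in seq_len(H)) {
    m <- matrix(c(cp, sp, -sp, cp), 2) %*%
      matrix(c(ef$an[h], ef$cn[h], ef$bn[h], ef$dn[h]), 2) %*%
      matrix(c(cos(h * theta), -sin(h * theta),
               sin(h * theta), cos(h * theta)), 2)
    ef$an[h] <- m[1, 1] / scale; ef$bn[h] <- m[1, 2] / scale
    ef$cn[h] <- m[2, 1] / scale; ef$dn[h] <- m[2, 2] / scale
  }
  ef$normalized <- TRUE
  ef
}

#' Flatten EFA coefficients to the 20-element named vector
#'
#' Order: A1..AH, B1..BH, C1..CH, D1..DH.
#'
#' @param ef an `efa_coefficients` object.
#' @return named numeric vector of length 4 x n_harmonics.
#' @export
efa_vector <- function(ef) {
  H <- length(ef$an)
  setNames(c(ef$an, ef$bn, ef$cn, ef$dn),
           c(paste0("A", 1:H), paste0("B", 1:H),
             paste0("C", 1:H), paste0("D", 1:H)))
}

#' Reconstruct a contour from EFA coefficients
#'
#' @param ef an `efa_coefficients` object.
#' @param n_points points on the reconstructed outline.
#' @param n_harmonics harmonics to use (default all available).
#' @return closed (n_points + 1) x 2 matrix.
#' @export
efa_reconstruct <- function(ef, n_points = 300,
                            n_harmonics = length(ef$an)) {
  t <- seq(0, 1, length.out = n_points + 1L)
  x <- rep(ef$a0, length(t)); y <- rep(ef$c0, length(t))
  for (h in seq_len(n_harmonics)) {
    x <- x + ef$an[h] * cos(2 * pi * h * t) + ef$bn[h] * sin(2 * pi * h * t)
    y <- y + ef$cn[h] * cos(2 * pi * h * t) + ef$dn[h] * sin(2 * pi * h * t)
  }
  cbind(x = x, y = y)
}
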