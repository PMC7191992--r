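# Sub-pixel outline tracing and pseudo-landmark placement.
#
# Contours live in image coordinates: x = column, y = row, y increasing
# downward. "Clockwise" means clockwise as the image is displayed.

#' Trace the sub-pixel outline of a normalized image
#'
#' Marching squares at the 0.5 level on the zero-padded pixel grid. The
#' contour is closed (first point repeated last), clockwise in display
#' orientation, and starts at the topmost boundary point (leftmost on tie).
#'
#' Marching squares on a binary raster leaves staircase jitter that biases
#' the perimeter upward by about 5%; a few passes of a (1,2,1)/4 moving
#' average along the closed polygon remove it. The number of passes adapts
#' to the contour length (roughly one pass per 60 points, at most 30) so
#' small outlines are not over-rounded; `smooth_iters` overrides it.
#'
#' @param img a `normalized_image` or binary matrix with a single connected
#'   foreground component.
#' @param smooth_iters smoothing passes; `NULL` (default) for adaptive.
#' @return a `shape_contour`: (m + 1) x 2 matrix of x, y image coordinates.
#' @export
trace_contour <- function(img, smooth_iters = NULL) {
  px <- if (inherits(img, "normalized_image")) img$pixels else img
  lab <- EBImage::bwlabel(EBImage::Image(t(px)))
  if (max(lab) > 1) stop("multiple components; trace one fruit at a time")
  if (max(lab) < 1) stop("no foreground")
  h <- nrow(px); w <- ncol(px)
  z <- matrix(0, h + 2L, w + 2L)
  z[2:(h + 1L), 2:(w + 1L)] <- px
  # contourLines: x along rows of z, y along columns
  cl <- grDevices::contourLines(x = seq_len(h + 2L), y = seq_len(w + 2L),
                                z = z, levels = 0.5)
  if (!length(cl)) stop("no contour found")
  lens <- vapply(cl, function(p) length(p$x), numeric(1))
  p <- cl[[which.max(lens)]]
  # p$x follows matrix rows (image y), p$y matrix columns (image x);
  # undo the 1-pixel pad
  pts <- cbind(x = p$y - 1, y = p$x - 1)
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 3) stop("degenerate contour")
  if (is.null(smooth_iters))
    smooth_iters <- min(30L, floor(nrow(pts) / 60))
  if (smooth_iters > 0) {
    n <- nrow(pts)
    for (i in seq_len(smooth_iters)) {
      up <- pts[c(2:n, 1), , drop = FALSE]
      dn <- pts[c(n, 1:(n - 1)), , drop = FALSE]
      pts <- (2 * pts + up + dn) / 4
    }
  }
  # enforce clockwise display orientation: with y down, clockwise visual
  # traversal has positive shoelace area in (x, y-down) coordinates
  a2 <- sum(pts[, 1] * c(pts[-1, 2], pts[1, 2]) -
              c(pts[-1, 1], pts[1, 1]) * pts[, 2])
  if (a2 < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  # rotate start to topmost (min y), leftmost on tie
  i0 <- which(pts[, 2] == min(pts[, 2]))
  i0 <- i0[which.min(pts[i0, 1])]
  pts <- pts[c(i0:nrow(pts), seq_len(i0 - 1L)), , drop = FALSE]
  out <- rbind(pts, pts[1, , drop = FALSE])
  class(out) <- c("shape_contour", "matrix")
  out
}

contour_perimeter <- function(contour) {
  d <- diff(unclass(contour))
  sum(sqrt(rowSums(d^2)))
}

#' Place equally spaced pseudo-landmarks along a closed contour
#'
#' Landmarks are spaced at equal arc length, moving clockwise, with landmark
#' 1 at the contour start (the topmost point, adjacent to the fruit tip).
#'
#' @param contour a closed `shape_contour`.
#' @param n number of landmarks (default 50).
#' @return n x 2 matrix of x, y coordinates.
#' @export
pseudo_landmarks <- function(contour, n = 50) {
  pts <- unclass(contour)
  if (!all(pts[1, ] == pts[nrow(pts), ])) stop("contour must be closed")
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  ix <- findInterval(target, s, rightmost.closed = TRUE)
  ix[ix >= nrow(pts)] <- nrow(pts) - 1L
  frac <- (target - s[ix]) / pmax(seg[ix], .Machine$double.eps)
  cbind(x = pts[ix, 1] + frac * (pts[ix + 1L, 1] - pts[ix, 1]),
        y = pts[ix, 2] + frac * (pts[ix + 1L, 2] - pts[ix, 2]))
}
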