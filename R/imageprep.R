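#' @importFrom stats cov kmeans rnorm runif sd var quantile setNames optim
#'   dlogis plogis qlogis median cor prcomp aggregate as.formula complete.cases
#' @importFrom grDevices contourLines chull
#' @importFrom utils head tail write.csv read.csv
NULL

# ---- mask helpers -----------------------------------------------------------

#' Coerce a matrix to a validated binary mask
#'
#' Masks are stored as integer matrices with foreground (fruit) = 1 and
#' background = 0, indexed `[row, col]` with the origin at the top-left and y
#' increasing downward.
#'
#' @param x numeric or logical matrix; any value > 0.5 is treated as
#'   foreground unless `invert = TRUE`, in which case values <= 0.5 are.
#' @param invert flip the foreground convention on load (useful for images
#'   saved as dark fruit on a white field, where fruit pixels are near 0).
#' @return an integer matrix of 0/1 with class `binary_mask`.
#' @export
as_binary_mask <- function(x, invert = FALSE) {
  if (!is.matrix(x)) stop("mask must be a matrix")
  m <- matrix(as.integer(x > 0.5), nrow(x), ncol(x))
  if (invert) m <- 1L - m
  class(m) <- c("binary_mask", "matrix")
  m
}

mask_area <- function(mask) sum(mask == 1L)

#' Read a binary mask from a PNG or TIFF file
#'
#' Multi-channel images are collapsed to their mean channel before
#' thresholding at 0.5.
#'
#' @inheritParams as_binary_mask
#' @param path file path ending in .png, .tif or .tiff.
#' @return a `binary_mask`.
#' @export
read_mask <- function(path, invert = FALSE) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- if (length(d) == 2) img@.Data else apply(img@.Data, c(1, 2), mean)
  # EBImage stores images x-major (columns = y); transpose to [row, col]
  as_binary_mask(t(a), invert = invert)
}

# ---- extract_objects --------------------------------------------------------

#' Split a segmented mask into per-fruit masks
#'
#' Each 4-connected foreground component becomes one mask, cropped to its
#' bounding rectangle. Holes are preserved: a background pixel inside a fruit
#' stays background. Components smaller than `min_area` pixels are dropped as
#' segmentation specks.
#'
#' @param mask a `binary_mask` possibly containing several fruit.
#' @param min_area minimum component area in source-scale pixels (default 50).
#' @return a list of `binary_mask`, one per retained component (possibly
#'   empty, with a warning when no foreground exists).
#' @export
extract_objects <- function(mask, min_area = 50) {
  mask <- as_binary_mask(mask)
  if (mask_area(mask) == 0L) {
    warning("no foreground pixels in mask")
    return(list())
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))  # back to x-major for EBImage
  lab <- t(EBImage::imageData(lab))
  out <- list()
  for (id in seq_len(max(lab))) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    r <- range(idx[, 1]); c <- range(idx[, 2])
    sub <- matrix(0L, r[2] - r[1] + 1L, c[2] - c[1] + 1L)
    sub[cbind(idx[, 1] - r[1] + 1L, idx[, 2] - c[1] + 1L)] <- 1L
    out[[length(out) + 1L]] <- as_binary_mask(sub)
  }
  out
}

# ---- normalize --------------------------------------------------------------

# Exact area-average (box-filter) resampling of a matrix to out x out.
# The box filter is separable, so the result is Wy %*% m %*% t(Wx) with
# overlap-weight matrices: source pixel j spans [j-1, j), output cell i
# spans [n*(i-1)/out, n*i/out) in source units.
overlap_weights <- function(n, out) {
  lo <- n * (seq_len(out) - 1) / out
  hi <- n * seq_len(out) / out
  ov <- outer(hi, seq_len(n), pmin) - outer(lo, seq_len(n) - 1L, pmax)
  ov[ov < 0] <- 0
  ov / (hi - lo)
}

area_resample <- function(m, out) {
  Wy <- overlap_weights(nrow(m), out)
  Wx <- overlap_weights(ncol(m), out)
  Wy %*% m %*% t(Wx)
}

#' Normalize a single-fruit mask to the common 100 x 100 raster
#'
#' The mask is padded with background to a square of side max(H, W), scaled so
#' that the larger dimension becomes `scale_px` pixels (aspect ratio
#' preserved), then downsampled to `out_px` x `out_px` by area averaging and
#' re-binarized at 0.5 (exact ties count as foreground).
#'
#' @param mask a cropped single-fruit `binary_mask`.
#' @param source_id sample identifier carried through as provenance.
#' @param out_px output side length (default 100).
#' @param scale_px intermediate major-axis length (default 1000); `NULL`
#'   resamples the padded square straight to `out_px`, which collapses the
#'   two box filters into one and skips the intermediate re-binarization
#'   (appropriate for synthetic rasters that never pass through an archival
#'   1,000-pixel form).
#' @return a `normalized_image`: list with `pixels` (out_px x out_px 0/1
#'   matrix), `source_id`, and `major_axis_px` (longer bounding-box side of
#'   the source).
#' @export
normalize_mask <- function(mask, source_id = NA_character_, out_px = 100,
                           scale_px = 1000) {
  mask <- as_binary_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  if (h < 3 || w < 3) stop("mask too small")
  s <- max(h, w)
  sq <- matrix(0L, s, s)
  r0 <- floor((s - h) / 2); c0 <- floor((s - w) / 2)
  sq[r0 + seq_len(h), c0 + seq_len(w)] <- mask
  if (is.null(scale_px)) {
    fin <- area_resample(sq, out_px)
  } else {
    mid <- area_resample(sq, scale_px)
    mid <- matrix(as.integer(mid >= 0.5), scale_px, scale_px)
    fin <- area_resample(mid, out_px)
  }
  px <- matrix(as.integer(fin >= 0.5), out_px, out_px)
  structure(list(pixels = px, source_id = source_id, major_axis_px = s),
            class = "normalized_image")
}

#' @export
print.normalized_image <- function(x, ...) {
  cat("normalized_image:", nrow(x$pixels), "x", ncol(x$pixels),
      "| id:", x$source_id, "| area:", sum(x$pixels), "px\n")
  invisible(x)
}

# ---- flatten ----------------------------------------------------------------

#' Flatten a normalized image to a 10,000-element row vector
#'
#' Row-major order: pixel (row 1, col 1), (row 1, col 2), ..., so the vector
#' index is (row - 1) * 100 + col.
#'
#' @param img a `normalized_image` or a 100 x 100 binary matrix.
#' @return integer vector of length `nrow * ncol` summing to the foreground
#'   area.
#' @export
flatten_image <- function(img) {
  px <- if (inherits(img, "normalized_image")) img$pixels else img
  if (!is.matrix(px)) stop("flatten_image: need a matrix or normalized_image")
  as.integer(t(px))
}

#' Inverse of [flatten_image()]
#'
#' @param v flattened vector whose length is a perfect square.
#' @return binary matrix with rows restored.
#' @export
unflatten_image <- function(v) {
  n <- sqrt(length(v))
  if (n != round(n)) stop("unflatten_image: length is not a perfect square")
  t(matrix(as.integer(v), n, n))
}

#' Write a normalized image as a PNG mask
#'
#' Foreground is written as black (0), background as white (1), matching
#' the display convention for fruit masks.
#'
#' @param img a `normalized_image`.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_normalized_png <- function(img, path) {
  png::writePNG(1 - img$pixels, path)
  invisible(path)
}

#' Flatten a list of normalized images into the sample x pixel matrix
#'
#' @param images list of `normalized_image`.
#' @return n x 10,000 integer matrix, rownames = source ids, colnames
#'   `px0000..px9999`.
#' @export
pixel_matrix <- function(images) {
  m <- do.call(rbind, lapply(images, flatten_image))
  rownames(m) <- vapply(images, function(x) as.character(x$source_id), "")
  colnames(m) <- sprintf("px%04d", seq_len(ncol(m)) - 1L)
  m
}
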