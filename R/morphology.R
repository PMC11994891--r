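as_mask <- function(x) {
  if (is.logical(x) && is.matrix(x)) return(x)
  if (is.matrix(x)) return(x > 0)
  stop("expected a logical matrix mask")
}

brush3 <- function() EBImage::makeBrush(3L, shape = "box")

#' Binary erosion
#'
#' Standard binary erosion with a 3x3 square structuring element, applied
#' `iterations` times ("reducing the object size"). The result is always a
#' subset of the input; 1-pixel-wide structures disappear after one pass.
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @param iterations Number of passes (`>= 1`).
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  mask <- as_mask(mask)
  if (iterations < 1) stop("iterations must be >= 1")
  m <- mask * 1
  for (i in seq_len(iterations)) m <- EBImage::erode(m, brush3())
  m > 0
}

#' Binary dilation
#'
#' Binary dilation with a 3x3 square structuring element, applied
#' `iterations` times ("expanding the signal's boundary"). The input is
#' always a subset of the result.
#'
#' @inheritParams erode_mask
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  mask <- as_mask(mask)
  if (iterations < 1) stop("iterations must be >= 1")
  m <- mask * 1
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, brush3())
  m > 0
}

#' Binary closing
#'
#' One dilation followed by one erosion (3x3 element): gaps and openings of
#' up to one pixel in object boundaries are sealed; the input is a subset of
#' the result.
#'
#' @inheritParams erode_mask
#' @return Logical matrix.
#' @export
close_mask <- function(mask) {
  erode_mask(dilate_mask(as_mask(mask), 1L), 1L)
}

#' Object outlines
#'
#' Keeps the foreground pixels that touch the background (those with at
#' least one background 8-neighbor): the mask minus its erosion. Interiors
#' are removed; single pixels are their own outline.
#'
#' @inheritParams erode_mask
#' @return Logical matrix.
#' @export
outline_mask <- function(mask) {
  mask <- as_mask(mask)
  mask & !erode_mask(mask, 1L)
}

#' Fill holes in objects
#'
#' Background regions not 4-connected to the image border ("cavities inside
#' the signal") become foreground. Idempotent; the input is a subset of the
#' result.
#'
#' @inheritParams erode_mask
#' @return Logical matrix.
#' @export
fill_holes <- function(mask) {
  mask <- as_mask(mask)
  bg <- cpp_label_components(!mask, 4L)
  border_labels <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  mask | (bg > 0L & !(bg %in% border_labels))
}

#' Label connected components
#'
#' Each maximal connected foreground region receives one positive integer
#' label, assigned in raster order (row by row) of its first-encountered
#' pixel. The field's convention for fluorescent objects is 8-connected
#' foreground (diagonal contacts join).
#'
#' @inheritParams erode_mask
#' @param connectivity 8 (default) or 4.
#' @return An object of class `labeled_components`: a list with `labels`
#'   (integer matrix, 0 = background), `n` (number of components), `sizes`
#'   (pixel count per label) and `centroids` (n x 2 matrix of row/col
#'   centroids).
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- as_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- cpp_label_components(mask, as.integer(connectivity))
  n <- attr(lab, "n")
  attr(lab, "n") <- NULL
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  centroids <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("row", "col")))
  if (n > 0L) {
    idx <- which(lab > 0L)
    rr <- ((idx - 1L) %% nrow(lab)) + 1L
    cc <- ((idx - 1L) %/% nrow(lab)) + 1L
    l <- lab[idx]
    centroids[, 1L] <- rowsum(rr, l)[, 1L] / sizes
    centroids[, 2L] <- rowsum(cc, l)[, 1L] / sizes
  }
  structure(list(labels = lab, n = n, sizes = sizes, centroids = centroids),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat("labeled_components:", x$n, "objects",
      if (x$n) sprintf("(sizes %d..%d px)", min(x$sizes), max(x$sizes)) else "",
      "\n")
  invisible(x)
}

#' @export
as.data.frame.labeled_components <- function(x, ...) {
  data.frame(label = seq_len(x$n), size = x$sizes,
             centroid_row = x$centroids[, 1L], centroid_col = x$centroids[, 2L])
}

#' Remove small objects
#'
#' Deletes 8-connected components smaller than `min_size` pixels; larger
#' components are untouched (pixel-exact). With `min_size = 2` exactly the
#' isolated single pixels are removed.
#'
#' @inheritParams erode_mask
#' @param min_size Minimum object area in pixels (`>= 1`).
#' @return Logical matrix.
#' @export
remove_small_objects <- function(mask, min_size) {
  mask <- as_mask(mask)
  if (min_size < 1) stop("min_size must be >= 1")
  lc <- label_components(mask, 8L)
  if (lc$n == 0L) return(mask)
  keep <- which(lc$sizes >= min_size)
  matrix(lc$labels %in% keep, nrow(mask)) & mask
}

watershed_line_pixels <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  line <- matrix(FALSE, H, W)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    sr <- s[1]; sc <- s[2]
    r1 <- max(1, 1 + sr):min(H, H + sr)
    c1 <- max(1, 1 + sc):min(W, W + sc)
    r0 <- r1 - sr
    c0 <- c1 - sc
    a <- labels[r0, c0, drop = FALSE]
    b <- labels[r1, c1, drop = FALSE]
    diff <- a > 0L & b > 0L & a != b
    line[r0, c0][diff] <- TRUE
  }
  line
}

#' Split touching objects by grayscale watershed
#'
#' Treats the inverted intensity landscape as topography and floods it from
#' its regional minima (i.e. from the bright peaks of the original image),
#' merging basins whose peak rises less than `h` gray levels above the point
#' of contact with a neighbor (suppression of shallow, noise-driven minima).
#' Pixels where two distinct basins meet - the watershed lines along the
#' intensity valleys between touching objects - are set to 0 in the returned
#' grayscale image, so that subsequent binarization yields separated
#' objects. All other pixels keep their input values, so the split image
#' never gains signal.
#'
#' @param image Integer matrix in `[0, 255]`.
#' @param h Minimum basin depth in gray levels; shallower basins are merged
#'   into their neighbors. Default 2.
#' @return Integer matrix in `[0, 255]` with zero-valued dividing lines.
#' @export
watershed_split <- function(image, h = 2) {
  stopifnot(is.matrix(image))
  labels <- cpp_watershed_labels(matrix(as.numeric(image), nrow(image)), h)
  out <- image
  out[watershed_line_pixels(labels)] <- 0L
  as_gray8_storage(out)
}

#' Split touching objects in a binary mask (distance-transform watershed)
#'
#' The alternative splitting mode for sensitivity checks: watershed on the
#' Euclidean distance transform of the mask itself, with dividing-line
#' pixels removed from the mask.
#'
#' @inheritParams erode_mask
#' @param h Minimum basin depth in distance units. Default 1.
#' @return Logical matrix.
#' @export
watershed_split_binary <- function(mask, h = 1) {
  mask <- as_mask(mask)
  d <- matrix(as.numeric(EBImage::distmap(mask * 1)), nrow(mask))
  labels <- cpp_watershed_labels(d, h)
  mask & !watershed_line_pixels(labels)
}
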