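#' Read a fluorescence micrograph from TIFF as an 8-bit grayscale matrix
#'
#' Reads a single-plane TIFF and returns an integer matrix of intensities in
#' `[0, 255]` (rows = image rows). 8-bit grayscale data are returned verbatim.
#' 16-bit grayscale data are linearly min-max rescaled onto `[0, 255]` with
#' [to_gray8()]. 8-bit RGB data are converted by the ITU luminance weighting
#' `0.299 R + 0.587 G + 0.114 B`, rounded half-up.
#'
#' @param path Path to a TIFF file (uncompressed or deflate; 8- or 16-bit
#'   grayscale, or 8-bit RGB/RGBA).
#' @return An integer matrix with values in `[0, 255]`.
#' @seealso [write_gray_tiff()], [to_gray8()]
#' @export
read_gray_tiff <- function(path) {
  if (!file.exists(path)) {
    stop("TIFF file not found: ", path)
  }
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] < 3L || bits != 8L) {
      stop("unsupported TIFF layout: multi-channel data must be 8-bit RGB(A)")
    }
    if (max(img) <= 1) img <- img * 255  # RGB planes come back normalized
    y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    return(as_gray8_storage(round_half_up(matrix(y, dim(img)[1]))))
  }
  img <- matrix(as.integer(img), nrow(img))  # drop TIFF info attributes
  if (bits == 8L) {
    return(img)
  }
  if (bits == 16L) {
    return(to_gray8(img))
  }
  stop("unsupported TIFF bit depth: ", bits)
}

#' Write an 8-bit grayscale matrix as an uncompressed TIFF
#'
#' The written file round-trips bit-exactly through [read_gray_tiff()].
#'
#' @param image Integer matrix with values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 255))
  tiff::writeTIFF(image / 255, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Convert an image of arbitrary integer depth to 8-bit
#'
#' Linear min-max rescale onto `[0, 255]`, rounded half-up. A constant image
#' maps to all zeros: a featureless field should binarize to empty foreground
#' downstream.
#'
#' @param image Numeric matrix of non-negative intensities (any depth).
#' @return Integer matrix in `[0, 255]`.
#' @examples
#' to_gray8(matrix(c(100, 150, 200, 300), 2))
#' @export
to_gray8 <- function(image) {
  if (!is.matrix(image) || any(dim(image) < 1L)) {
    stop("image must be a non-empty matrix")
  }
  if (any(image < 0)) stop("intensities must be non-negative")
  lo <- min(image)
  hi <- max(image)
  if (lo == hi) {
    return(as_gray8_storage(matrix(0L, nrow(image), ncol(image))))
  }
  as_gray8_storage(round_half_up((image - lo) * 255 / (hi - lo)))
}

#' Intensity histogram of an 8-bit image
#'
#' @param image Integer matrix in `[0, 255]`.
#' @return An object of class `intensity_histogram`: a list with `counts`
#'   (256 integer bin counts for gray levels 0..255) and `total`
#'   (number of pixels).
#' @export
compute_histogram <- function(image) {
  stopifnot(is.matrix(image))
  if (any(image < 0) || any(image > 255)) {
    stop("compute_histogram expects an 8-bit image")
  }
  counts <- tabulate(as.integer(image) + 1L, nbins = 256L)
  structure(list(counts = counts, total = length(image)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  nz <- which(x$counts > 0L) - 1L
  cat("intensity histogram:", x$total, "pixels,",
      length(nz), "occupied gray levels",
      if (length(nz)) sprintf("[%d..%d]", min(nz), max(nz)) else "", "\n")
  invisible(x)
}

as_histogram <- function(x) {
  if (inherits(x, "intensity_histogram")) return(x)
  if (is.matrix(x)) return(compute_histogram(x))
  stop("expected an intensity_histogram or an 8-bit image matrix")
}
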