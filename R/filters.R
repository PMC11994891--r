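#' Rolling-ball background subtraction
#'
#' Estimates the background of a fluorescence image by grayscale opening with
#' a spherical-cap (ball) structuring element of the given radius - the
#' surface traced by a ball rolled beneath the intensity landscape - and
#' subtracts it. Uneven illumination and slowly varying nonspecific staining
#' wider than the ball are removed while objects smaller than the ball are
#' preserved. The output never exceeds the input pixelwise.
#'
#' @param image Integer matrix in `[0, 255]`.
#' @param radius Ball radius in pixels (`>= 1`). Choose it at least as large
#'   as the largest object of interest.
#' @return Integer matrix in `[0, 255]` with the background removed.
#' @references Sternberg, S.R. (1983) Biomedical image processing.
#'   IEEE Computer 16, 22-34.
#' @export
rolling_ball_subtract <- function(image, radius) {
  stopifnot(is.matrix(image))
  if (radius < 1) stop("rolling-ball radius must be >= 1")
  if (radius > nrow(image) && radius > ncol(image)) {
    stop("rolling-ball radius exceeds both image dimensions")
  }
  bg <- cpp_rolling_ball_background(matrix(as.numeric(image), nrow(image)),
                                    as.integer(radius))
  as_gray8_storage(clamp8(round_half_up(image - bg)))
}

#' Sharpen an image
#'
#' 3x3 unsharp kernel (all coefficients -1, center 12, divided by 4 so the
#' coefficients sum to one), edge-replicated borders, result clamped to
#' `[0, 255]`. Constant regions are unchanged; local contrast is amplified.
#'
#' @param image Integer matrix in `[0, 255]`.
#' @return Integer matrix in `[0, 255]`.
#' @export
sharpen <- function(image) {
  k <- matrix(-1, 3, 3)
  k[2, 2] <- 12
  convolve_kernel(image, k / 4, normalize = FALSE)
}

#' Sobel edge magnitude
#'
#' Gradient magnitude `sqrt(Gx^2 + Gy^2)` from the 3x3 Sobel operators with
#' edge-replicated borders, rounded half-up and clamped to `[0, 255]`.
#' Interior pixels of constant regions map to 0; object outlines light up.
#'
#' @param image Integer matrix in `[0, 255]`.
#' @return Integer matrix in `[0, 255]`.
#' @export
edge_magnitude <- function(image) {
  stopifnot(is.matrix(image))
  m <- matrix(as.numeric(image), nrow(image))
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- cpp_convolve(m, sx)
  gy <- cpp_convolve(m, t(sx))
  as_gray8_storage(clamp8(round_half_up(sqrt(gx^2 + gy^2))))
}

#' Min-max luminance normalization
#'
#' Maps each pixel's luminance `Px` onto the target range `(c, d)` from the
#' image's own minimum `a` and maximum `b`:
#' `Py = (Px - a) (d - c) / (b - a) + c`, rounded half-up. With the default
#' target `(0, 255)` this is a full contrast stretch; for a non-constant
#' image the output extremes equal `c` and `d` exactly.
#'
#' @param image Integer matrix in `[0, 255]`.
#' @param c,d Target range bounds, `c < d`; default `(0, 255)`.
#' @param a,b Source range; default the image minimum and maximum.
#' @return Integer matrix.
#' @export
normalize_range <- function(image, c = 0, d = 255, a = min(image), b = max(image)) {
  stopifnot(is.matrix(image))
  if (c >= d) stop("target range must satisfy c < d")
  if (a > b) stop("source range must satisfy a <= b")
  if (a == b) {
    warning("constant image: degenerate stretch, returning constant c")
    return(as_gray8_storage(matrix(as.integer(c), nrow(image), ncol(image))))
  }
  as_gray8_storage(round_half_up((image - a) * (d - c) / (b - a) + c))
}

#' Median filter
#'
#' Replaces each pixel with the median of its `(2 radius + 1)` square
#' neighborhood (edge-replicated). Isolated single-pixel outliers vanish for
#' any `radius >= 1`.
#'
#' @param image Integer matrix in `[0, 255]`.
#' @param radius Neighborhood radius in pixels (`>= 1`).
#' @return Integer matrix in `[0, 255]`.
#' @export
median_filter <- function(image, radius = 1L) {
  stopifnot(is.matrix(image))
  if (radius < 1) stop("median filter radius must be >= 1")
  m <- image
  storage.mode(m) <- "integer"
  cpp_median_filter(m, as.integer(radius))
}

#' Convolve an image with an arbitrary odd-sized kernel
#'
#' Spatial convolution with edge-replicated borders. With `normalize = TRUE`
#' and a kernel of non-zero sum, the result is divided by the kernel sum
#' (smoothing kernels then preserve the mean level). The result is rounded
#' half-up and clamped to `[0, 255]`.
#'
#' @param image Integer matrix in `[0, 255]`.
#' @param kernel Numeric matrix with odd dimensions.
#' @param normalize Divide by the kernel sum when it is non-zero.
#' @return Integer matrix in `[0, 255]`.
#' @export
convolve_kernel <- function(image, kernel, normalize = TRUE) {
  stopifnot(is.matrix(image), is.matrix(kernel))
  if (nrow(kernel) %% 2L == 0L || ncol(kernel) %% 2L == 0L) {
    stop("kernel dimensions must be odd")
  }
  out <- cpp_convolve(matrix(as.numeric(image), nrow(image)),
                      matrix(as.numeric(kernel), nrow(kernel)))
  s <- sum(kernel)
  if (isTRUE(normalize) && s != 0) out <- out / s
  as_gray8_storage(clamp8(round_half_up(out)))
}
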