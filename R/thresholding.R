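new_threshold_result <- function(t, method, diagnostics = list()) {
  structure(list(t = as.integer(t), method = method, diagnostics = diagnostics),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold_result: t = %d (method: %s)\n", x$t, x$method))
  invisible(x)
}

#' Mean-intensity threshold
#'
#' The threshold is the integer part of the image's average gray level:
#' `t = floor(sum(k * counts[k]) / total)`. Pixels strictly above `t` are
#' foreground under [apply_threshold()].
#'
#' @param hist An `intensity_histogram` (or an 8-bit image, from which one is
#'   computed).
#' @return A `threshold_result` with fields `t`, `method`, `diagnostics`.
#' @export
threshold_mean <- function(hist) {
  h <- as_histogram(hist)
  if (h$total <= 0L) stop("empty histogram")
  t <- floor(sum((0:255) * h$counts) / h$total)
  new_threshold_result(t, "mean", list(mean = sum((0:255) * h$counts) / h$total))
}

# Per-alpha Renyi maximizer over all admissible t (both classes non-empty).
# Returns the smallest maximizing t. alpha = 1 is the Shannon limit.
renyi_best_t <- function(p, alpha) {
  cum <- cumsum(p)
  # admissibility decided on occupied bins (integer-exact): both classes
  # must contain at least one actual pixel
  nz <- cumsum(p > 0)
  admissible <- which(nz >= 1L & nz < nz[256L]) - 1L   # gray levels t
  if (!length(admissible)) return(NA_integer_)
  if (alpha == 1) {
    plogp <- ifelse(p > 0, p * log(p), 0)
    cpl <- cumsum(plogp)
    tot <- cpl[256]
    pa <- cum[admissible + 1L]
    ha <- -(cpl[admissible + 1L] / pa - log(pa))
    hb <- -((tot - cpl[admissible + 1L]) / (1 - pa) - log(1 - pa))
  } else {
    pa_ <- cumsum(p^alpha)
    tot <- pa_[256]
    pa <- cum[admissible + 1L]
    ha <- log(pa_[admissible + 1L] / pa^alpha) / (1 - alpha)
    hb <- log((tot - pa_[admissible + 1L]) / (1 - pa)^alpha) / (1 - alpha)
  }
  obj <- ha + hb
  # cumsum cancellation can leave a NaN at the extreme admissible t
  ok <- is.finite(obj)
  if (!any(ok)) return(NA_integer_)
  # mathematically tied maximizers (e.g. mirror-symmetric splits) can differ
  # in the last float digits; treat scores within a relative tolerance of the
  # maximum as ties and take the smallest t
  best <- max(obj[ok])
  admissible[which(ok & obj >= best - 1e-9 * max(1, abs(best)))[1L]]
}

#' Renyi-entropy threshold
#'
#' For each order `alpha` in `{0.5, 1, 2}` (with `alpha = 1` the Shannon
#' limit), the candidate threshold `t_alpha` maximizes the sum of the Renyi
#' entropies of the below-`t` and above-`t` intensity distributions,
#' `H_A(t) + H_B(t)` with
#' `H_A(t) = 1/(1-alpha) ln sum_{i<=t} (P_i/P_A)^alpha` and
#' `H_B(t) = 1/(1-alpha) ln sum_{i>t} (P_i/P_B)^alpha`,
#' evaluated exhaustively over every gray level with both classes non-empty
#' (ties broken toward the smallest t). The three candidates are then
#' combined by the weighted rule of Sahoo et al. (1997): the sorted
#' candidates `t1 <= t2 <= t3` receive weights `beta` depending on their
#' mutual separation (cutoff 5 gray levels), and
#' `t = floor(t1 (P1(t1) + omega beta1 / 4) + t2 omega beta2 / 4 +
#'  t3 (P2(t3) + omega beta3 / 4))` with `omega = P1(t3) - P1(t1)`,
#' `P1` the cumulative probability and `P2 = 1 - P1`.
#'
#' On fluorescence histograms with a very small foreground fraction the
#' combined rule can collapse into the background lobe (the `alpha = 2`
#' candidate degenerates toward the dominant bin and the cumulative-weight
#' average follows it); `variant` therefore allows any single-alpha
#' candidate to be used as the operative threshold instead. All per-alpha
#' candidates are always recorded in `diagnostics`, so every variant is
#' reproducible from one result.
#'
#' @inheritParams threshold_mean
#' @param variant Which candidate becomes the operative threshold `t`:
#'   `"combined"` (the Sahoo weighted rule, default), or a single order
#'   `"shannon"` (`alpha = 1`), `"alpha0.5"`, `"alpha2"`.
#' @return A `threshold_result`; `diagnostics` records the per-alpha
#'   candidates, the weights and `omega`, so both the single-alpha and the
#'   combined variants are reproducible.
#' @references Sahoo, P., Wilkins, C., Yeager, J. (1997) Threshold selection
#'   using Renyi's entropy. Pattern Recognition 30, 71-84.
#' @export
threshold_renyi_entropy <- function(hist,
                                    variant = c("combined", "shannon",
                                                "alpha0.5", "alpha2")) {
  variant <- match.arg(variant)
  h <- as_histogram(hist)
  if (h$total <= 0L) stop("empty histogram")
  if (sum(h$counts > 0L) < 2L) {
    stop("degenerate histogram: Renyi entropy threshold needs at least two occupied gray levels")
  }
  p <- h$counts / h$total
  alphas <- c(0.5, 1, 2)
  t_alpha <- vapply(alphas, function(a) renyi_best_t(p, a), integer(1))
  ts <- sort(t_alpha)
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) beta <- c(1, 2, 1) else beta <- c(0, 1, 3)
  } else {
    if (abs(t2 - t3) <= 5) beta <- c(3, 1, 0) else beta <- c(1, 2, 1)
  }
  cum <- cumsum(p)
  p1 <- function(t) cum[t + 1L]
  omega <- p1(t3) - p1(t1)
  t_combined <- floor(t1 * (p1(t1) + 0.25 * omega * beta[1]) +
                      0.25 * t2 * omega * beta[2] +
                      t3 * ((1 - p1(t3)) + 0.25 * omega * beta[3]))
  t <- switch(variant,
              combined = t_combined,
              shannon = t_alpha[2L],
              alpha0.5 = t_alpha[1L],
              alpha2 = t_alpha[3L])
  new_threshold_result(
    t, "renyi_entropy",
    list(alpha = alphas, t_alpha = t_alpha, t_sorted = ts,
         beta = beta, omega = omega, t_combined = t_combined,
         variant = variant)
  )
}

# One 3-point running-mean smoothing pass over a 256-bin histogram
# (bins outside [0,255] count as empty).
smooth_histogram_pass <- function(counts) {
  (c(0, counts[-256]) + counts + c(counts[-1], 0)) / 3
}

histogram_modes <- function(counts) {
  k <- 2:255
  which(counts[k] > counts[k - 1L] & counts[k] > counts[k + 1L]) + 1L
}

#' Intermodes threshold
#'
#' Iteratively smooths the 256-bin histogram with a 3-point running mean
#' until exactly two local maxima remain, then takes the midpoint:
#' `t = floor((m1 + m2) / 2)` for mode gray levels `m1 < m2`. Histograms
#' that never become bimodal within 10000 smoothing passes (e.g. extremely
#' skewed unimodal data, or an image with a single gray level) raise an
#' error.
#'
#' @inheritParams threshold_mean
#' @return A `threshold_result`; `diagnostics` records the two mode
#'   locations and the number of smoothing iterations used.
#' @references Prewitt, J.M.S., Mendelsohn, M.L. (1966) The analysis of cell
#'   images. Annals of the New York Academy of Sciences 128, 1035-1053.
#' @export
threshold_intermodes <- function(hist) {
  h <- as_histogram(hist)
  if (h$total <= 0L) stop("empty histogram")
  counts <- as.numeric(h$counts)
  iter <- 0L
  repeat {
    modes <- histogram_modes(counts)
    if (length(modes) == 2L) break
    if (iter >= 10000L) {
      stop("histogram did not become bimodal within 10000 smoothing iterations")
    }
    counts <- smooth_histogram_pass(counts)
    iter <- iter + 1L
  }
  m <- modes - 1L  # gray levels
  t <- floor((m[1] + m[2]) / 2)
  new_threshold_result(t, "intermodes",
                       list(modes = m, iterations = iter))
}

#' Binarize an image at a threshold
#'
#' Foreground ("objects, white") is every pixel strictly above `t`;
#' everything else is background ("black"). The foreground pixel count is
#' non-increasing in `t`.
#'
#' @param image Integer matrix in `[0, 255]`.
#' @param result A `threshold_result`, or a bare gray level in `[0, 255]`.
#' @return A logical matrix (`TRUE` = foreground) of the same dimensions.
#' @export
apply_threshold <- function(image, result) {
  stopifnot(is.matrix(image))
  t <- if (inherits(result, "threshold_result")) result$t else result
  if (t < 0 || t > 255) stop("threshold must lie in [0, 255]")
  image > t
}
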