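#' Parameters for a synthetic immunofluorescence section
#'
#' Describes the scene the generator renders: bright, roughly circular
#' nuclei (soft cosine-tapered disks) on a smooth low-frequency background
#' with pixel noise, with known subsets of nuclei carrying Pax-7 and/or
#' BrdU signal. Defaults emulate a 640 x 480 field at 40x with about 100
#' nuclei of 5-7 px radius.
#'
#' @param width,height Image dimensions in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param pax7_frac,brdu_frac Fractions of nuclei carrying each marker.
#' @param n_copositive Number of nuclei forced to carry both markers
#'   (must not exceed either marker count).
#' @param radius_range Nucleus radius range in pixels (drawn uniformly).
#' @param min_distance Minimum pairwise center distance; default 3x the
#'   mean radius, so that at default radii nuclei stay disjoint through
#'   every processing chain (the Sobel edge ring extends one pixel beyond
#'   the disk footprint and closing can bridge two-pixel gaps). Touching
#'   pairs are generated explicitly by [generate_touching_pair()] instead.
#' @param background_amplitude Peak-to-trough amplitude of the smooth
#'   background field, in gray levels (the tissue-thickness variation the
#'   rolling ball must suppress).
#' @param background_scale Characteristic spatial scale of the background
#'   sinusoids, in pixels.
#' @param noise_sigma Gaussian pixel-noise standard deviation, gray levels.
#' @param poisson_scaling Scale the noise standard deviation with the
#'   square root of the local intensity (photon-like noise).
#' @param nucleus_peak,marker_peak Peak intensities of the DAPI and marker
#'   disks, gray levels.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(width = 640L, height = 480L,
                         n_nuclei = 100L,
                         pax7_frac = 0.2, brdu_frac = 0.1,
                         n_copositive = 5L,
                         radius_range = c(5, 7),
                         min_distance = 3 * mean(radius_range),
                         background_amplitude = 20,
                         background_scale = 150,
                         noise_sigma = 5,
                         poisson_scaling = FALSE,
                         nucleus_peak = 180,
                         marker_peak = 200) {
  stopifnot(width >= 1, height >= 1, n_nuclei >= 1,
            pax7_frac >= 0, pax7_frac <= 1, brdu_frac >= 0, brdu_frac <= 1,
            radius_range[1] >= 2, radius_range[2] >= radius_range[1])
  n_pax7 <- round(pax7_frac * n_nuclei)
  n_brdu <- round(brdu_frac * n_nuclei)
  if (n_copositive > min(n_pax7, n_brdu)) {
    stop("n_copositive cannot exceed either marker count")
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_nuclei = as.integer(n_nuclei),
    n_pax7 = as.integer(n_pax7), n_brdu = as.integer(n_brdu),
    n_copositive = as.integer(n_copositive),
    radius_range = radius_range, min_distance = min_distance,
    background_amplitude = background_amplitude,
    background_scale = background_scale,
    noise_sigma = noise_sigma, poisson_scaling = poisson_scaling,
    nucleus_peak = nucleus_peak, marker_peak = marker_peak
  ), class = "scene_params")
}

# sub-seeds keep placement, background and noise on independent streams so
# that e.g. changing noise_sigma does not reshuffle the nuclei
derive_seeds <- function(seed) {
  (as.integer(seed) + c(placement = 101L, background = 202L, noise = 303L) *
     1000003L) %% .Machine$integer.max
}

place_nuclei <- function(params) {
  margin <- max(params$radius_range) + 2
  centers <- matrix(NA_real_, params$n_nuclei, 2L)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 5000L * params$n_nuclei
  while (placed < params$n_nuclei) {
    if (attempts >= max_attempts) {
      stop("could not place ", params$n_nuclei,
           " nuclei under the minimum-distance constraint")
    }
    attempts <- attempts + 1L
    cand <- c(runif(1, margin, params$height - margin),
              runif(1, margin, params$width - margin))
    if (placed == 0L ||
        min((centers[seq_len(placed), 1L] - cand[1])^2 +
            (centers[seq_len(placed), 2L] - cand[2])^2) >= params$min_distance^2) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  centers
}

# soft disk: flat core, cosine rim over the outermost `rim` pixels
render_disks <- function(height, width, centers, radii, peak, rim = 2) {
  img <- matrix(0, height, width)
  if (!nrow(centers)) return(img)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    w_rim <- min(rim, r / 2)
    r0 <- ceiling(r)
    rows <- max(1L, floor(centers[i, 1L] - r0)):min(height, ceiling(centers[i, 1L] + r0))
    cols <- max(1L, floor(centers[i, 2L] - r0)):min(width, ceiling(centers[i, 2L] + r0))
    d <- sqrt(outer((rows - centers[i, 1L])^2, (cols - centers[i, 2L])^2, `+`))
    prof <- ifelse(d <= r - w_rim, 1,
                   ifelse(d <= r, 0.5 * (1 + cos(pi * (d - (r - w_rim)) / w_rim)), 0))
    img[rows, cols] <- pmax(img[rows, cols], peak * prof)
  }
  img
}

render_background <- function(height, width, amplitude, scale) {
  if (amplitude <= 0) return(matrix(0, height, width))
  n_waves <- sample(2:4, 1L)
  field <- matrix(0, height, width)
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  for (k in seq_len(n_waves)) {
    theta <- runif(1, 0, pi)
    wavelength <- runif(1, 0.7 * scale, 1.5 * scale)
    phase <- runif(1, 0, 2 * pi)
    field <- field + runif(1, 0.5, 1) *
      sin(2 * pi * (rr * cos(theta) + cc * sin(theta)) / wavelength + phase)
  }
  amplitude * (field - min(field)) / (max(field) - min(field))
}

finalize_channel <- function(signal, background, params, sigma) {
  x <- signal + background
  if (sigma > 0) {
    sd_map <- if (isTRUE(params$poisson_scaling)) {
      sigma * sqrt(pmax(x, 1) / params$nucleus_peak)
    } else sigma
    x <- x + rnorm(length(x), 0, sd_map)
  }
  as_gray8_storage(clamp8(round_half_up(matrix(x, nrow(signal)))))
}

#' Generate a seeded three-channel synthetic section with ground truth
#'
#' Renders a DAPI channel with soft-edged disks at every nucleus, a Pax-7
#' channel with disks only at Pax-7-positive nuclei and a BrdU channel with
#' disks only at BrdU-positive nuclei (marker disks sit inside the nucleus
#' footprint, as both are nuclear markers). Each channel receives an
#' independent smooth low-frequency background plus pixel noise. One seed
#' drives placement, labels, background and noise through independent
#' derived streams; identical `(params, seed)` give byte-identical output.
#'
#' @param params A [scene_params()].
#' @param seed Integer seed.
#' @return A list with components `dapi`, `pax7`, `brdu` (8-bit integer
#'   matrices) and `truth`, an object of class `synthetic_scene` holding the
#'   nucleus table (`center_row`, `center_col`, `radius`, `is_pax7`,
#'   `is_brdu`) and the exact counts.
#' @export
generate_scene <- function(params = scene_params(), seed = 1L) {
  seeds <- derive_seeds(seed)

  set.seed(seeds[["placement"]])
  centers <- place_nuclei(params)
  radii <- runif(params$n_nuclei, params$radius_range[1], params$radius_range[2])
  co_idx <- sample(params$n_nuclei, params$n_copositive)
  rest <- setdiff(seq_len(params$n_nuclei), co_idx)
  pax7_only <- sample(rest, params$n_pax7 - params$n_copositive)
  brdu_only <- sample(setdiff(rest, pax7_only), params$n_brdu - params$n_copositive)
  is_pax7 <- seq_len(params$n_nuclei) %in% c(co_idx, pax7_only)
  is_brdu <- seq_len(params$n_nuclei) %in% c(co_idx, brdu_only)

  h <- params$height; w <- params$width
  # both markers are nuclear (a transcription factor and DNA-incorporated
  # BrdU), so marker disks share the full nucleus footprint
  dapi_sig <- render_disks(h, w, centers, radii, params$nucleus_peak)
  pax7_sig <- render_disks(h, w, centers[is_pax7, , drop = FALSE],
                           radii[is_pax7], params$marker_peak)
  brdu_sig <- render_disks(h, w, centers[is_brdu, , drop = FALSE],
                           radii[is_brdu], params$marker_peak)

  set.seed(seeds[["background"]])
  bg <- lapply(1:3, function(i) {
    render_background(h, w, params$background_amplitude, params$background_scale)
  })

  set.seed(seeds[["noise"]])
  dapi <- finalize_channel(dapi_sig, bg[[1]], params, params$noise_sigma)
  pax7 <- finalize_channel(pax7_sig, bg[[2]], params, params$noise_sigma)
  brdu <- finalize_channel(brdu_sig, bg[[3]], params, params$noise_sigma)

  truth <- structure(list(
    params = params, seed = as.integer(seed),
    nuclei = data.frame(center_row = centers[, 1L], center_col = centers[, 2L],
                        radius = radii, is_pax7 = is_pax7, is_brdu = is_brdu),
    n_nuclei = params$n_nuclei,
    n_pax7 = sum(is_pax7),
    n_brdu = sum(is_brdu),
    n_copositive = sum(is_pax7 & is_brdu)
  ), class = "synthetic_scene")

  list(dapi = dapi, pax7 = pax7, brdu = brdu, truth = truth)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic_scene (seed %d): %d nuclei, %d Pax-7+, %d BrdU+, %d co-positive\n",
    x$seed, x$n_nuclei, x$n_pax7, x$n_brdu, x$n_copositive))
  invisible(x)
}

#' Generate a touching pair of nuclei (watershed fixture)
#'
#' Two overlapping soft disks forming a dumbbell with an intensity valley
#' between the peaks: a single connected bright region with two intensity
#' maxima, ground truth two objects. Used to exercise watershed splitting.
#'
#' @param separation Center distance in pixels; must be less than 1.2x the
#'   sum of the radii (the disks must genuinely touch).
#' @param radius Disk radius in pixels (both disks).
#' @param peak Peak intensity, gray levels.
#' @param noise_sigma Gaussian noise standard deviation, gray levels.
#' @param size Image side length in pixels (square frame).
#' @param seed Integer seed (noise only; geometry is deterministic).
#' @return A list with `image` (8-bit integer matrix) and `truth`
#'   (list with `n = 2`, the two centers and the radius).
#' @export
generate_touching_pair <- function(separation = 18, radius = 12, peak = 200,
                                   noise_sigma = 3, size = 64L, seed = 1L) {
  if (separation >= 1.2 * (2 * radius)) {
    stop("centers must be closer than 1.2x the sum of the radii")
  }
  mid <- (size + 1) / 2
  centers <- rbind(c(mid, mid - separation / 2), c(mid, mid + separation / 2))
  # wide cosine rims: the bridge between the flat cores stays bright enough
  # to remain one connected region after binarization, yet carries a genuine
  # intensity valley between the two maxima for the watershed to cut
  x <- render_disks(size, size, centers, c(radius, radius), peak, rim = 5)
  set.seed(as.integer(seed))
  if (noise_sigma > 0) x <- x + rnorm(length(x), 0, noise_sigma)
  list(image = as_gray8_storage(clamp8(round_half_up(matrix(x, size)))),
       truth = list(n = 2L, centers = centers, radius = radius))
}
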