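#' Pipeline configuration
#'
#' The ledger of every tunable parameter of the three channel chains and the
#' co-positivity counting. Defaults: rolling-ball radius 50 px for the
#' broad DAPI/BrdU backgrounds and 25 px for the punctate Pax-7 channel;
#' 3x3 structuring element with one iteration per named morphology step;
#' minimum object sizes 30 px (nuclei) and 20 px (marker objects);
#' watershed minima depth 10 gray levels (the suppression must exceed the
#' within-object intensity fluctuation left after sharpening, which roughly
#' triples the pixel noise); 3x3 normalized smoothing kernel for
#' the BrdU filtration step; intersection masks dilated 2 iterations during
#' co-positivity counting so marker fragments within one nucleus merge.
#'
#' @param dapi,pax7,brdu,copositivity Named lists overriding individual
#'   defaults of the corresponding channel (see the defaults in the
#'   function body; unknown names are an error).
#' @return An object of class `pipeline_config` (a nested named list).
#' @export
pipeline_config <- function(dapi = list(), pax7 = list(), brdu = list(),
                            copositivity = list()) {
  defaults <- list(
    dapi = list(
      rolling_ball_radius = 50L,
      threshold_method = "mean",
      erode_iterations = 1L,
      dilate_iterations = 1L,
      min_object_size = 30L
    ),
    pax7 = list(
      rolling_ball_radius = 25L,
      threshold_method = "renyi_entropy",
      renyi_variant = "shannon",
      watershed = TRUE,
      watershed_h = 10,
      erode_iterations = 1L,
      min_object_size = 20L
    ),
    brdu = list(
      rolling_ball_radius = 50L,
      threshold_method = "intermodes",
      kernel = matrix(1, 3L, 3L),
      kernel_normalize = TRUE,
      watershed = TRUE,
      watershed_h = 10,
      min_object_size = 20L
    ),
    copositivity = list(
      dilation_iterations = 2L,
      median_radius = 1L
    )
  )
  overrides <- list(dapi = dapi, pax7 = pax7, brdu = brdu,
                    copositivity = copositivity)
  cfg <- defaults
  for (section in names(overrides)) {
    ov <- overrides[[section]]
    if (length(ov)) {
      bad <- setdiff(names(ov), names(defaults[[section]]))
      if (length(bad)) {
        stop("unknown ", section, " config field(s): ", paste(bad, collapse = ", "))
      }
      cfg[[section]][names(ov)] <- ov
    }
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  methods <- c("mean", "renyi_entropy", "intermodes")
  for (ch in c("dapi", "pax7", "brdu")) {
    s <- cfg[[ch]]
    if (!s$threshold_method %in% methods) {
      stop(ch, ": threshold_method must be one of ", paste(methods, collapse = ", "))
    }
    num <- s[vapply(s, is.numeric, logical(1))]
    if (any(unlist(num) <= 0)) stop(ch, ": every numeric config field must be positive")
  }
  if (cfg$copositivity$dilation_iterations < 1) {
    stop("copositivity dilation_iterations must be >= 1")
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(config_json(x))
  cat("\n")
  invisible(x)
}

config_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   matrix = "rowmajor")
}

#' Write / read a pipeline configuration as JSON
#'
#' One JSON document holds one full [pipeline_config()]; round-trips
#' exactly (the BrdU kernel is stored row-major).
#'
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  writeLines(config_json(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!is.null(x$brdu$kernel)) x$brdu$kernel <- as.matrix(x$brdu$kernel)
  pipeline_config(dapi = x$dapi, pax7 = x$pax7, brdu = x$brdu,
                  copositivity = x$copositivity)
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical JSON serialization; embedded in every results table
#' for provenance.
#'
#' @param cfg A `pipeline_config`.
#' @return A character scalar.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(config_json(cfg), f)
  unname(tools::md5sum(f))
}

finish_stage_mask <- function(mask, trace, thresholds) {
  attr(mask, "trace") <- trace
  attr(mask, "thresholds") <- thresholds
  mask
}

save_stage <- function(img, dir, prefix, step, name) {
  if (is.null(dir)) return(invisible())
  if (is.logical(img)) img <- as_gray8_storage(img * 255L)
  write_gray_tiff(img, file.path(dir, sprintf("%s_%02d_%s.tif", prefix, step, name)))
}

#' DAPI nucleus-detection chain
#'
#' Executes, in order: rolling-ball background subtraction, 8-bit rescale,
#' sharpening, mean-threshold binarization, erosion ("reducing signals"),
#' dilation ("recovering signals"). The remaining objects are the nuclei.
#'
#' @param image 8-bit DAPI image (integer matrix in `[0, 255]`).
#' @param cfg A [pipeline_config()].
#' @param save_stages Optional directory; each stage is written there as an
#'   8-bit TIFF for visual audit.
#' @return Logical nucleus mask, with attributes `trace` (ordered stage
#'   names) and `thresholds` (the gray level used for binarization).
#' @export
process_dapi <- function(image, cfg = pipeline_config(), save_stages = NULL) {
  p <- cfg$dapi
  trace <- character()
  step <- function(name) trace <<- c(trace, name)

  save_stage(image, save_stages, "dapi", 1L, "input")
  x <- rolling_ball_subtract(image, p$rolling_ball_radius); step("rolling_ball_subtract")
  save_stage(x, save_stages, "dapi", 2L, "rolling_ball")
  x <- to_gray8(x); step("to_gray8")
  x <- sharpen(x); step("sharpen")
  save_stage(x, save_stages, "dapi", 3L, "sharpen")
  th <- threshold_mean(compute_histogram(x))
  m <- apply_threshold(x, th); step("threshold_mean")
  save_stage(m, save_stages, "dapi", 4L, "binarized")
  m <- erode_mask(m, p$erode_iterations); step("erode")
  save_stage(m, save_stages, "dapi", 5L, "erode")
  m <- dilate_mask(m, p$dilate_iterations); step("dilate")
  save_stage(m, save_stages, "dapi", 6L, "dilate")
  finish_stage_mask(m, trace, c(dapi = th$t))
}

#' Pax-7 object-detection chain
#'
#' Executes, in order: Sobel edge magnitude ("emphasize signal outline"),
#' 8-bit conversion, min-max luminance normalization, grayscale watershed
#' splitting (optional), rolling-ball background subtraction, Renyi-entropy
#' binarization, closing, outlining, hole filling, erosion, small-object
#' removal.
#'
#' @param image 8-bit Pax-7 image.
#' @inheritParams process_dapi
#' @return Logical Pax-7 object mask with `trace` and `thresholds`
#'   attributes.
#' @export
process_pax7 <- function(image, cfg = pipeline_config(), save_stages = NULL) {
  p <- cfg$pax7
  trace <- character()
  step <- function(name) trace <<- c(trace, name)

  save_stage(image, save_stages, "pax7", 1L, "input")
  x <- edge_magnitude(image); step("edge_magnitude")
  save_stage(x, save_stages, "pax7", 2L, "edges")
  x <- to_gray8(x); step("to_gray8")
  x <- normalize_range(x); step("normalize_range")
  if (isTRUE(p$watershed)) {
    x <- watershed_split(x, h = p$watershed_h); step("watershed_split")
    save_stage(x, save_stages, "pax7", 3L, "watershed")
  }
  x <- rolling_ball_subtract(x, p$rolling_ball_radius); step("rolling_ball_subtract")
  save_stage(x, save_stages, "pax7", 4L, "rolling_ball")
  if (max(x) == 0L) {
    # a blank channel carries no signal at all: zero objects, no threshold
    return(finish_stage_mask(matrix(FALSE, nrow(x), ncol(x)), trace,
                             c(pax7 = NA_integer_)))
  }
  th <- tryCatch(threshold_renyi_entropy(compute_histogram(x), variant = p$renyi_variant),
                 error = function(e) stop("Pax-7 channel: ", conditionMessage(e)))
  m <- apply_threshold(x, th); step("threshold_renyi_entropy")
  save_stage(m, save_stages, "pax7", 5L, "binarized")
  m <- close_mask(m); step("close")
  save_stage(m, save_stages, "pax7", 6L, "close")
  m <- outline_mask(m); step("outline")
  save_stage(m, save_stages, "pax7", 7L, "outline")
  m <- fill_holes(m); step("fill_holes")
  save_stage(m, save_stages, "pax7", 8L, "fill_holes")
  m <- erode_mask(m, p$erode_iterations); step("erode")
  save_stage(m, save_stages, "pax7", 9L, "erode")
  m <- remove_small_objects(m, p$min_object_size); step("remove_small_objects")
  save_stage(m, save_stages, "pax7", 10L, "small_removed")
  finish_stage_mask(m, trace, c(pax7 = th$t))
}

#' BrdU object-detection chain
#'
#' Executes, in order: 8-bit conversion, sharpening, rolling-ball background
#' subtraction, kernel-convolution filtration, grayscale watershed splitting
#' (optional), Intermodes binarization, small-object removal (which also
#' removes isolated pixels).
#'
#' A blank BrdU channel puts all histogram mass into one bin; Intermodes is
#' undefined there and the chain surfaces the not-bimodal error rather than
#' silently reporting zero objects.
#'
#' @param image 8-bit BrdU image.
#' @inheritParams process_dapi
#' @return Logical BrdU object mask with `trace` and `thresholds`
#'   attributes.
#' @export
process_brdu <- function(image, cfg = pipeline_config(), save_stages = NULL) {
  p <- cfg$brdu
  trace <- character()
  step <- function(name) trace <<- c(trace, name)

  save_stage(image, save_stages, "brdu", 1L, "input")
  x <- to_gray8(image); step("to_gray8")
  x <- sharpen(x); step("sharpen")
  save_stage(x, save_stages, "brdu", 2L, "sharpen")
  x <- rolling_ball_subtract(x, p$rolling_ball_radius); step("rolling_ball_subtract")
  save_stage(x, save_stages, "brdu", 3L, "rolling_ball")
  x <- convolve_kernel(x, p$kernel, normalize = p$kernel_normalize); step("convolve_kernel")
  save_stage(x, save_stages, "brdu", 4L, "filtered")
  if (isTRUE(p$watershed)) {
    x <- watershed_split(x, h = p$watershed_h); step("watershed_split")
    save_stage(x, save_stages, "brdu", 5L, "watershed")
  }
  th <- tryCatch(threshold_intermodes(compute_histogram(x)),
                 error = function(e) stop("BrdU channel: ", conditionMessage(e)))
  m <- apply_threshold(x, th); step("threshold_intermodes")
  save_stage(m, save_stages, "brdu", 6L, "binarized")
  m <- remove_small_objects(m, p$min_object_size); step("remove_small_objects")
  save_stage(m, save_stages, "brdu", 7L, "small_removed")
  finish_stage_mask(m, trace, c(brdu = th$t))
}

#' Count marker-co-positive objects from two masks
#'
#' Intersects the two masks (pixels where both signals are present),
#' optionally median-filters the intersection (used for the BrdU/DAPI merge
#' to suppress incorrect background detections), then dilates it
#' (`copositivity$dilation_iterations`) so that marker fragments within one
#' nucleus merge and are not counted multiple times. Returns the 8-connected
#' component count of the result; the counted mask is attached as attribute
#' `mask`.
#'
#' @param mask_a,mask_b Logical masks of equal dimensions.
#' @param cfg A [pipeline_config()].
#' @param median_first Apply a median filter to the intersection before
#'   dilating (the BrdU/DAPI merge variant).
#' @return Integer count, with the counted mask in attribute `mask`.
#' @export
count_copositive <- function(mask_a, mask_b, cfg = pipeline_config(),
                             median_first = FALSE) {
  mask_a <- as_mask(mask_a)
  mask_b <- as_mask(mask_b)
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("mask dimensions differ; channels must be co-registered")
  }
  inter <- mask_a & mask_b
  if (isTRUE(median_first)) {
    inter <- median_filter(as_gray8_storage(inter * 255L),
                           cfg$copositivity$median_radius) > 127L
  }
  merged <- dilate_mask0(inter, cfg$copositivity$dilation_iterations)
  n <- label_components(merged, 8L)$n
  structure(as.integer(n), mask = merged)
}

# dilation that tolerates an empty mask (EBImage is fine with it, but keep
# the iterations >= 1 contract of dilate_mask out of the counting path)
dilate_mask0 <- function(mask, iterations) {
  if (iterations >= 1) dilate_mask(mask, iterations) else mask
}

#' Quantify one three-channel section
#'
#' Runs the three channel chains on co-registered DAPI / Pax-7 / BrdU images
#' and counts, per section: nuclei (DAPI components of at least
#' `dapi$min_object_size` pixels), Pax-7 positive cells (Pax-7/DAPI merge),
#' BrdU positive cells (BrdU/DAPI merge, median-filtered), and BrdU/Pax-7
#' co-positive cells. Ratios are the counts divided by the nucleus count;
#' with zero nuclei the ratios are `NA` and `ratios_defined` is `FALSE`
#' rather than a division failure.
#'
#' @param dapi,pax7,brdu 8-bit images of identical dimensions.
#' @param cfg A [pipeline_config()].
#' @param section_id Optional identifier carried into the results row.
#' @param save_stages Optional directory for per-stage TIFFs.
#' @return An object of class `section_quantification`: counts, ratios,
#'   per-channel thresholds, the config used and its hash. Coerce with
#'   [as.data.frame()] for the tabular row.
#' @export
quantify_section <- function(dapi, pax7, brdu, cfg = pipeline_config(),
                             section_id = NA_character_, save_stages = NULL) {
  dims <- list(dim(dapi), dim(pax7), dim(brdu))
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]])) {
    stop("channel dimensions differ; channels must be co-registered")
  }
  dapi_mask <- process_dapi(dapi, cfg, save_stages)
  pax7_mask <- process_pax7(pax7, cfg, save_stages)
  brdu_mask <- process_brdu(brdu, cfg, save_stages)

  nuclei <- label_components(dapi_mask, 8L)
  n_nuclei <- sum(nuclei$sizes >= cfg$dapi$min_object_size)

  n_pax7 <- count_copositive(pax7_mask, dapi_mask, cfg)
  n_brdu <- count_copositive(brdu_mask, dapi_mask, cfg, median_first = TRUE)
  n_copositive <- count_copositive(brdu_mask, pax7_mask, cfg)

  defined <- n_nuclei > 0L
  ratio <- function(n) if (defined) as.numeric(n) / n_nuclei else NA_real_

  structure(list(
    section_id = section_id,
    n_nuclei = as.integer(n_nuclei),
    n_pax7 = as.integer(n_pax7),
    n_brdu = as.integer(n_brdu),
    n_copositive = as.integer(n_copositive),
    ratio_pax7 = ratio(n_pax7),
    ratio_brdu = ratio(n_brdu),
    ratio_copositive = ratio(n_copositive),
    ratios_defined = defined,
    thresholds = c(attr(dapi_mask, "thresholds"),
                   attr(pax7_mask, "thresholds"),
                   attr(brdu_mask, "thresholds")),
    traces = list(dapi = attr(dapi_mask, "trace"),
                  pax7 = attr(pax7_mask, "trace"),
                  brdu = attr(brdu_mask, "trace")),
    config_used = cfg,
    config_hash = config_hash(cfg)
  ), class = "section_quantification")
}

#' @export
print.section_quantification <- function(x, ...) {
  cat(sprintf(
    "section %s: %d nuclei | Pax-7+ %d (%.3f) | BrdU+ %d (%.3f) | co-positive %d (%.3f)\n",
    x$section_id, x$n_nuclei, x$n_pax7, x$ratio_pax7, x$n_brdu, x$ratio_brdu,
    x$n_copositive, x$ratio_copositive))
  invisible(x)
}

#' @export
as.data.frame.section_quantification <- function(x, ...) {
  data.frame(
    section_id = x$section_id,
    n_nuclei = x$n_nuclei, n_pax7 = x$n_pax7, n_brdu = x$n_brdu,
    n_copositive = x$n_copositive,
    ratio_pax7 = x$ratio_pax7, ratio_brdu = x$ratio_brdu,
    ratio_copositive = x$ratio_copositive,
    threshold_dapi = unname(x$thresholds["dapi"]),
    threshold_pax7 = unname(x$thresholds["pax7"]),
    threshold_brdu = unname(x$thresholds["brdu"]),
    config_hash = x$config_hash,
    package_version = as.character(packageVersion("satquant")),
    stringsAsFactors = FALSE
  )
}

#' Validate automated counts against manual counts
#'
#' Ordinary least squares of the automated values on the manual values for
#' paired sections, summarized by slope, intercept and the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot`. Either raw counts or ratios
#' may be supplied, as long as the same quantity is used on both sides;
#' report which alongside `R^2`.
#'
#' @param auto,manual Equal-length numeric vectors of paired measurements
#'   (`n >= 3`); `manual` must not be constant.
#' @return An object of class `validation_fit` with fields `slope`,
#'   `intercept`, `r_squared`, `n` and the fitted `model`.
#' @export
validate_against_manual <- function(auto, manual) {
  auto <- as.numeric(auto)
  manual <- as.numeric(manual)
  if (length(auto) != length(manual)) stop("auto and manual must be paired (equal length)")
  if (length(auto) < 3L) stop("need at least 3 paired observations")
  if (stats::var(manual) == 0) stop("manual values have zero variance; fit undefined")
  fit <- stats::lm(auto ~ manual)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((auto - mean(auto))^2)
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = 1 - ss_res / ss_tot,
    n = length(auto),
    model = fit
  ), class = "validation_fit")
}

#' @export
print.validation_fit <- function(x, ...) {
  cat(sprintf("validation_fit (n = %d): auto = %.4f * manual %+.4f, R^2 = %.4f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}
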