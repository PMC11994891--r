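#' Run the quantification over a manifest of sections
#'
#' The manifest is a data frame (or CSV path) with columns `section_id`,
#' `dapi_path`, `pax7_path`, `brdu_path` and optionally `group_label`. Each
#' section is quantified independently; a failing section contributes a row
#' with its error message in the `error` column and the run continues.
#' Output rows embed the config hash and package version, and re-running
#' with the same inputs reproduces the table byte-for-byte.
#'
#' @param manifest Data frame or CSV path as above; `section_id` must be
#'   unique.
#' @param cfg A [pipeline_config()].
#' @param aggregate_by Optional column name (e.g. `"group_label"`): also
#'   return per-group means of counts and ratios in attribute `aggregated`
#'   (sections of one animal are typically averaged to one animal-level
#'   value).
#' @return A data frame with one row per manifest row (quantification
#'   columns as in [as.data.frame.section_quantification()], plus `error`,
#'   `NA` on success), with attributes `n_failed` and, if requested,
#'   `aggregated`.
#' @export
run_batch <- function(manifest, cfg = pipeline_config(), aggregate_by = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  required <- c("section_id", "dapi_path", "pax7_path", "brdu_path")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(manifest) == 0L) stop("empty manifest")
  if (anyDuplicated(manifest$section_id)) stop("section_id values must be unique")

  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    out <- tryCatch({
      q <- quantify_section(read_gray_tiff(m$dapi_path),
                            read_gray_tiff(m$pax7_path),
                            read_gray_tiff(m$brdu_path),
                            cfg, section_id = m$section_id)
      cbind(as.data.frame(q), error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      empty <- as.data.frame(
        c(list(section_id = m$section_id),
          stats::setNames(rep(list(NA_integer_), 4L),
                          c("n_nuclei", "n_pax7", "n_brdu", "n_copositive")),
          stats::setNames(rep(list(NA_real_), 3L),
                          c("ratio_pax7", "ratio_brdu", "ratio_copositive")),
          stats::setNames(rep(list(NA_integer_), 3L),
                          c("threshold_dapi", "threshold_pax7", "threshold_brdu")),
          list(config_hash = config_hash(cfg),
               package_version = as.character(packageVersion("satquant")))),
        stringsAsFactors = FALSE)
      cbind(empty, error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    if ("group_label" %in% names(manifest)) out$group_label <- m$group_label
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "n_failed") <- sum(!is.na(res$error))

  if (!is.null(aggregate_by)) {
    if (!aggregate_by %in% names(res)) stop("aggregate_by column not present: ", aggregate_by)
    ok <- res[is.na(res$error), ]
    value_cols <- c("n_nuclei", "n_pax7", "n_brdu", "n_copositive",
                    "ratio_pax7", "ratio_brdu", "ratio_copositive")
    agg <- stats::aggregate(ok[value_cols], by = ok[aggregate_by], FUN = mean)
    attr(res, "aggregated") <- agg
  }
  res
}

#' Write batch results with a JSON sidecar
#'
#' Writes the results CSV and a `<path>.json` sidecar holding the
#' per-section thresholds, the config hash and the package version.
#'
#' @param results Data frame from [run_batch()].
#' @param path Output CSV path.
#' @param cfg The `pipeline_config` used (serialized into the sidecar).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, cfg = NULL) {
  write.csv(results, path, row.names = FALSE)
  sidecar <- list(
    config_hash = unique(results$config_hash),
    package_version = unique(results$package_version),
    thresholds = results[c("section_id", "threshold_dapi",
                           "threshold_pax7", "threshold_brdu")]
  )
  if (!is.null(cfg)) sidecar$config <- unclass(cfg)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}
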