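# small, fast scenes for pipeline-level tests
small_params <- function(...) {
  scene_params(width = 320L, height = 240L, n_nuclei = 25L,
               pax7_frac = 0.2, brdu_frac = 0.12, n_copositive = 2L, ...)
}

test_that("each channel chain applies exactly its documented stage sequence", {
  sc <- generate_scene(small_params(), seed = 3)
  cfg <- pipeline_config()
  expect_equal(attr(process_dapi(sc$dapi, cfg), "trace"),
               c("rolling_ball_subtract", "to_gray8", "sharpen",
                 "threshold_mean", "erode", "dilate"))
  expect_equal(attr(process_pax7(sc$pax7, cfg), "trace"),
               c("edge_magnitude", "to_gray8", "normalize_range",
                 "watershed_split", "rolling_ball_subtract",
                 "threshold_renyi_entropy", "close", "outline", "fill_holes",
                 "erode", "remove_small_objects"))
  expect_equal(attr(process_brdu(sc$brdu, cfg), "trace"),
               c("to_gray8", "sharpen", "rolling_ball_subtract",
                 "convolve_kernel", "watershed_split",
                 "threshold_intermodes", "remove_small_objects"))
})

test_that("channel chains are deterministic and recover synthetic objects", {
  sc <- generate_scene(small_params(), seed = 4)
  cfg <- pipeline_config()
  m1 <- process_dapi(sc$dapi, cfg)
  m2 <- process_dapi(sc$dapi, cfg)
  expect_identical(m1, m2)
  lc <- label_components(m1)
  expect_equal(sum(lc$sizes >= cfg$dapi$min_object_size), sc$truth$n_nuclei)
  expect_true(abs(label_components(process_pax7(sc$pax7, cfg))$n -
                  sc$truth$n_pax7) <= 1)
  expect_true(abs(label_components(process_brdu(sc$brdu, cfg))$n -
                  sc$truth$n_brdu) <= 1)
})

test_that("blank channels behave as documented per chain", {
  blank <- matrix(0L, 60, 80)
  expect_equal(sum(process_dapi(blank)), 0L)
  suppressWarnings(pm <- process_pax7(blank))
  expect_equal(sum(pm), 0L)
  expect_true(is.na(attr(pm, "thresholds")["pax7"]))
  # Intermodes is undefined with all mass in one bin: surfaced, not hidden
  expect_error(process_brdu(blank), "BrdU channel.*bimodal")
})

test_that("count_copositive intersects, merges fragments, and validates dims", {
  a <- matrix(FALSE, 40, 40); a[5:10, 5:10] <- TRUE
  b <- matrix(FALSE, 40, 40); b[20:25, 20:25] <- TRUE
  expect_equal(as.integer(count_copositive(a, b)), 0L)

  both <- a | b
  expect_equal(as.integer(count_copositive(both, both)), 2L)

  # one nucleus overlapped by two marker fragments within dilation reach -> 1
  nucleus <- matrix(FALSE, 40, 40); nucleus[10:22, 10:22] <- TRUE
  marker <- matrix(FALSE, 40, 40)
  marker[12:14, 12:14] <- TRUE
  marker[18:20, 18:20] <- TRUE   # 4 px gap, bridged by 2 dilation passes
  expect_equal(label_components(marker & nucleus)$n, 2L)
  expect_equal(as.integer(count_copositive(marker, nucleus)), 1L)

  expect_error(count_copositive(a, matrix(FALSE, 10, 10)), "dimensions")
})

test_that("the median-filtered co-positivity variant suppresses single-pixel overlap", {
  a <- matrix(FALSE, 30, 30); a[15, 15] <- TRUE; a[5:9, 5:9] <- TRUE
  b <- matrix(FALSE, 30, 30); b[15, 15] <- TRUE; b[5:9, 5:9] <- TRUE
  expect_equal(as.integer(count_copositive(a, b)), 2L)
  expect_equal(as.integer(count_copositive(a, b, median_first = TRUE)), 1L)
})

test_that("quantify_section recovers a small synthetic section and records provenance", {
  sc <- generate_scene(small_params(noise_sigma = 0, background_amplitude = 0),
                       seed = 5)
  cfg <- pipeline_config()
  q <- quantify_section(sc$dapi, sc$pax7, sc$brdu, cfg, section_id = "a")
  expect_s3_class(q, "section_quantification")
  expect_equal(q$n_nuclei, sc$truth$n_nuclei)
  expect_equal(q$n_pax7, sc$truth$n_pax7)
  expect_equal(q$n_brdu, sc$truth$n_brdu)
  expect_equal(q$n_copositive, sc$truth$n_copositive)
  expect_equal(q$ratio_pax7, q$n_pax7 / q$n_nuclei)
  expect_true(q$ratios_defined)
  expect_true(q$n_copositive <= min(q$n_pax7, q$n_brdu))
  expect_match(q$config_hash, "^[0-9a-f]{32}$")
  df <- as.data.frame(q)
  expect_equal(df$n_nuclei, q$n_nuclei)
  expect_equal(df$threshold_brdu, unname(q$thresholds["brdu"]))

  expect_error(quantify_section(sc$dapi, sc$pax7, matrix(0L, 10, 10)),
               "dimensions")
})

test_that("zero nuclei flags the ratios instead of failing", {
  sc <- generate_scene(small_params(noise_sigma = 0, background_amplitude = 0),
                       seed = 6)
  blank <- matrix(0L, 240L, 320L)
  suppressWarnings(q <- quantify_section(blank, sc$pax7, sc$brdu))
  expect_equal(q$n_nuclei, 0L)
  expect_false(q$ratios_defined)
  expect_true(is.na(q$ratio_pax7))
})

test_that("raising min_object_size never increases any object count", {
  sc <- generate_scene(small_params(), seed = 7)
  sizes <- c(5L, 20L, 60L)
  counts <- vapply(sizes, function(s) {
    cfg <- pipeline_config(pax7 = list(min_object_size = s))
    label_components(process_pax7(sc$pax7, cfg))$n
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("validate_against_manual matches closed-form least squares", {
  fit <- validate_against_manual(c(0.1, 0.2, 0.3, 0.4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)

  fit2 <- validate_against_manual(2 * c(0.1, 0.3, 0.2), c(0.1, 0.3, 0.2))
  expect_equal(fit2$r_squared, 1)
  expect_equal(fit2$slope, 2)

  # pairs (auto, manual) = (1,1), (2,2), (3,4): hand OLS gives
  # Sxy = 3, Sxx = 14/3, Syy = 2, R^2 = Sxy^2/(Sxx Syy) = 27/28
  fit3 <- validate_against_manual(c(1, 2, 3), c(1, 2, 4))
  expect_equal(fit3$r_squared, 27 / 28)
  expect_equal(fit3$slope, 9 / 14)
  # independent check through the correlation coefficient
  expect_equal(fit3$r_squared, cor(c(1, 2, 3), c(1, 2, 4))^2)

  expect_error(validate_against_manual(1:2, 1:3), "equal length")
  expect_error(validate_against_manual(1:2, 1:2), "at least 3")
  expect_error(validate_against_manual(c(1, 2, 3), c(2, 2, 2)), "variance")
})

test_that("pipeline configuration validates, serializes and hashes stably", {
  cfg <- pipeline_config(pax7 = list(min_object_size = 15L))
  expect_equal(cfg$pax7$min_object_size, 15L)
  expect_error(pipeline_config(dapi = list(nope = 1)), "unknown")
  expect_error(pipeline_config(dapi = list(threshold_method = "otsu")),
               "threshold_method")
  expect_error(pipeline_config(brdu = list(rolling_ball_radius = -3)),
               "positive")

  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_pipeline_config(cfg, f)
  back <- read_pipeline_config(f)
  expect_equal(unclass(back), unclass(cfg))
  expect_identical(config_hash(cfg), config_hash(back))
  expect_false(config_hash(cfg) == config_hash(pipeline_config()))
})

write_scene_tiffs <- function(sc, dir, id) {
  paths <- file.path(dir, paste0(id, "_", c("dapi", "pax7", "brdu"), ".tif"))
  write_gray_tiff(sc$dapi, paths[1])
  write_gray_tiff(sc$pax7, paths[2])
  write_gray_tiff(sc$brdu, paths[3])
  paths
}

test_that("run_batch isolates per-section failures and reproduces byte-identical output", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  p <- small_params(noise_sigma = 0, background_amplitude = 0)
  p1 <- write_scene_tiffs(generate_scene(p, seed = 11), dir, "s1")
  p2 <- write_scene_tiffs(generate_scene(p, seed = 12), dir, "s2")
  manifest <- data.frame(
    section_id = c("s1", "s2", "s3"),
    dapi_path = c(p1[1], p2[1], file.path(dir, "missing.tif")),
    pax7_path = c(p1[2], p2[2], p1[2]),
    brdu_path = c(p1[3], p2[3], p1[3]),
    group_label = c("ctl", "ctl", "trt"),
    stringsAsFactors = FALSE
  )
  res <- run_batch(manifest, pipeline_config())
  expect_equal(nrow(res), 3L)
  expect_equal(attr(res, "n_failed"), 1L)
  expect_true(is.na(res$error[1]) && is.na(res$error[2]))
  expect_match(res$error[3], "not found")
  ok <- res[1:2, ]
  expect_true(all(ok$ratio_pax7 >= 0 & ok$ratio_pax7 <= 1))

  out1 <- file.path(dir, "r1.csv"); out2 <- file.path(dir, "r2.csv")
  write_results(run_batch(manifest, pipeline_config()), out1)
  write_results(run_batch(manifest, pipeline_config()), out2)
  expect_identical(readLines(out1), readLines(out2))
  expect_identical(unname(tools::md5sum(out1)), unname(tools::md5sum(out2)))

  agg <- attr(run_batch(manifest, pipeline_config(), aggregate_by = "group_label"),
              "aggregated")
  expect_equal(nrow(agg), 1L) # only the ctl group has successful sections
  expect_equal(agg$n_nuclei, mean(ok$n_nuclei))

  expect_error(run_batch(manifest[0, ], pipeline_config()), "empty")
  expect_error(run_batch(manifest[c(1, 1), ], pipeline_config()), "unique")
  expect_error(run_batch(manifest[, -2], pipeline_config()), "lacks")
})
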