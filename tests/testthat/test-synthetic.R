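test_that("scene truth counts are exact by construction", {
  p <- scene_params(n_nuclei = 100L, pax7_frac = 0.2, brdu_frac = 0.1,
                    n_copositive = 5L)
  sc <- generate_scene(p, seed = 42)
  expect_equal(sc$truth$n_nuclei, 100L)
  expect_equal(sc$truth$n_pax7, 20L)
  expect_equal(sc$truth$n_brdu, 10L)
  expect_equal(sc$truth$n_copositive, 5L)
  nuc <- sc$truth$nuclei
  expect_equal(sum(nuc$is_pax7), 20L)
  expect_equal(sum(nuc$is_brdu & nuc$is_pax7), 5L)
  expect_equal(dim(sc$dapi), c(480L, 640L))
  expect_error(scene_params(n_copositive = 50L), "exceed")
})

test_that("generation is byte-reproducible and seed-sensitive", {
  p <- scene_params(width = 200L, height = 150L, n_nuclei = 12L,
                    n_copositive = 1L)
  a <- generate_scene(p, seed = 9)
  b <- generate_scene(p, seed = 9)
  expect_identical(a$dapi, b$dapi)
  expect_identical(a$pax7, b$pax7)
  expect_identical(a$brdu, b$brdu)
  expect_identical(a$truth$nuclei, b$truth$nuclei)

  c <- generate_scene(p, seed = 10)
  expect_false(identical(a$dapi, c$dapi))
  expect_equal(c$truth$n_nuclei, a$truth$n_nuclei) # truth contract unchanged
})

test_that("changing the noise level does not reshuffle nucleus placement", {
  p1 <- scene_params(width = 200L, height = 150L, n_nuclei = 12L,
                     n_copositive = 1L, noise_sigma = 0)
  p2 <- scene_params(width = 200L, height = 150L, n_nuclei = 12L,
                     n_copositive = 1L, noise_sigma = 15)
  a <- generate_scene(p1, seed = 21)
  b <- generate_scene(p2, seed = 21)
  expect_identical(a$truth$nuclei[c("center_row", "center_col", "radius")],
                   b$truth$nuclei[c("center_row", "center_col", "radius")])
})

test_that("nucleus placement respects the minimum-distance constraint", {
  p <- scene_params(width = 300L, height = 200L, n_nuclei = 30L,
                    n_copositive = 2L)
  sc <- generate_scene(p, seed = 2)
  xy <- as.matrix(sc$truth$nuclei[c("center_row", "center_col")])
  expect_true(min(dist(xy)) >= p$min_distance)
  # an unplaceable request errors instead of looping forever
  expect_error(
    generate_scene(scene_params(width = 60L, height = 60L, n_nuclei = 200L,
                                n_copositive = 1L), seed = 1),
    "could not place")
})

test_that("marker disks are co-located with their nuclei", {
  p <- scene_params(width = 250L, height = 200L, n_nuclei = 15L,
                    noise_sigma = 0, background_amplitude = 0,
                    n_copositive = 1L)
  sc <- generate_scene(p, seed = 13)
  nuc <- sc$truth$nuclei
  for (i in which(nuc$is_pax7)) {
    r <- round(nuc$center_row[i]); c <- round(nuc$center_col[i])
    expect_gt(sc$pax7[r, c], 100)
    expect_gt(sc$dapi[r, c], 100)
  }
  # no Pax-7 signal where no Pax-7 nucleus lies
  far <- sc$pax7
  for (i in which(nuc$is_pax7)) {
    rr <- pmax(1, round(nuc$center_row[i]) - 10):pmin(200, round(nuc$center_row[i]) + 10)
    cc <- pmax(1, round(nuc$center_col[i]) - 10):pmin(250, round(nuc$center_col[i]) + 10)
    far[rr, cc] <- 0L
  }
  expect_true(all(far == 0L))
})

test_that("a touching pair is one connected bright region with two maxima", {
  tp <- generate_touching_pair(separation = 18, radius = 12, noise_sigma = 0,
                               seed = 1)
  expect_equal(tp$truth$n, 2L)
  mask <- tp$image > 100L
  expect_equal(label_components(mask)$n, 1L)
  # two local maxima at the disk cores, valley on the bisector
  mid <- (ncol(tp$image) + 1) / 2
  row <- tp$image[ (nrow(tp$image) + 1) / 2, ]
  expect_lt(row[mid], max(row))
  expect_equal(sum(row == max(row)) >= 2, TRUE)
  expect_error(generate_touching_pair(separation = 40, radius = 12), "closer")
})

test_that("watershed-enabled pipelines split a touching pair, disabled merge it", {
  tp <- generate_touching_pair(seed = 5)
  on_cfg <- pipeline_config()
  off_cfg <- pipeline_config(brdu = list(watershed = FALSE))
  expect_equal(label_components(process_brdu(tp$image, on_cfg))$n, 2L)
  expect_equal(label_components(process_brdu(tp$image, off_cfg))$n, 1L)
  # the dividing line sits within +/- 1 px of the perpendicular bisector
  x <- watershed_split(to_gray8(tp$image), 10)
  mid <- (ncol(x) + 1) / 2
  cut_cols <- which(apply(x == 0L & tp$image > 100L, 2, any))
  expect_true(length(cut_cols) > 0)
  expect_true(all(abs(cut_cols - mid) <= 1))
})

test_that("the Pax-7 outline-and-fill chain keeps a fully merged pair as one object", {
  # hole filling re-solidifies everything inside the outermost closed edge
  # contour, so this chain cannot split a dumbbell regardless of watershed
  tp <- generate_touching_pair(seed = 6)
  for (ws in c(TRUE, FALSE)) {
    cfg <- pipeline_config(pax7 = list(watershed = ws))
    expect_equal(label_components(process_pax7(tp$image, cfg))$n, 1L)
  }
})

test_that("count error grows no faster than noise on average", {
  sigmas <- c(0, 5, 15)
  err <- vapply(sigmas, function(s) {
    e <- 0
    for (seed in 1:20) {
      p <- scene_params(width = 320L, height = 240L, n_nuclei = 25L,
                        n_copositive = 2L, noise_sigma = s)
      sc <- generate_scene(p, seed = seed)
      lc <- label_components(process_dapi(sc$dapi))
      # the quantification rule: components of at least the minimum nucleus size
      n <- sum(lc$sizes >= pipeline_config()$dapi$min_object_size)
      e <- e + abs(n - sc$truth$n_nuclei)
    }
    e / 20
  }, numeric(1))
  expect_true(err[1] <= err[2] + 1e-9)
  expect_true(err[2] <= err[3] + 1e-9)
})
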