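test_that("fat/tissue classification applies the boundary convention", {
  d <- c(4, 1, 1)
  p <- array(c(10, 40, 41, 90), d)
  mk <- array(TRUE, d)
  lab <- classify_fat_voxels(p, mk, threshold = 40)
  expect_equal(as.vector(lab), c(1L, 1L, 2L, 2L))   # == threshold is tissue
  expect_equal(sum(classify_fat_voxels(p, mk, 100) == 2L), 0)
  mk2 <- array(c(TRUE, FALSE, TRUE, TRUE), d)
  lab2 <- classify_fat_voxels(p, mk2, 40)
  expect_equal(as.vector(lab2), c(1L, 0L, 2L, 2L))
  expect_error(classify_fat_voxels(p, mk, 0), "threshold")
})

test_that("classification of a noise-free phantom matches the ground truth", {
  res <- run_pipeline(pipeline_config(seed = 9,
                                      phantom = phantom_config(seed = 9),
                                      thresholds = "fixed", fixed_threshold = 40,
                                      with_mt = FALSE),
                      out_dir = withr::local_tempdir())
  tr <- res$truth
  truth_lab <- ifelse(tr$background, 0L, ifelse(tr$ff_true > 40, 2L, 1L))
  expect_equal(as.vector(res$labels), as.vector(truth_lab))
})

test_that("box quantification reproduces printed-count arithmetic", {
  # 68,032 fat voxels at 200 um isotropic -> 0.54 cm^3 of fat
  d <- c(60, 60, 30)
  lab <- array(1L, d)
  lab[seq_len(68032)] <- 2L
  row <- quantify_box(lab, NULL, spacing = c(0.2, 0.2, 0.2), threshold = 40)
  expect_equal(round(row$fat_cm3, 2), 0.54)
  expect_equal(row$fat_voxels, 68032)
  # 10^3 all-fat voxels at 1 mm isotropic
  lab2 <- array(2L, c(10, 10, 10))
  r2 <- quantify_box(lab2, NULL, spacing = c(1, 1, 1))
  expect_equal(r2$fat_cm3, 1.0)
  expect_equal(r2$fat_ratio_pct, 100)
  # conservation holds exactly
  expect_equal(row$fat_cm3 + row$tissue_cm3, row$total_cm3)
  expect_equal(r2$fat_cm3 + r2$tissue_cm3, r2$total_cm3)
})

test_that("boxes convert mm bounds to half-open voxel ranges", {
  d <- c(10, 10, 10)
  lab <- array(1L, d)
  lab[1:5, 1:10, 1:10] <- 2L
  sp <- c(1, 1, 1)
  b <- roi_box("left", origin_mm = c(0, 0, 0), size_mm = c(5, 10, 10))
  r <- quantify_box(lab, b, sp)
  expect_equal(r$fat_voxels, 500)
  expect_equal(r$fat_ratio_pct, 100)
  expect_error(roi_box("bad", c(0, 0, 0), c(0, 1, 1)), "positive")
  expect_warning(r0 <- quantify_box(lab, roi_box("out", c(100, 100, 100),
                                                 c(5, 5, 5)), sp), "intersect")
  expect_equal(r0$total_cm3, 0)
  # disjoint boxes tiling the grid sum to the whole-volume counts
  lab3 <- classify_fat_voxels(array(runif(1000, 0, 100), d), array(TRUE, d), 50)
  halves <- list(roi_box("a", c(0, 0, 0), c(5, 10, 10)),
                 roi_box("b", c(5, 0, 0), c(5, 10, 10)))
  rep <- quantify_regions(lab3, halves, sp)
  expect_equal(rep$fat_voxels[1], sum(rep$fat_voxels[2:3]))
  expect_equal(rep$total_cm3[1], sum(rep$total_cm3[2:3]))
})

test_that("fat voxel counts are non-increasing in the threshold", {
  set.seed(13)
  d <- c(8, 8, 8)
  p <- array(runif(prod(d), 0, 100), d)
  mk <- array(TRUE, d)
  counts <- sapply(c(10, 30, 50, 70, 90), function(t)
    sum(classify_fat_voxels(p, mk, t) == 2L))
  expect_true(all(diff(counts) <= 0))
})

test_that("composites separate fat from high-transfer tissue", {
  d <- c(3, 1, 1)
  pd <- structure(list(values = array(c(80, 10, 10), d),
                       mask = array(TRUE, d)), class = "pdff_map")
  mt <- structure(list(values = array(c(90, 90, 50), d),
                       valid = array(TRUE, d)), class = "mtr_map")
  cp <- overlay_composite(pd, mt, threshold = 40, high_mtr = 70)
  expect_equal(as.vector(cp$label), c(2L, 1L, 0L))
  expect_equal(cp$overlay[1, 1, 1], 80)
  expect_true(is.na(cp$overlay[2, 1, 1]))
  expect_equal(cp$base, mt$values)
})

test_that("the pipeline is deterministic and supports partial input", {
  cfg <- pipeline_config(seed = 5,
                         phantom = phantom_config(dim = c(16, 16, 16), seed = 5),
                         thresholds = "fixed", fixed_threshold = 40)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cfg, d1)
  r2 <- run_pipeline(cfg, d2)
  expect_identical(readBin(file.path(d1, "report.csv"), "raw", 1e6),
                   readBin(file.path(d2, "report.csv"), "raw", 1e6))
  expect_identical(r1$report, r2$report)
  expect_true(file.exists(file.path(d1, "mtr.nii.gz")))
  # without MT volumes: water-fat half only, MTR flagged absent
  cfg2 <- pipeline_config(seed = 5,
                          phantom = phantom_config(dim = c(16, 16, 16), seed = 5),
                          thresholds = "fixed", fixed_threshold = 40,
                          with_mt = FALSE)
  d3 <- withr::local_tempdir()
  r3 <- run_pipeline(cfg2, d3)
  expect_null(r3$mtr)
  expect_false(file.exists(file.path(d3, "mtr.nii.gz")))
  log <- jsonlite::read_json(file.path(d3, "run_log.json"))
  expect_true(isTRUE(log$mtr_absent))
})

test_that("the end-to-end fat ratio matches the phantom truth", {
  res <- run_pipeline(pipeline_config(seed = 10,
                                      phantom = phantom_config(seed = 10),
                                      thresholds = "fixed",
                                      fixed_threshold = 40),
                      out_dir = withr::local_tempdir())
  tr <- res$truth
  truth_ratio <- 100 * sum(tr$ff_true > 40 & !tr$background) / sum(!tr$background)
  expect_lt(abs(res$report$fat_ratio_pct[1] - truth_ratio), 1)
})

test_that("a JSON config drives the pipeline to the same result", {
  cfgfile <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 5,
                            phantom = list(dim = c(16, 16, 16), seed = 5),
                            thresholds = "fixed", fixed_threshold = 40,
                            with_mt = FALSE),
                       cfgfile, auto_unbox = TRUE)
  d1 <- withr::local_tempdir()
  r <- run_pipeline(cfgfile, d1)
  rref <- run_pipeline(pipeline_config(seed = 5,
                                       phantom = phantom_config(dim = c(16, 16, 16),
                                                                seed = 5),
                                       thresholds = "fixed", fixed_threshold = 40,
                                       with_mt = FALSE),
                       withr::local_tempdir())
  expect_identical(r$report, rref$report)
})
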