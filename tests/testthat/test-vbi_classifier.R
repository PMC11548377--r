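test_that("water extraction masks exactly the pixels above the NDWI cut", {
  geo <- grid_geo(4, 4, res = 30)
  up <- index_raster(matrix(0.5, 4, 4), "NDWI", geo)
  down <- index_raster(matrix(-0.5, 4, 4), "NDWI", geo)
  expect_true(all(extract_water_mask(up, 0)))
  expect_false(any(extract_water_mask(down, 0)))
  half <- index_raster(rbind(matrix(0.5, 2, 4), matrix(-0.5, 2, 4)),
                       "NDWI", geo)
  m <- extract_water_mask(half, 0)
  expect_equal(sum(m), 8)
  expect_true(all(m[1:2, ]))
  # nodata pixels never enter the mask
  withna <- index_raster(matrix(c(0.5, NA), 4, 4), "NDWI", geo)
  expect_equal(sum(extract_water_mask(withna, 0)), 8)
  expect_error(extract_water_mask(index_raster(matrix(1, 4, 4), "AVI", geo)),
               "NDWI")
})

test_that("AVI threshold calibration is mean + k_sigma * sd over water", {
  geo <- grid_geo(10, 10, res = 30)
  const <- index_raster(matrix(-0.1, 10, 10), "AVI", geo)
  full <- matrix(TRUE, 10, 10)
  expect_equal(calibrate_avi_threshold(const, full, k_sigma = 0), -0.1)
  expect_equal(calibrate_avi_threshold(const, full, k_sigma = 5), -0.1)
  three <- index_raster(matrix(c(-2, 0, 2, rep(NA, 97)), 10, 10), "AVI", geo)
  expect_equal(
    calibrate_avi_threshold(three, full, k_sigma = 0, min_pixels = 3), 0)
  # large-sample statistic approaches mu + 2 sigma
  set.seed(314)
  n <- 1e4
  vals <- matrix(rnorm(n, mean = -0.03, sd = 0.01), 100, 100)
  big <- index_raster(vals, "AVI", grid_geo(100, 100, res = 30))
  t_avi <- calibrate_avi_threshold(big, matrix(TRUE, 100, 100), k_sigma = 2)
  expect_lt(abs(t_avi - (-0.03 + 2 * 0.01)), 1e-3)
  # too few pixels -> explicit error carrying the count
  tiny <- matrix(FALSE, 10, 10); tiny[1:5] <- TRUE
  expect_error(calibrate_avi_threshold(const, tiny), "5 valid water pixels")
})

test_that("the tree assigns the default leaf and honors all four branches", {
  spectra <- default_class_spectra()
  th <- vbi_thresholds(t_avi = 0)
  for (cl in names(spectra)) {
    s <- uniform_scene(spectra[[cl]], 3, 3)
    got <- class_labels(classify_scene(s, thresholds = th))[1, 1]
    expect_equal(got, cl)
  }
})

test_that("wide-separation synthetic scenes classify to ground truth", {
  g <- generate_scene(64, 64, noise_sd = 0, seed = 1)
  cm <- classify_scene(g$scene)
  expect_identical(cm$codes, g$truth$codes)
  expect_true(cm$provenance$thresholds$t_avi_calibrated)
  g2 <- generate_scene(64, 64, noise_sd = 0.01, seed = 2)
  cm2 <- classify_scene(g2$scene)
  expect_gte(mean(cm2$codes == g2$truth$codes), 0.95)
})

test_that("AV/non-AV partition matches the AVI cut exactly", {
  g <- generate_scene(48, 48, noise_sd = 0.02, seed = 9)
  th <- vbi_thresholds(t_avi = -0.01)
  cm <- classify_scene(g$scene, thresholds = th)
  avi <- compute_avi(g$scene)
  av <- cm$codes %in% VBI_CLASSES[c("SAV", "FEAV")]
  expect_identical(matrix(av, 48, 48), avi$values > -0.01)
})

test_that("raising a threshold never grows the class it gates", {
  g <- generate_scene(48, 48, noise_sd = 0.03, seed = 12)
  count <- function(cm, cl) sum(cm$codes == VBI_CLASSES[[cl]])
  base <- classify_scene(g$scene, thresholds = vbi_thresholds(t_avi = -0.02))
  up_avi <- classify_scene(g$scene, thresholds = vbi_thresholds(t_avi = 0.01))
  expect_lte(count(up_avi, "SAV") + count(up_avi, "FEAV"),
             count(base, "SAV") + count(base, "FEAV"))
  up_ndvi <- classify_scene(g$scene,
                            thresholds = vbi_thresholds(t_avi = -0.02,
                                                        t_ndvi = 0.5))
  expect_lte(count(up_ndvi, "FEAV"), count(base, "FEAV"))
  up_fai <- classify_scene(g$scene,
                           thresholds = vbi_thresholds(t_avi = -0.02,
                                                       t_fai = 0.05))
  expect_lte(count(up_fai, "AB"), count(base, "AB"))
})

test_that("classification commutes with cropping when the cut is fixed", {
  g <- generate_scene(40, 40, noise_sd = 0.02, seed = 21)
  th <- vbi_thresholds(t_avi = -0.01)
  whole <- classify_scene(g$scene, thresholds = th)
  rows <- 5:30; cols <- 10:35
  then_crop <- crop_classmap(whole, rows, cols)
  crop_then <- classify_scene(crop_scene(g$scene, rows, cols),
                              thresholds = th)
  expect_identical(then_crop$codes, crop_then$codes)
  expect_equal(then_crop$geo, crop_then$geo)
})

test_that("the vectorized tree equals the per-pixel reference classifier", {
  th <- vbi_thresholds(t_avi = -0.005)
  for (seed in 1:10) {
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    scene <- random_scene(nr, nc, seed = seed, na_frac = 0.05)
    got <- classify_scene(scene, thresholds = th)$codes
    expect_identical(got, oracle_classify(scene, th))
  }
})

test_that("lake masking excludes land before classification", {
  g <- generate_scene(20, 20, noise_sd = 0, seed = 4)
  lake <- matrix(FALSE, 20, 20); lake[1:10, ] <- TRUE
  cm <- classify_scene(g$scene, thresholds = vbi_thresholds(t_avi = -0.01),
                       lake_mask = lake)
  expect_true(all(cm$codes[11:20, ] == VBI_CLASSES[["NODATA"]]))
  expect_true(all(cm$codes[1:10, ] != VBI_CLASSES[["NODATA"]]))
})

test_that("batch classification is element-wise and failure-tolerant", {
  empty <- classify_batch(list(), as.Date(character(0)))
  expect_length(empty$maps, 0)
  g <- generate_scene(32, 32, noise_sd = 0, seed = 6)
  two <- classify_batch(list(g$scene, g$scene),
                        c("2001-04-20", "2002-04-20"))
  expect_identical(two$maps[[1]]$codes, two$maps[[2]]$codes)
  expect_length(two$failures, 0)
  # a scene whose calibration must fail (no water at all) is reported,
  # not fatal
  feav_only <- uniform_scene(default_class_spectra()$FEAV, 8, 8)
  mixed <- classify_batch(list(g$scene, feav_only),
                          c("2003-04-20", "2004-04-20"))
  expect_length(mixed$maps, 1)
  expect_match(mixed$failures[["2004-04-20"]], "water pixels")
})

test_that("a declining synthetic lake series yields declining SAV fractions", {
  series <- generate_lake_timeseries(5, sav_start = 0.6, sav_end = 0.1,
                                     seed = 8, noise_sd = 0.005)
  batch <- classify_batch(lapply(series, `[[`, "scene"),
                          sapply(series, function(e) as.character(e$date)))
  expect_length(batch$failures, 0)
  sav <- vapply(batch$maps,
                function(m) coverage_fraction(m)$fractions[["SAV"]], 1)
  expect_true(all(diff(sav) < 0))
})
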