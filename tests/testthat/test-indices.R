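# Frozen hand-computed values
# TM FAI example: red 0.05, swir1 0.02, nir 0.10 at centres 660/830/1650 nm:
#   baseline = 0.05 + (0.02 - 0.05) * 170/990 = 0.0448484848...
#   FAI      = 0.10 - baseline            = 0.0551515151...
FAI_TM_EXAMPLE <- 0.10 - (0.05 + (0.02 - 0.05) * 170 / 990)

test_that("AVI is the negated wetness dot product (scalar oracle)", {
  scene <- random_scene(8, 8, seed = 42)
  profile <- get_profile("TM")
  avi <- compute_avi(scene, profile)
  set.seed(99)
  for (rep in 1:5) {
    i <- sample(8, 1); j <- sample(8, 1)
    expect_equal(avi$values[i, j],
                 -sum(profile$wetness * scene$bands[i, j, ]),
                 tolerance = 1e-12)
  }
  # homogeneity of the linear form
  scene2 <- scene
  scene2$bands <- scene$bands * 2
  expect_equal(compute_avi(scene2, profile)$values, 2 * avi$values,
               tolerance = 1e-12)
})

test_that("FAI baseline identities hold", {
  profile <- get_profile("TM")
  mk <- function(red, nir, swir1)
    uniform_scene(c(blue = 0.01, green = 0.02, red = red, nir = nir,
                    swir1 = swir1, swir2 = 0.01), 2, 2)
  # NIR exactly on the red-swir1 line -> 0
  frac <- (830 - 660) / (1650 - 660)
  on_line <- 0.05 + (0.02 - 0.05) * frac
  expect_equal(compute_fai(mk(0.05, on_line, 0.02), profile)$values[1, 1], 0,
               tolerance = 1e-12)
  # zero baseline collapses FAI to R_nir
  expect_equal(compute_fai(mk(0, 0.2, 0), profile)$values[1, 1], 0.2,
               tolerance = 1e-12)
  # hand-computed interpolation example
  expect_equal(compute_fai(mk(0.05, 0.10, 0.02), profile)$values[1, 1],
               FAI_TM_EXAMPLE, tolerance = 1e-12)
})

test_that("FAI is invariant to adding a constant to red, nir and swir1", {
  scene <- random_scene(16, 16, seed = 5)
  profile <- get_profile("TM")
  f1 <- compute_fai(scene, profile)
  shifted <- scene
  for (b in c("red", "nir", "swir1"))
    shifted$bands[, , b] <- shifted$bands[, , b] + 0.17
  expect_equal(compute_fai(shifted, profile)$values, f1$values,
               tolerance = 1e-10)
})

test_that("NDVI and NDWI match direct formula values and bounds", {
  mk <- function(green, red, nir)
    uniform_scene(c(blue = 0.01, green = green, red = red, nir = nir,
                    swir1 = 0.01, swir2 = 0.01), 2, 2)
  expect_equal(compute_ndvi(mk(0.1, 0.3, 0.3))$values[1, 1], 0)
  expect_equal(compute_ndvi(mk(0.1, 0.1, 0.5))$values[1, 1], 2 / 3,
               tolerance = 1e-12)
  expect_equal(compute_ndvi(mk(0.1, 0.2, 0))$values[1, 1], -1)
  expect_equal(compute_ndwi(mk(0.2, 0.1, 0.05))$values[1, 1], 0.6,
               tolerance = 1e-12)
  expect_equal(compute_ndwi(mk(0, 0.1, 0.3))$values[1, 1], -1)
  scene <- random_scene(16, 16, seed = 11)
  for (v in list(compute_ndvi(scene)$values, compute_ndwi(scene)$values)) {
    expect_true(all(v >= -1 & v <= 1, na.rm = TRUE))
  }
})

test_that("NDVI and NDWI negate when their two bands are swapped", {
  scene <- random_scene(12, 12, seed = 3)
  swapped <- scene
  swapped$bands[, , "nir"] <- scene$bands[, , "red"]
  swapped$bands[, , "red"] <- scene$bands[, , "nir"]
  expect_equal(compute_ndvi(swapped)$values, -compute_ndvi(scene)$values,
               tolerance = 1e-12)
  swapped2 <- scene
  swapped2$bands[, , "green"] <- scene$bands[, , "nir"]
  swapped2$bands[, , "nir"] <- scene$bands[, , "green"]
  expect_equal(compute_ndwi(swapped2)$values, -compute_ndwi(scene)$values,
               tolerance = 1e-12)
})

test_that("zero-denominator pixels become nodata, not zero", {
  s <- uniform_scene(c(blue = 0.1, green = 0, red = 0, nir = 0,
                       swir1 = 0.1, swir2 = 0.1), 2, 2)
  expect_true(all(is.na(compute_ndvi(s)$values)))
  expect_true(all(is.na(compute_ndwi(s)$values)))
})

test_that("every index equals its scalar loop oracle and keeps the nodata footprint", {
  scene <- random_scene(32, 32, seed = 7, na_frac = 0.1)
  profile <- get_profile("TM")
  pairs <- list(AVI = compute_avi(scene, profile),
                FAI = compute_fai(scene, profile),
                NDVI = compute_ndvi(scene),
                NDWI = compute_ndwi(scene))
  footprint <- is.na(scene$bands[, , 1])
  for (kind in names(pairs)) {
    expect_equal(pairs[[kind]]$values, oracle_index(scene, kind, profile),
                 tolerance = 1e-10)
    expect_true(all(is.na(pairs[[kind]]$values[footprint])))
  }
})

test_that("profile/scene mismatch and band-count violations error descriptively", {
  scene <- random_scene(4, 4, sensor = "OLI")
  expect_error(compute_avi(scene, get_profile("TM")), "does not match")
  expect_error(reflectance_scene(list(matrix(0, 2, 2), matrix(0, 2, 2))),
               "6 bands")
})
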