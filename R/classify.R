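# The three-step VBI decision tree.
#
#   step 1: AVI  > t_avi   splits aquatic vegetation (AV) from non-AV;
#   step 2: NDVI > t_ndvi  splits AV into FEAV (high NIR) vs SAV;
#   step 3: FAI  > t_fai   splits non-AV into algal bloom vs open water.
#
# Every node uses a strict ">"; a value exactly equal to its threshold falls
# to the lower branch, so the tree is deterministic and testable.
# t_avi is normally calibrated per scene: open water is extracted with
# NDWI > t_ndwi and t_avi set to mean(AVI over water) + k_sigma * sd.

#' Decision-tree thresholds
#'
#' Container for the four index cuts used by [classify_scene()].  `t_avi =
#' NULL` (the default) requests per-scene calibration from the open-water AVI
#' population; a finite value fixes the cut globally.
#'
#' @param t_avi AV vs non-AV cut on AVI, or NULL for per-scene calibration.
#' @param t_ndvi FEAV vs SAV cut on NDVI (default 0.2: emergent canopies sit
#'   well above it, water-attenuated submerged canopies below).
#' @param t_fai Algal bloom vs open water cut on FAI (default 0: any positive
#'   baseline exceedance is bloom).
#' @param t_ndwi Water-extraction cut on NDWI used only for calibration
#'   (default 0, the standard water cut).
#' @param k_sigma Offset, in water AVI standard deviations, added to the
#'   water-mean AVI during calibration (default 2; keeps the false-AV rate of
#'   open water near 2.3% under a Gaussian water model).
#' @return A `vbi_thresholds` object.
#' @export
vbi_thresholds <- function(t_avi = NULL, t_ndvi = 0.2, t_fai = 0,
                           t_ndwi = 0, k_sigma = 2) {
  if (!is.null(t_avi) && !is.finite(t_avi)) stop("t_avi must be finite or NULL")
  stopifnot(is.finite(t_ndvi), t_ndvi >= -1, t_ndvi <= 1,
            is.finite(t_fai), is.finite(t_ndwi), t_ndwi >= -1, t_ndwi <= 1,
            is.finite(k_sigma))
  structure(list(t_avi = t_avi, t_ndvi = t_ndvi, t_fai = t_fai,
                 t_ndwi = t_ndwi, k_sigma = k_sigma),
            class = "vbi_thresholds")
}

#' Extract an open-water mask from NDWI
#'
#' @param ndwi An [index_raster()] of kind `"NDWI"`.
#' @param t_ndwi Water cut; pixels with NDWI strictly above it are water.
#' @return Logical matrix, TRUE on valid water pixels, FALSE elsewhere
#'   (including nodata).
#' @export
extract_water_mask <- function(ndwi, t_ndwi = 0) {
  if (!inherits(ndwi, "index_raster") || ndwi$kind != "NDWI")
    stop("extract_water_mask expects an NDWI index_raster")
  m <- ndwi$values > t_ndwi
  m[is.na(m)] <- FALSE
  m
}

#' Calibrate the AVI classification threshold against open water
#'
#' Computes `mean(AVI over the water mask) + k_sigma * sd(...)`.  With
#' `k_sigma = 0` this is exactly the water-mean AVI statistic; the positive
#' default offsets the cut above the water population so that symmetric
#' sensor noise does not push half of the open water into the AV branch.
#'
#' @param avi An [index_raster()] of kind `"AVI"`.
#' @param water_mask Logical matrix from [extract_water_mask()].
#' @param k_sigma Standard-deviation multiple added to the water mean.
#' @param min_pixels Minimum number of valid water pixels required.
#' @return Calibrated threshold (numeric scalar).
#' @export
calibrate_avi_threshold <- function(avi, water_mask, k_sigma = 2,
                                    min_pixels = 30) {
  if (!inherits(avi, "index_raster") || avi$kind != "AVI")
    stop("calibrate_avi_threshold expects an AVI index_raster")
  stopifnot(identical(dim(water_mask), dim(avi$values)))
  vals <- avi$values[water_mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) < min_pixels)
    stop("AVI calibration impossible: only ", length(vals),
         " valid water pixels (need >= ", min_pixels, ")")
  s <- if (length(vals) > 1) stats::sd(vals) else 0
  mean(vals) + k_sigma * s
}

# vectorized tree over index matrices; returns an integer code matrix
classify_codes <- function(avi, ndvi, fai, t_avi, t_ndvi, t_fai) {
  codes <- matrix(VBI_CLASSES[["NODATA"]], nrow(avi), ncol(avi))
  av <- avi > t_avi
  codes[which(av & ndvi > t_ndvi)] <- VBI_CLASSES[["FEAV"]]
  codes[which(av & !(ndvi > t_ndvi))] <- VBI_CLASSES[["SAV"]]
  codes[which(!av & fai > t_fai)] <- VBI_CLASSES[["AB"]]
  codes[which(!av & !(fai > t_fai))] <- VBI_CLASSES[["OW"]]
  # NDVI can be NA (zero denominator) where AVI is not; keep those nodata
  codes[is.na(avi) | (av & is.na(ndvi))] <- VBI_CLASSES[["NODATA"]]
  codes
}

#' Classify a scene into SAV / FEAV / AB / OW
#'
#' Runs the three-step decision tree on the scene's AVI, NDVI and FAI
#' rasters.  When `thresholds$t_avi` is NULL, the AVI cut is calibrated from
#' the scene's own open water (NDWI > t_ndwi) via
#' [calibrate_avi_threshold()]; the calibrated value is recorded in the
#' result's provenance.
#'
#' @param scene A [reflectance_scene()].
#' @param profile Matching [get_profile()]; defaults to the scene's sensor.
#' @param thresholds A [vbi_thresholds()] object.
#' @param lake_mask Optional logical matrix; pixels outside it (land, clouds)
#'   are excluded before classification and come back as nodata.
#' @param date Optional acquisition date recorded in provenance.
#' @return A [class_map()] whose provenance records the thresholds used.
#' @export
classify_scene <- function(scene, profile = get_profile(scene$sensor),
                           thresholds = vbi_thresholds(), lake_mask = NULL,
                           date = NULL) {
  check_profile_match(scene, profile)
  if (!inherits(thresholds, "vbi_thresholds"))
    stop("thresholds must come from vbi_thresholds()")
  if (!is.null(lake_mask)) scene <- mask_scene(scene, lake_mask)
  avi <- compute_avi(scene, profile)
  ndvi <- compute_ndvi(scene)
  fai <- compute_fai(scene, profile)
  t_avi <- thresholds$t_avi
  calibrated <- FALSE
  if (is.null(t_avi)) {
    wm <- extract_water_mask(compute_ndwi(scene), thresholds$t_ndwi)
    t_avi <- calibrate_avi_threshold(avi, wm, thresholds$k_sigma)
    calibrated <- TRUE
  }
  codes <- classify_codes(avi$values, ndvi$values, fai$values,
                          t_avi, thresholds$t_ndvi, thresholds$t_fai)
  class_map(codes, scene$geo, provenance = list(
    sensor = scene$sensor, date = date,
    thresholds = list(t_avi = t_avi, t_ndvi = thresholds$t_ndvi,
                      t_fai = thresholds$t_fai, t_ndwi = thresholds$t_ndwi,
                      k_sigma = thresholds$k_sigma,
                      t_avi_calibrated = calibrated)))
}

#' Classify a dated batch of scenes
#'
#' Applies [classify_scene()] to each (date, scene) pair.  A failure in one
#' scene (e.g. AVI calibration impossible) is captured and reported without
#' aborting the rest of the batch.
#'
#' @param scenes Named or unnamed list of [reflectance_scene()]s.
#' @param dates Vector of dates (anything `as.Date` accepts), one per scene.
#' @param profile Optional shared [get_profile()]; by default each scene's
#'   own sensor is used.
#' @param thresholds A [vbi_thresholds()] object; with `t_avi = NULL` the AVI
#'   cut is re-calibrated per scene.
#' @param lake_mask Optional shared logical lake mask.
#' @return List with `maps` (named list of [class_map()], names are dates)
#'   and `failures` (named character vector of error messages, empty when
#'   all scenes succeed).
#' @export
classify_batch <- function(scenes, dates, profile = NULL,
                           thresholds = vbi_thresholds(), lake_mask = NULL) {
  stopifnot(length(scenes) == length(dates))
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparseable date in batch")
  maps <- list()
  failures <- character(0)
  for (i in seq_along(scenes)) {
    key <- as.character(dates[i])
    res <- tryCatch(
      classify_scene(scenes[[i]],
                     profile = if (is.null(profile))
                       get_profile(scenes[[i]]$sensor) else profile,
                     thresholds = thresholds, lake_mask = lake_mask,
                     date = dates[i]),
      error = function(e) e)
    if (inherits(res, "error")) failures[key] <- conditionMessage(res)
    else maps[[key]] <- res
  }
  list(maps = maps, failures = failures)
}
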