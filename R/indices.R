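# Per-pixel spectral indices.  All four operations are pure matrix
# arithmetic; nodata (NA) propagates from the source scene and is never
# filled in.

check_profile_match <- function(scene, profile) {
  if (!inherits(profile, "sensor_profile"))
    stop("profile must be a sensor_profile (see get_profile())")
  if (!identical(scene$sensor, profile$sensor_id))
    stop("profile sensor '", profile$sensor_id,
         "' does not match scene sensor '", scene$sensor, "'")
}

#' Aquatic vegetation index (negated tasseled-cap wetness)
#'
#' AVI = -sum_i k_i R_i over the six reflective bands, where k are the
#' sensor's tasseled-cap wetness coefficients.  Open water has high wetness
#' and hence low AVI; macrophyte canopies (and submerged canopies near the
#' surface) depress wetness, so AVI rises over aquatic vegetation.
#'
#' @param scene A [reflectance_scene()].
#' @param profile Matching [get_profile()] output; defaults to the scene's
#'   sensor.
#' @return An [index_raster()] of kind `"AVI"`.
#' @export
compute_avi <- function(scene, profile = get_profile(scene$sensor)) {
  check_profile_match(scene, profile)
  k <- profile$wetness[VBI_BANDS]
  v <- matrix(0, scene$geo$nrow, scene$geo$ncol)
  for (i in seq_along(VBI_BANDS))
    v <- v + k[[i]] * matrix(scene$bands[, , i], scene$geo$nrow,
                             scene$geo$ncol)
  index_raster(-v, "AVI", scene$geo)
}

#' Floating algae index
#'
#' FAI is the height of NIR reflectance above a linear baseline interpolated
#' between the red and SWIR1 bands at the NIR band centre:
#' `FAI = R_nir - [R_red + (R_swir1 - R_red) * (l_nir - l_red) / (l_swir1 - l_red)]`
#' with band-centre wavelengths `l` from the sensor profile.  Surface algal
#' accumulations raise NIR above the baseline (FAI > 0); open water sits
#' below it.
#'
#' @inheritParams compute_avi
#' @return An [index_raster()] of kind `"FAI"`.
#' @export
compute_fai <- function(scene, profile = get_profile(scene$sensor)) {
  check_profile_match(scene, profile)
  wl <- profile$wavelengths_nm
  frac <- (wl[["nir"]] - wl[["red"]]) / (wl[["swir1"]] - wl[["red"]])
  red <- scene_band(scene, "red")
  nir <- scene_band(scene, "nir")
  swir1 <- scene_band(scene, "swir1")
  baseline <- red + (swir1 - red) * frac
  index_raster(nir - baseline, "FAI", scene$geo)
}

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - Red) / (NIR + Red), in \[-1, 1\].  Emergent/floating
#' canopies have strongly positive NDVI; submerged canopies are
#' water-attenuated in the NIR and stay low.  Pixels with a zero denominator
#' become nodata.
#'
#' @param scene A [reflectance_scene()].
#' @return An [index_raster()] of kind `"NDVI"`.
#' @export
compute_ndvi <- function(scene) {
  nir <- scene_band(scene, "nir")
  red <- scene_band(scene, "red")
  den <- nir + red
  den[den == 0] <- NA_real_
  index_raster((nir - red) / den, "NDVI", scene$geo)
}

#' Normalized difference water index
#'
#' NDWI = (Green - NIR) / (Green + NIR), in \[-1, 1\]; positive over open
#' water.  Used here to extract the open-water population from which the AVI
#' classification threshold is calibrated.  Zero-denominator pixels become
#' nodata.
#'
#' @param scene A [reflectance_scene()].
#' @return An [index_raster()] of kind `"NDWI"`.
#' @export
compute_ndwi <- function(scene) {
  green <- scene_band(scene, "green")
  nir <- scene_band(scene, "nir")
  den <- green + nir
  den[den == 0] <- NA_real_
  index_raster((green - nir) / den, "NDWI", scene$geo)
}
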