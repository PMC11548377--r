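# Sensor constants: tasseled-cap wetness coefficients and band-centre
# wavelengths.  The wetness sets are the widely used reflectance-domain
# derivations: Crist (1985) for TM, Huang et al. (2002) for ETM+, and
# Baig et al. (2014) for OLI.  Band centres are nominal Landsat values; FAI
# needs only their ratios.

.SENSOR_PROFILES <- list(
  "TM" = list(
    wetness = c(blue = 0.0315, green = 0.2021, red = 0.3102,
                nir = 0.1594, swir1 = -0.6806, swir2 = -0.6109),
    wavelengths_nm = c(red = 660, nir = 830, swir1 = 1650)
  ),
  "ETM+" = list(
    wetness = c(blue = 0.2626, green = 0.2141, red = 0.0926,
                nir = 0.0656, swir1 = -0.7629, swir2 = -0.5388),
    wavelengths_nm = c(red = 660, nir = 835, swir1 = 1650)
  ),
  "OLI" = list(
    wetness = c(blue = 0.1511, green = 0.1973, red = 0.3283,
                nir = 0.3407, swir1 = -0.7117, swir2 = -0.4559),
    wavelengths_nm = c(red = 655, nir = 865, swir1 = 1609)
  )
)

#' Sensor profile: wetness coefficients and band-centre wavelengths
#'
#' Returns the per-sensor constants needed by the AVI (tasseled-cap wetness
#' coefficients for the six reflective bands) and the FAI (band-centre
#' wavelengths of red, NIR and SWIR1).  Shipped sets are standard published
#' reflectance-domain tasseled-cap wetness derivations; both arguments can be
#' overridden to substitute another coefficient set.
#'
#' @param sensor_id One of `"TM"`, `"ETM+"`, `"OLI"`.
#' @param wetness Optional override: named numeric vector of six wetness
#'   coefficients ordered/named as [VBI_BANDS].
#' @param wavelengths_nm Optional override: named numeric vector with at
#'   least `red`, `nir`, `swir1` centre wavelengths in nm.
#' @return A `sensor_profile` object: list with `sensor_id`, `wetness`
#'   (length 6) and `wavelengths_nm`.
#' @examples
#' get_profile("TM")$wetness
#' @export
get_profile <- function(sensor_id, wetness = NULL, wavelengths_nm = NULL) {
  if (length(sensor_id) != 1 || !sensor_id %in% names(.SENSOR_PROFILES))
    stop("unknown sensor '", paste(sensor_id, collapse = ","),
         "'; supported sensors: ",
         paste(names(.SENSOR_PROFILES), collapse = ", "))
  p <- .SENSOR_PROFILES[[sensor_id]]
  if (!is.null(wetness)) {
    if (length(wetness) != 6)
      stop("wetness override must have 6 coefficients, got ", length(wetness))
    if (!is.null(names(wetness))) wetness <- wetness[VBI_BANDS]
    if (anyNA(wetness)) stop("wetness override has missing coefficients")
    names(wetness) <- VBI_BANDS
    p$wetness <- wetness
  }
  if (!is.null(wavelengths_nm)) {
    need <- c("red", "nir", "swir1")
    if (!all(need %in% names(wavelengths_nm)))
      stop("wavelength override must name at least red, nir, swir1")
    p$wavelengths_nm <- wavelengths_nm[need]
  }
  wl <- p$wavelengths_nm[c("red", "nir", "swir1")]
  if (any(diff(wl) <= 0))
    stop("band-centre wavelengths must satisfy red < nir < swir1")
  structure(list(sensor_id = sensor_id, wetness = p$wetness,
                 wavelengths_nm = p$wavelengths_nm),
            class = "sensor_profile")
}

#' @export
print.sensor_profile <- function(x, ...) {
  cat("sensor_profile:", x$sensor_id, "\n  wetness:",
      paste(sprintf("%s=%.4f", names(x$wetness), x$wetness), collapse = " "),
      "\n  band centres (nm):",
      paste(sprintf("%s=%g", names(x$wavelengths_nm), x$wavelengths_nm),
            collapse = " "), "\n")
  invisible(x)
}
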