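# Synthetic scene and water-quality generators.  Every generator is fully
# deterministic under its seed, and the scene generator verifies its own
# separability contract: the class-mean spectra must classify correctly
# under the requested thresholds at zero noise, otherwise it refuses with a
# diagnostic naming the decision-tree node that failed.

#' Default class-mean reflectance spectra
#'
#' Six-band mean surface reflectances (ordered as [VBI_BANDS]) for the four
#' cover classes, chosen to emulate their Landsat-scale signatures:
#' * `OW`: clear-water spectrum — green peak, very low NIR/SWIR, NDWI > 0,
#'   FAI below the red-SWIR baseline;
#' * `AB`: surface bloom — NIR peak well above the red-SWIR baseline
#'   (FAI > 0) without a macrophyte wetness deficit;
#' * `SAV`: submerged canopy at/near the surface — water-like visible bands
#'   with moderately raised NIR/SWIR, NDVI ~ 0, wetness depressed below
#'   water so AVI exceeds the water-calibrated cut;
#' * `FEAV`: emergent canopy — strong NIR plateau, NDVI ~ 0.8.
#'
#' @return Named list of four numeric vectors of length 6.
#' @export
default_class_spectra <- function() {
  list(
    OW   = c(blue = 0.060, green = 0.080, red = 0.055,
             nir = 0.015, swir1 = 0.008, swir2 = 0.004),
    AB   = c(blue = 0.060, green = 0.090, red = 0.060,
             nir = 0.150, swir1 = 0.030, swir2 = 0.015),
    SAV  = c(blue = 0.040, green = 0.060, red = 0.090,
             nir = 0.090, swir1 = 0.100, swir2 = 0.030),
    FEAV = c(blue = 0.040, green = 0.070, red = 0.050,
             nir = 0.450, swir1 = 0.200, swir2 = 0.100)
  )
}

# classify the noiseless class-mean spectra and return the first violated
# decision-tree node, or NULL when all classes separate
check_separability <- function(spectra, sensor, thresholds) {
  profile <- get_profile(sensor)
  classes <- names(spectra)
  bands <- array(NA_real_, c(1, length(classes), 6))
  for (j in seq_along(classes)) bands[1, j, ] <- spectra[[j]][VBI_BANDS]
  mini <- reflectance_scene(bands, grid_geo(1, length(classes), res = 1),
                            sensor)
  avi <- compute_avi(mini, profile)$values[1, ]
  ndvi <- compute_ndvi(mini)$values[1, ]
  fai <- compute_fai(mini, profile)$values[1, ]
  ndwi <- compute_ndwi(mini)$values[1, ]
  t_avi <- thresholds$t_avi
  if (is.null(t_avi)) {
    if (!"OW" %in% classes || ndwi[classes == "OW"] <= thresholds$t_ndwi)
      return(paste("water extraction: no class passes NDWI >",
                   thresholds$t_ndwi, "so the AVI cut cannot be calibrated"))
    # noiseless water is constant, so the calibrated cut is its mean AVI
    t_avi <- avi[classes == "OW"]
  }
  for (j in seq_along(classes)) {
    cl <- classes[j]
    want_av <- cl %in% c("SAV", "FEAV")
    if (want_av != (avi[j] > t_avi))
      return(sprintf(
        "node 1 (AVI > %.4g): class %s has AVI %.4g on the wrong side",
        t_avi, cl, avi[j]))
    if (want_av) {
      want_feav <- cl == "FEAV"
      if (want_feav != (ndvi[j] > thresholds$t_ndvi))
        return(sprintf(
          "node 2 (NDVI > %.4g): class %s has NDVI %.4g on the wrong side",
          thresholds$t_ndvi, cl, ndvi[j]))
    } else {
      want_ab <- cl == "AB"
      if (want_ab != (fai[j] > thresholds$t_fai))
        return(sprintf(
          "node 3 (FAI > %.4g): class %s has FAI %.4g on the wrong side",
          thresholds$t_fai, cl, fai[j]))
    }
  }
  NULL
}

default_quadrant_layout <- function(width, height) {
  codes <- matrix(VBI_CLASSES[["OW"]], height, width)
  top <- seq_len(floor(height / 2))
  left <- seq_len(floor(width / 2))
  codes[top, left] <- VBI_CLASSES[["SAV"]]
  codes[top, setdiff(seq_len(width), left)] <- VBI_CLASSES[["FEAV"]]
  codes[setdiff(seq_len(height), top), left] <- VBI_CLASSES[["AB"]]
  codes
}

#' Generate a synthetic six-band scene with known ground truth
#'
#' Each pixel's reflectance is its class-mean spectrum plus independent
#' per-band Gaussian noise.  Before generating, the class-mean spectra are
#' run through the decision tree at zero noise; if any class lands on the
#' wrong side of a node the generator refuses, naming the violated node,
#' rather than emit an untestable fixture.
#'
#' @param width,height Scene size in pixels.
#' @param layout Integer matrix of class codes ([VBI_CLASSES]) defining the
#'   region layout, or NULL for the default layout (SAV, FEAV, AB quadrants
#'   over an OW background).
#' @param spectra Named list of class-mean spectra; see
#'   [default_class_spectra()].
#' @param noise_sd Per-band Gaussian noise standard deviation (reflectance
#'   units).
#' @param seed Integer seed; fixes the output bit-for-bit.
#' @param sensor Sensor identifier for the generated scene.
#' @param thresholds The [vbi_thresholds()] against which separability is
#'   verified.
#' @return List with `scene` (a [reflectance_scene()]) and `truth` (a
#'   [class_map()] of the intended classes).
#' @export
generate_scene <- function(width = 64, height = 64, layout = NULL,
                           spectra = default_class_spectra(),
                           noise_sd = 0.005, seed = 1, sensor = "TM",
                           thresholds = vbi_thresholds()) {
  stopifnot(width >= 1, height >= 1, noise_sd >= 0)
  if (any(unlist(spectra) < 0)) stop("class spectra must be non-negative")
  if (is.null(layout)) layout <- default_quadrant_layout(width, height)
  stopifnot(is.matrix(layout), nrow(layout) == height, ncol(layout) == width)
  used <- setdiff(unique(as.vector(layout)), VBI_CLASSES[["NODATA"]])
  used_names <- names(VBI_CLASSES)[match(used, VBI_CLASSES)]
  missing_spec <- setdiff(used_names, names(spectra))
  if (length(missing_spec))
    stop("no spectrum supplied for layout class(es): ",
         paste(missing_spec, collapse = ", "))
  viol <- check_separability(spectra[used_names], sensor, thresholds)
  if (!is.null(viol))
    stop("class spectra violate the separability contract at ", viol)
  geo <- grid_geo(height, width, res = 30, crs = "local")
  bands <- array(NA_real_, c(height, width, 6))
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (cl in used_names) {
    idx <- layout == VBI_CLASSES[[cl]]
    npx <- sum(idx)
    mu <- spectra[[cl]][VBI_BANDS]
    for (k in 1:6)
      bands[, , k][idx] <- mu[[k]] +
        if (noise_sd > 0) stats::rnorm(npx, 0, noise_sd) else 0
  }
  list(scene = reflectance_scene(bands, geo, sensor),
       truth = class_map(layout, geo,
                         provenance = list(generator = "generate_scene",
                                           seed = seed,
                                           noise_sd = noise_sd)))
}

#' Generate a multi-year lake series with declining SAV coverage
#'
#' Emulates the interannual pattern of a macrophyte-losing shallow lake: a
#' submerged-vegetation region whose area interpolates linearly from
#' `sav_start` to `sav_end` of the lake across years, the vacated area
#' turning to open water, over a fixed emergent fringe.  One spring scene
#' per year.
#'
#' @param n_years Number of yearly scenes (>= 2).
#' @param sav_start,sav_end Initial and final SAV area fractions in \[0, 1\].
#' @param seed Integer seed.
#' @param width,height Scene size in pixels.
#' @param noise_sd Per-band noise sd passed to [generate_scene()].
#' @param start_year First calendar year (scenes are dated April 20).
#' @param feav_fraction Constant emergent-fringe fraction along the bottom
#'   edge (default 0.05).
#' @param sensor Sensor identifier.
#' @return List of per-year entries, each with `date`, `scene`, `truth`.
#' @export
generate_lake_timeseries <- function(n_years, sav_start = 0.6,
                                     sav_end = 0.05, seed = 1,
                                     width = 48, height = 48,
                                     noise_sd = 0.005, start_year = 2000,
                                     feav_fraction = 0.05, sensor = "TM") {
  stopifnot(n_years >= 2, sav_start >= 0, sav_start <= 1,
            sav_end >= 0, sav_end <= 1, feav_fraction >= 0,
            sav_start + feav_fraction <= 1, sav_end + feav_fraction <= 1)
  fr <- seq(sav_start, sav_end, length.out = n_years)
  n_feav_rows <- round(feav_fraction * height)
  out <- vector("list", n_years)
  for (i in seq_len(n_years)) {
    layout <- matrix(VBI_CLASSES[["OW"]], height, width)
    n_sav_rows <- round(fr[i] * height)
    if (n_sav_rows > 0)
      layout[seq_len(n_sav_rows), ] <- VBI_CLASSES[["SAV"]]
    if (n_feav_rows > 0)
      layout[seq(height - n_feav_rows + 1, height), ] <- VBI_CLASSES[["FEAV"]]
    g <- generate_scene(width, height, layout, noise_sd = noise_sd,
                        seed = seed + i, sensor = sensor)
    out[[i]] <- list(date = as.Date(sprintf("%d-04-20", start_year + i - 1)),
                     scene = g$scene, truth = g$truth)
  }
  out
}

#' Generate a synthetic water-quality and coverage series
#'
#' Emulates a quarterly field campaign: per-date TP, TN, water depth Z_M and
#' Secchi depth Z_SD drawn around season-specific means, and an SAV coverage
#' fraction tied to one driver by the linear relation
#' `coverage = a + b * driver + N(0, sigma^2)`.  Concentrations and depths
#' are truncated at zero.  The true (a, b, sigma) are returned alongside so
#' recovery tests can compare estimates against them.
#'
#' @param n_dates Number of sampling dates (quarterly from `start_year`).
#' @param a,b Intercept and slope of the coverage-driver relation (defaults
#'   0.65 and -5 per mg/L, an SAV-vs-TP-like relation).
#' @param driver Which variable drives coverage: `"TP"`, `"TN"` or
#'   `"zm_zsd"`.
#' @param sigma Coverage noise standard deviation.
#' @param seed Integer seed.
#' @param start_year First calendar year.
#' @param season_means Named list of per-season mean vectors for TP, TN,
#'   Z_M, Z_SD (defaults emulate a eutrophic shallow lake with clearer,
#'   lower-TP springs).
#' @param rel_sd Relative sd of each water-quality variable around its
#'   seasonal mean (default 0.15).
#' @return List with `env` (data frame: date, season, TP, TN, Z_M, Z_SD),
#'   `coverage` (data frame: date, season, sav_coverage) and `truth`
#'   (list a, b, sigma, driver).
#' @export
generate_env_series <- function(n_dates = 24, a = 0.65, b = -5,
                                driver = c("TP", "TN", "zm_zsd"),
                                sigma = 0.08, seed = 1, start_year = 2018,
                                season_means = NULL, rel_sd = 0.15) {
  driver <- match.arg(driver)
  stopifnot(n_dates >= 3, sigma >= 0, rel_sd >= 0)
  if (is.null(season_means))
    season_means <- list(
      TP   = c(spring = 0.032, summer = 0.085, autumn = 0.070, winter = 0.055),
      TN   = c(spring = 0.90, summer = 1.60, autumn = 1.30, winter = 1.10),
      Z_M  = c(spring = 1.80, summer = 2.40, autumn = 2.20, winter = 1.90),
      Z_SD = c(spring = 0.60, summer = 0.35, autumn = 0.45, winter = 0.55))
  set.seed(as.integer(seed %% .Machine$integer.max))
  # quarterly mid-season sampling dates
  months <- c(4, 7, 10, 1)
  idx <- seq_len(n_dates) - 1
  years <- start_year + (idx %/% 4) + ifelse(months[idx %% 4 + 1] == 1, 1, 0)
  dates <- as.Date(sprintf("%d-%02d-15", years, months[idx %% 4 + 1]))
  seasons <- season_of(dates)
  draw <- function(var) {
    mu <- season_means[[var]][seasons]
    pmax(0, stats::rnorm(n_dates, mu, rel_sd * mu))
  }
  env <- data.frame(date = dates, season = seasons,
                    TP = draw("TP"), TN = draw("TN"),
                    Z_M = draw("Z_M"), Z_SD = draw("Z_SD"))
  x <- switch(driver, TP = env$TP, TN = env$TN,
              zm_zsd = zm_zsd_ratio(env$Z_M, env$Z_SD))
  coverage <- a + b * x + stats::rnorm(n_dates, 0, sigma)
  cov <- data.frame(date = dates, season = seasons, sav_coverage = coverage)
  list(env = env, coverage = cov,
       truth = list(a = a, b = b, sigma = sigma, driver = driver))
}
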