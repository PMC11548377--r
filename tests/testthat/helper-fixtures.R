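# Shared fixture builders and independent scalar oracles.

# a scene with independent uniform reflectances (optionally with nodata)
random_scene <- function(nrow = 32, ncol = 32, seed = 1, sensor = "TM",
                         na_frac = 0) {
  set.seed(seed)
  bands <- array(runif(nrow * ncol * 6, 0, 0.6), c(nrow, ncol, 6))
  if (na_frac > 0) {
    drop <- matrix(runif(nrow * ncol) < na_frac, nrow, ncol)
    for (k in 1:6) bands[, , k][drop] <- NA_real_
  }
  reflectance_scene(bands, grid_geo(nrow, ncol, res = 30), sensor)
}

# scalar per-pixel re-implementations of the four indices, used as loop
# oracles; deliberately written element by element, not vectorized
oracle_index <- function(scene, kind, profile = get_profile(scene$sensor)) {
  nr <- scene$geo$nrow; nc <- scene$geo$ncol
  out <- matrix(NA_real_, nr, nc)
  wl <- profile$wavelengths_nm
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r <- scene$bands[i, j, ]
    if (anyNA(r)) next
    out[i, j] <- switch(kind,
      AVI = {
        s <- 0
        for (k in 1:6) s <- s + profile$wetness[[k]] * r[[k]]
        -s
      },
      FAI = {
        base <- r[["red"]] + (r[["swir1"]] - r[["red"]]) *
          (wl[["nir"]] - wl[["red"]]) / (wl[["swir1"]] - wl[["red"]])
        r[["nir"]] - base
      },
      NDVI = if (r[["nir"]] + r[["red"]] == 0) NA_real_ else
        (r[["nir"]] - r[["red"]]) / (r[["nir"]] + r[["red"]]),
      NDWI = if (r[["green"]] + r[["nir"]] == 0) NA_real_ else
        (r[["green"]] - r[["nir"]]) / (r[["green"]] + r[["nir"]]))
  }
  out
}

# per-pixel nested-conditional reference classifier (the tree spelt out)
oracle_classify <- function(scene, thresholds,
                            profile = get_profile(scene$sensor)) {
  avi <- oracle_index(scene, "AVI", profile)
  ndvi <- oracle_index(scene, "NDVI", profile)
  fai <- oracle_index(scene, "FAI", profile)
  nr <- scene$geo$nrow; nc <- scene$geo$ncol
  out <- matrix(VBI_CLASSES[["NODATA"]], nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(avi[i, j])) next
    if (avi[i, j] > thresholds$t_avi) {
      if (is.na(ndvi[i, j])) next
      if (ndvi[i, j] > thresholds$t_ndvi) out[i, j] <- VBI_CLASSES[["FEAV"]]
      else out[i, j] <- VBI_CLASSES[["SAV"]]
    } else {
      if (fai[i, j] > thresholds$t_fai) out[i, j] <- VBI_CLASSES[["AB"]]
      else out[i, j] <- VBI_CLASSES[["OW"]]
    }
  }
  out
}

# build a uniform single-spectrum scene
uniform_scene <- function(spectrum, nrow = 4, ncol = 4, sensor = "TM") {
  bands <- array(rep(spectrum[VBI_BANDS], each = nrow * ncol),
                 c(nrow, ncol, 6))
  reflectance_scene(bands, grid_geo(nrow, ncol, res = 30), sensor)
}
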