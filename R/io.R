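# File interchange.  Rasters travel as TIFF with a JSON sidecar
# ("<file>.json") carrying georeferencing, band order, sensor and the affine
# packing applied to fit the TIFF sample range:
#   stored = (value - pack_min) / (pack_max - pack_min)
# A trailing plane flags validity (1 = data, 0 = nodata), since TIFF floats
# cannot carry NA.  Everything the package writes can be re-read by its own
# readers.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a reflectance scene to TIFF + JSON sidecar
#'
#' Bands are stored as 32-bit samples affinely packed into \[0, 1\] (the
#' packing range is recorded in the sidecar and undone on read), with the
#' band order of [VBI_BANDS] and a trailing validity plane.
#'
#' @param scene A [reflectance_scene()].
#' @param path Output TIFF path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  b <- scene$bands
  vmask <- valid_mask(scene)
  rng <- range(b, na.rm = TRUE)
  pack_min <- min(rng[1], 0)
  pack_max <- max(rng[2], 1)
  planes <- vector("list", 7)
  for (k in 1:6) {
    p <- (b[, , k] - pack_min) / (pack_max - pack_min)
    p[!vmask] <- 0
    planes[[k]] <- p
  }
  planes[[7]] <- vmask * 1
  tiff::writeTIFF(planes, path, bits.per.sample = 32)
  meta <- list(type = "reflectance_scene", bands = VBI_BANDS,
               sensor = scene$sensor,
               geo = scene$geo[c("nrow", "ncol", "xmin", "ymax", "res",
                                 "crs")],
               pack = list(min = pack_min, max = pack_max),
               validity_plane = TRUE)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing georeferencing sidecar '", sc,
         "': cannot interpret the raster")
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Read a reflectance scene written by [write_scene()]
#'
#' Validates the band count, restores the packing recorded in the sidecar,
#' and unifies nodata across bands (a pixel invalid in any band is invalid
#' in all).
#'
#' @param path TIFF path with sidecar.
#' @param sensor Optional sensor override; defaults to the sidecar's.
#' @return A [reflectance_scene()].
#' @export
read_scene <- function(path, sensor = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  meta <- read_sidecar(path)
  if (is.null(meta$geo$crs)) stop("sidecar of '", path, "' carries no CRS")
  planes <- tiff::readTIFF(path, all = TRUE)
  n_band <- length(planes) - isTRUE(meta$validity_plane)
  if (n_band < 6)
    stop("scene file '", path, "' has ", n_band, " bands; need 6 (",
         paste(VBI_BANDS, collapse = ", "), ")")
  pack <- meta$pack
  vmask <- if (isTRUE(meta$validity_plane))
    planes[[length(planes)]] > 0.5 else NULL
  bands <- array(NA_real_, c(nrow(planes[[1]]), ncol(planes[[1]]), 6))
  for (k in 1:6) {
    p <- planes[[k]] * (pack$max - pack$min) + pack$min
    if (!is.null(vmask)) p[!vmask] <- NA_real_
    bands[, , k] <- p
  }
  geo <- grid_geo(meta$geo$nrow, meta$geo$ncol, meta$geo$xmin,
                  meta$geo$ymax, meta$geo$res, meta$geo$crs)
  reflectance_scene(bands,
                    geo,
                    sensor = if (is.null(sensor)) meta$sensor else sensor)
}

#' Write a class map as an 8-bit TIFF + sidecar
#'
#' Uses the frozen class code table [VBI_CLASSES] (0 nodata, 1 SAV, 2 FEAV,
#' 3 AB, 4 OW); codes round-trip bit-exactly.
#'
#' @param cm A [class_map()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_classmap <- function(cm, path) {
  tiff::writeTIFF(cm$codes / 255, path, bits.per.sample = 8)
  meta <- list(type = "class_map", class_codes = as.list(VBI_CLASSES),
               geo = cm$geo[c("nrow", "ncol", "xmin", "ymax", "res", "crs")],
               provenance = cm$provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a class map written by [write_classmap()]
#'
#' @param path TIFF path with sidecar.
#' @return A [class_map()].
#' @export
read_classmap <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  meta <- read_sidecar(path)
  codes <- round(tiff::readTIFF(path) * 255)
  storage.mode(codes) <- "integer"
  geo <- grid_geo(meta$geo$nrow, meta$geo$ncol, meta$geo$xmin,
                  meta$geo$ymax, meta$geo$res, meta$geo$crs)
  prov <- meta$provenance
  if (is.null(prov)) prov <- list()
  class_map(codes, geo, provenance = prov)
}

# even-odd rule point-in-polygon; ring is a data.frame/matrix with x, y
points_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon (lake boundary) onto a grid
#'
#' Pixel-centre membership with the even-odd rule: a pixel is inside when
#' its centre falls inside an odd number of rings, so holes are supported by
#' supplying inner rings.
#'
#' @param polygon A data.frame/matrix with columns `x`, `y` (one ring), or a
#'   list of such rings.
#' @param geo Target [grid_geo()].
#' @return Logical matrix over the grid; a warning is raised when no pixel
#'   centre falls inside.
#' @export
rasterize_mask <- function(polygon, geo) {
  if (!is.list(polygon) || is.data.frame(polygon)) polygon <- list(polygon)
  ctr <- pixel_centers(geo)
  px <- rep(ctr$x, each = geo$nrow)
  py <- rep(ctr$y, times = geo$ncol)
  inside <- rep(FALSE, length(px))
  for (ring in polygon) {
    ring <- as.matrix(as.data.frame(ring)[, c("x", "y")])
    if (nrow(ring) < 3) stop("a polygon ring needs at least 3 vertices")
    inside <- xor(inside, points_in_ring(px, py, ring))
  }
  m <- matrix(inside, geo$nrow, geo$ncol)
  if (!any(m))
    warning("rasterized mask is empty: polygon does not overlap the grid")
  m
}

#' Write an analysis artifact with a provenance sidecar
#'
#' Writes a data frame as CSV (or a list as JSON) together with a
#' `<path>.provenance.json` sidecar recording the configuration used, a
#' deterministic config hash, and the package version.  Identical
#' configurations yield identical hashes.
#'
#' @param object Data frame (written as CSV) or list (written as JSON).
#' @param path Output path.
#' @param config List of settings to record (thresholds, seeds, inputs...).
#' @return `path`, invisibly.
#' @export
write_outputs <- function(object, path, config = list()) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  if (is.data.frame(object)) {
    utils::write.csv(object, path, row.names = FALSE)
  } else {
    jsonlite::write_json(object, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  prov <- list(config = config, config_hash = hash,
               package = "vbimap",
               version = as.character(utils::packageVersion("vbimap")))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
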