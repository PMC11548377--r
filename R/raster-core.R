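# Lightweight in-memory raster containers used throughout the package.
#
# Grids are row-major matrices; row 1 is the northernmost row, column 1 the
# westernmost column.  Georeferencing follows the usual north-up affine
# convention: pixel (row, col) has its centre at
#   x = xmin + (col - 0.5) * res,  y = ymax - (row - 0.5) * res.
# Missing data is represented with NA inside the matrices; a pixel that is NA
# in any band of a scene is NA in all bands.

#' Reflective band order used by every multiband scene
#'
#' The six Landsat-class reflective bands, in the order expected by
#' [reflectance_scene()] and produced by [read_scene()].
#'
#' @format Character vector of length 6.
#' @export
VBI_BANDS <- c("blue", "green", "red", "nir", "swir1", "swir2")

#' Class code table for categorical maps
#'
#' Integer codes used in [class_map()] rasters and in files written by
#' [write_classmap()]: 0 nodata, 1 SAV, 2 FEAV, 3 AB, 4 OW.  The table is
#' frozen so class maps interchange bit-exactly across runs.
#'
#' @format Named integer vector.
#' @export
VBI_CLASSES <- c(NODATA = 0L, SAV = 1L, FEAV = 2L, AB = 3L, OW = 4L)

#' Construct grid georeferencing metadata
#'
#' @param nrow,ncol Grid dimensions in pixels.
#' @param xmin X coordinate of the western (left) grid edge.
#' @param ymax Y coordinate of the northern (top) grid edge.
#' @param res Square pixel size in CRS units.
#' @param crs Coordinate reference system, stored as an opaque string.
#' @return A `grid_geo` object (list with the grid shape and affine terms).
#' @export
grid_geo <- function(nrow, ncol, xmin = 0, ymax = nrow * res, res = 30,
                     crs = "local") {
  stopifnot(nrow >= 1, ncol >= 1, res > 0)
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         xmin = xmin, ymax = ymax, res = res, crs = crs),
    class = "grid_geo"
  )
}

geo_equal <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$res - b$res) < tol && identical(a$crs, b$crs)
}

#' Pixel-centre coordinates of a grid
#'
#' @param geo A [grid_geo()] object.
#' @return List with numeric vectors `x` (length ncol) and `y` (length nrow).
#' @export
pixel_centers <- function(geo) {
  list(x = geo$xmin + (seq_len(geo$ncol) - 0.5) * geo$res,
       y = geo$ymax - (seq_len(geo$nrow) - 0.5) * geo$res)
}

#' Map point coordinates to grid row/column indices
#'
#' Points are assigned to the pixel whose centre is nearest (equivalently, the
#' pixel whose cell contains the point; points on a cell edge fall to the
#' cell below/right by the floor convention).
#'
#' @param geo A [grid_geo()] object.
#' @param x,y Numeric coordinate vectors of equal length.
#' @return Data frame with integer columns `row`, `col`; NA where the point
#'   falls outside the grid extent.
#' @export
point_to_cell <- function(geo, x, y) {
  stopifnot(length(x) == length(y))
  col <- floor((x - geo$xmin) / geo$res) + 1
  row <- floor((geo$ymax - y) / geo$res) + 1
  bad <- col < 1 | col > geo$ncol | row < 1 | row > geo$nrow
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Construct a six-band surface-reflectance scene
#'
#' Bands are dimensionless surface reflectance, nominally in \[0, 1\]; small
#' negative values (possible after atmospheric correction) are deliberately
#' not clipped.  The nodata footprint is unified on construction: a pixel NA
#' in any band becomes NA in all bands.
#'
#' @param bands Either a `nrow x ncol x 6` numeric array or a list of six
#'   equally sized matrices, ordered as [VBI_BANDS].
#' @param geo A [grid_geo()] object; defaults to a unit local grid.
#' @param sensor Sensor identifier (`"TM"`, `"ETM+"` or `"OLI"`).
#' @return A `reflectance_scene` object.
#' @seealso [compute_avi()], [classify_scene()], [read_scene()]
#' @export
reflectance_scene <- function(bands, geo = NULL, sensor = "TM") {
  if (is.list(bands)) {
    if (length(bands) != 6)
      stop("a reflectance scene needs exactly 6 bands, got ", length(bands))
    dm <- dim(bands[[1]])
    for (b in bands)
      if (!identical(dim(b), dm))
        stop("all band planes must share the same shape")
    bands <- array(unlist(bands, use.names = FALSE), dim = c(dm, 6))
  }
  if (!is.array(bands) || length(dim(bands)) != 3 || dim(bands)[3] != 6)
    stop("a reflectance scene needs exactly 6 bands, got ",
         if (is.array(bands)) dim(bands)[3] else "a non-array")
  dimnames(bands) <- list(NULL, NULL, VBI_BANDS)
  if (is.null(geo)) geo <- grid_geo(dim(bands)[1], dim(bands)[2], res = 1)
  if (geo$nrow != dim(bands)[1] || geo$ncol != dim(bands)[2])
    stop("grid metadata shape (", geo$nrow, "x", geo$ncol,
         ") does not match band shape (", dim(bands)[1], "x", dim(bands)[2], ")")
  # unify nodata across bands
  invalid <- apply(is.na(bands), c(1, 2), any)
  if (any(invalid))
    for (k in 1:6) bands[, , k][invalid] <- NA_real_
  structure(list(bands = bands, geo = geo, sensor = sensor),
            class = "reflectance_scene")
}

#' @export
print.reflectance_scene <- function(x, ...) {
  cat(sprintf("reflectance_scene: %d x %d pixels, 6 bands, sensor %s\n",
              x$geo$nrow, x$geo$ncol, x$sensor))
  cat(sprintf("  valid pixels: %d / %d\n",
              sum(!is.na(x$bands[, , 1])), x$geo$nrow * x$geo$ncol))
  invisible(x)
}

#' Extract one band plane of a scene
#'
#' @param scene A [reflectance_scene()].
#' @param band Band name, one of [VBI_BANDS].
#' @return Numeric matrix.
#' @export
scene_band <- function(scene, band) {
  band <- match.arg(band, VBI_BANDS)
  matrix(scene$bands[, , band], scene$geo$nrow, scene$geo$ncol)
}

#' Logical matrix of valid (non-nodata) scene pixels
#' @param scene A [reflectance_scene()].
#' @return Logical matrix, TRUE where the pixel carries data.
#' @export
valid_mask <- function(scene) !is.na(scene$bands[, , 1])

#' Apply an invalid-pixel or lake mask to a scene
#'
#' Pixels where `mask` is FALSE (e.g. land outside the lake boundary, clouds)
#' become nodata in every band.
#'
#' @param scene A [reflectance_scene()].
#' @param mask Logical matrix of the scene's shape.
#' @return A masked `reflectance_scene`.
#' @export
mask_scene <- function(scene, mask) {
  stopifnot(is.logical(mask), identical(dim(mask), dim(scene$bands)[1:2]))
  bands <- scene$bands
  drop <- !mask
  for (k in 1:6) bands[, , k][drop] <- NA_real_
  reflectance_scene(bands, scene$geo, scene$sensor)
}

#' Single-index raster derived from a scene
#'
#' @param values Numeric matrix of index values (NA = nodata).
#' @param kind One of `"AVI"`, `"FAI"`, `"NDVI"`, `"NDWI"`.
#' @param geo A [grid_geo()] matching `values`.
#' @return An `index_raster` object.
#' @export
index_raster <- function(values, kind, geo) {
  kind <- match.arg(kind, c("AVI", "FAI", "NDVI", "NDWI"))
  stopifnot(is.matrix(values), geo$nrow == nrow(values), geo$ncol == ncol(values))
  structure(list(values = values, kind = kind, geo = geo),
            class = "index_raster")
}

#' @export
print.index_raster <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("index_raster (%s): %d x %d, range [%.4f, %.4f]\n",
              x$kind, x$geo$nrow, x$geo$ncol, rng[1], rng[2]))
  invisible(x)
}

#' Categorical class map over a scene grid
#'
#' @param codes Integer matrix with values from [VBI_CLASSES] (0 = nodata).
#' @param geo A [grid_geo()] matching `codes`.
#' @param provenance Optional list recording how the map was produced
#'   (thresholds used, scene identifier, acquisition date).
#' @return A `class_map` object.
#' @export
class_map <- function(codes, geo, provenance = list()) {
  stopifnot(is.matrix(codes), geo$nrow == nrow(codes), geo$ncol == ncol(codes))
  storage.mode(codes) <- "integer"
  bad <- setdiff(unique(as.vector(codes)), unname(VBI_CLASSES))
  if (length(bad))
    stop("class map contains codes outside the class table: ",
         paste(bad, collapse = ", "))
  structure(list(codes = codes, geo = geo, provenance = provenance),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(class_labels(x), levels = names(VBI_CLASSES)[-1]))
  cat(sprintf("class_map: %d x %d pixels\n", x$geo$nrow, x$geo$ncol))
  print(tab)
  invisible(x)
}

#' Class labels of a class map as a character matrix
#'
#' @param cm A [class_map()].
#' @return Character matrix with entries `"SAV"`, `"FEAV"`, `"AB"`, `"OW"`
#'   and NA for nodata.
#' @export
class_labels <- function(cm) {
  lab <- names(VBI_CLASSES)[match(cm$codes, VBI_CLASSES)]
  lab[lab == "NODATA"] <- NA_character_
  matrix(lab, nrow(cm$codes), ncol(cm$codes))
}

crop_geo <- function(geo, rows, cols) {
  stopifnot(all(diff(rows) == 1), all(diff(cols) == 1))
  grid_geo(length(rows), length(cols),
           xmin = geo$xmin + (min(cols) - 1) * geo$res,
           ymax = geo$ymax - (min(rows) - 1) * geo$res,
           res = geo$res, crs = geo$crs)
}

#' Crop a scene to a contiguous row/column window
#'
#' @param scene A [reflectance_scene()].
#' @param rows,cols Contiguous integer index vectors.
#' @return Cropped `reflectance_scene` with adjusted georeferencing.
#' @export
crop_scene <- function(scene, rows, cols) {
  reflectance_scene(scene$bands[rows, cols, , drop = FALSE],
                    crop_geo(scene$geo, rows, cols), scene$sensor)
}

#' Crop a class map to a contiguous row/column window
#'
#' @param cm A [class_map()].
#' @param rows,cols Contiguous integer index vectors.
#' @return Cropped `class_map`.
#' @export
crop_classmap <- function(cm, rows, cols) {
  class_map(cm$codes[rows, cols, drop = FALSE],
            crop_geo(cm$geo, rows, cols), cm$provenance)
}
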