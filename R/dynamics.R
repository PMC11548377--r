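# Coverage dynamics: per-class area fractions of dated class maps and their
# seasonal/interannual assembly into a long-format time series.

#' Season of a calendar date
#'
#' Meteorological seasons: Mar-May spring, Jun-Aug summer, Sep-Nov autumn,
#' Dec-Feb winter.  The imaging windows used for vegetation mapping
#' (April-May and July-August) fall inside spring and summer respectively.
#'
#' @param date Anything `as.Date` accepts; vectorized.
#' @return Character vector with values `"spring"`, `"summer"`, `"autumn"`,
#'   `"winter"`.
#' @export
season_of <- function(date) {
  d <- as.Date(date)
  if (anyNA(d)) stop("unparseable date: ",
                     paste(date[is.na(d)], collapse = ", "))
  m <- as.integer(format(d, "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Per-class coverage fractions of a class map
#'
#' Fractions are counts over the *valid* (classified, non-nodata) pixels
#' inside the lake mask, so cloud- or land-masked pixels do not deflate
#' coverage.
#'
#' @param cm A [class_map()].
#' @param lake_mask Optional logical matrix restricting the accounting to the
#'   lake; defaults to the whole grid.
#' @param date Optional date attached to the record.
#' @return A `coverage_record`: list with `date`, `season`, `fractions`
#'   (named over SAV, FEAV, AB, OW; sums to 1) and `valid_pixel_count`.
#' @export
coverage_fraction <- function(cm, lake_mask = NULL, date = NULL) {
  stopifnot(inherits(cm, "class_map"))
  codes <- cm$codes
  if (!is.null(lake_mask)) {
    stopifnot(identical(dim(lake_mask), dim(codes)))
    if (!any(lake_mask)) stop("empty lake mask: no pixels to account")
    codes[!lake_mask] <- VBI_CLASSES[["NODATA"]]
  }
  valid <- codes != VBI_CLASSES[["NODATA"]]
  n <- sum(valid)
  if (n == 0) stop("no valid classified pixels under the mask")
  classes <- names(VBI_CLASSES)[-1]
  fr <- vapply(classes, function(cl) sum(codes == VBI_CLASSES[[cl]]) / n,
               numeric(1))
  if (is.null(date) && !is.null(cm$provenance$date)) date <- cm$provenance$date
  structure(list(date = if (is.null(date)) NA else as.Date(date),
                 season = if (is.null(date)) NA_character_
                          else season_of(date),
                 fractions = fr, valid_pixel_count = n),
            class = "coverage_record")
}

#' Assemble coverage records into a long-format time series
#'
#' @param records List of `coverage_record`s (each with a non-missing date).
#' @return Data frame with columns `year`, `season`, `class`, `fraction`,
#'   `valid_pixels`, sorted by year within season.  Missing year-season
#'   combinations are simply absent.  Duplicate (year, season) pairs are an
#'   error.
#' @export
build_timeseries <- function(records) {
  cols <- c("year", "season", "class", "fraction", "valid_pixels")
  if (length(records) == 0) {
    out <- data.frame(year = integer(0), season = character(0),
                      class = character(0), fraction = numeric(0),
                      valid_pixels = integer(0))
    return(out[cols])
  }
  rows <- lapply(records, function(r) {
    if (!inherits(r, "coverage_record")) stop("not a coverage_record")
    if (is.na(r$date)) stop("coverage record without a date")
    data.frame(year = as.integer(format(r$date, "%Y")), season = r$season,
               class = names(r$fractions), fraction = unname(r$fractions),
               valid_pixels = r$valid_pixel_count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keys <- paste(sapply(records, function(r) format(r$date, "%Y")),
                sapply(records, function(r) r$season))
  if (anyDuplicated(keys))
    stop("duplicate (year, season) records: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  out <- out[order(out$season, out$year, out$class), cols]
  rownames(out) <- NULL
  out
}
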