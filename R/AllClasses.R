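#' @import methods
NULL

#' Crop calendar
#'
#' Reference planting and harvest days for the crops grown at a site.
#' Day-of-year values are 1-based on a 365-day-year convention; winter crops
#' (harvest DOY smaller than planting DOY) span the year boundary.
#'
#' @slot entries data.frame with columns \code{crop}, \code{planting_doy},
#'   \code{harvest_doy}.
#' @exportClass CropCalendar
setClass("CropCalendar", representation(entries = "data.frame"))

setValidity("CropCalendar", function(object) {
  e <- object@entries
  msg <- character(0)
  need <- c("crop", "planting_doy", "harvest_doy")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(e$crop)) msg <- c(msg, "duplicate crop names")
  doys <- c(e$planting_doy, e$harvest_doy)
  if (any(!is.finite(doys)) || any(doys < 1 | doys > 366))
    msg <- c(msg, "DOYs must lie in [1, 366]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a crop calendar
#'
#' @param crop character vector of crop names.
#' @param planting_doy,harvest_doy 1-based day-of-year vectors.
#' @return A \linkS4class{CropCalendar}.
#' @examples
#' cropCalendar(c("rice", "wheat"), c(135, 314), c(283, 121))
#' @export
cropCalendar <- function(crop, planting_doy, harvest_doy) {
  new("CropCalendar", entries = data.frame(
    crop = as.character(crop),
    planting_doy = as.numeric(planting_doy),
    harvest_doy = as.numeric(harvest_doy),
    stringsAsFactors = FALSE))
}

#' Reference crop calendar for the Nile Delta study system
#'
#' Planting/harvest days for the four major cash crops of an irrigated
#' double-cropping rotation: rice (15 May - 10 Oct), maize (1 May - 10 Aug),
#' wheat (10 Nov - 1 May) and clover (1 Oct - 1 May).
#'
#' @return A \linkS4class{CropCalendar}.
#' @export
nileDeltaCalendar <- function() {
  cropCalendar(
    crop = c("rice", "maize", "wheat", "clover"),
    planting_doy = c(135, 121, 314, 274),
    harvest_doy = c(283, 222, 121, 121))
}

#' @describeIn CropCalendar crops present in the calendar
#' @param object,x a \code{CropCalendar}
#' @export
setMethod("names", "CropCalendar", function(x) x@entries$crop)

#' Calendar entry lookup
#'
#' @param calendar a \linkS4class{CropCalendar}
#' @param crop crop name
#' @return list with \code{planting_doy} and \code{harvest_doy}
#' @export
calendarEntry <- function(calendar, crop) {
  i <- match(crop, calendar@entries$crop)
  if (is.na(i)) stop("crop '", crop, "' not found in calendar")
  list(planting_doy = calendar@entries$planting_doy[i],
       harvest_doy = calendar@entries$harvest_doy[i])
}

setMethod("show", "CropCalendar", function(object) {
  cat("CropCalendar with", nrow(object@entries), "crops\n")
  print(object@entries, row.names = FALSE)
})

#' Sampled LAI time series
#'
#' An irregularly sampled per-parcel (or per-pixel) LAI series. Times are
#' continuous days since the epoch (1 January of the first simulated year);
#' values are green LAI in m2/m2. Optional per-point predictive standard
#' deviations and sensor tags are carried along.
#'
#' @slot times strictly increasing numeric days since epoch
#' @slot values numeric LAI values, same length
#' @slot sd numeric per-point standard deviations (NA when unknown)
#' @slot sensor character per-point sensor tag
#' @slot parcelId length-1 character parcel identifier
#' @exportClass SampledSeries
setClass("SampledSeries", representation(
  times = "numeric", values = "numeric", sd = "numeric",
  sensor = "character", parcelId = "character"))

setValidity("SampledSeries", function(object) {
  n <- length(object@times)
  msg <- character(0)
  if (length(object@values) != n || length(object@sd) != n ||
      length(object@sensor) != n)
    msg <- c(msg, "per-point slots must have equal lengths")
  if (n > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@parcelId) != 1) msg <- c(msg, "parcelId must be length 1")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a sampled series
#'
#' @param times days since epoch, strictly increasing
#' @param values LAI values
#' @param sd optional per-point standard deviation
#' @param sensor per-point sensor tag (recycled if length 1)
#' @param parcelId parcel identifier
#' @return A \linkS4class{SampledSeries}.
#' @export
sampledSeries <- function(times, values, sd = NA_real_, sensor = "unknown",
                          parcelId = "parcel") {
  n <- length(times)
  new("SampledSeries",
      times = as.numeric(times), values = as.numeric(values),
      sd = rep_len(as.numeric(sd), n), sensor = rep_len(as.character(sensor), n),
      parcelId = as.character(parcelId))
}

#' @describeIn SampledSeries number of observations
#' @export
setMethod("length", "SampledSeries", function(x) length(x@times))

#' Accessors for SampledSeries
#'
#' @param x a \linkS4class{SampledSeries}
#' @return numeric or character vector of per-point fields.
#' @name series-accessors
NULL

#' @rdname series-accessors
#' @export
seriesTimes <- function(x) x@times
#' @rdname series-accessors
#' @export
seriesValues <- function(x) x@values
#' @rdname series-accessors
#' @export
seriesSd <- function(x) x@sd
#' @rdname series-accessors
#' @export
seriesSensor <- function(x) x@sensor
#' @rdname series-accessors
#' @export
parcelId <- function(x) x@parcelId

setMethod("show", "SampledSeries", function(object) {
  n <- length(object@times)
  if (n == 0) {
    cat(sprintf("SampledSeries '%s': empty\n", object@parcelId))
    return(invisible(NULL))
  }
  cat(sprintf("SampledSeries '%s': %d obs, days %.1f..%.1f, LAI %.2f..%.2f\n",
              object@parcelId, n, min(object@times), max(object@times),
              min(object@values), max(object@values)))
  cat("  sensors:", paste(unique(object@sensor), collapse = ", "), "\n")
})

#' Convert a SampledSeries to a data.frame
#'
#' @param x a \linkS4class{SampledSeries}
#' @param epochYear first simulated year, used to render ISO dates
#' @param ... ignored
#' @return data.frame with columns parcel_id, date, sensor, lai, lai_sd, day
#' @export
seriesAsDataFrame <- function(x, epochYear = 2016, ...) {
  data.frame(
    parcel_id = x@parcelId,
    date = format(as.Date(paste0(epochYear, "-01-01")) + round(x@times)),
    sensor = x@sensor,
    lai = x@values,
    lai_sd = x@sd,
    day = x@times,
    stringsAsFactors = FALSE)
}

#' Scene stack: a small raster LAI (or truth) time series
#'
#' Pixel-by-pixel LAI series on a regular grid with per-date metadata, plus a
#' parcel-membership map. Values are stored as an array with dimensions
#' (rows, cols, dates).
#'
#' @slot lai numeric array (nrow, ncol, ntime)
#' @slot times numeric acquisition days since epoch
#' @slot sensor character per-date sensor tags
#' @slot parcelMap integer matrix (nrow, ncol); 0 = background
#' @slot parcelIds character names for parcel indices
#' @exportClass SceneStack
setClass("SceneStack", representation(
  lai = "array", times = "numeric", sensor = "character",
  parcelMap = "matrix", parcelIds = "character"))

setValidity("SceneStack", function(object) {
  d <- dim(object@lai)
  msg <- character(0)
  if (length(d) != 3) return("lai must be a 3-d array (rows, cols, dates)")
  if (d[1] < 1 || d[2] < 1) msg <- c(msg, "grid must be non-empty")
  if (d[3] != length(object@times)) msg <- c(msg, "times length must match dim 3")
  if (length(object@sensor) != length(object@times))
    msg <- c(msg, "sensor length must match times")
  if (!all(dim(object@parcelMap) == d[1:2]))
    msg <- c(msg, "parcelMap dimensions must match the grid")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "SceneStack", function(object) {
  d <- dim(object@lai)
  cat(sprintf("SceneStack: %d x %d pixels, %d dates, %d parcels\n",
              d[1], d[2], d[3], length(object@parcelIds)))
})

#' @describeIn SceneStack grid dimensions (rows, cols, dates)
#' @param x a \code{SceneStack}
#' @export
setMethod("dim", "SceneStack", function(x) dim(x@lai))

#' Extract one pixel's series from a scene stack
#'
#' @param stack a \linkS4class{SceneStack}
#' @param row,col 1-based pixel indices
#' @return A \linkS4class{SampledSeries} tagged with \code{pixel_<row>_<col>}.
#' @export
pixelSeries <- function(stack, row, col) {
  v <- stack@lai[row, col, ]
  keep <- !is.na(v)
  sampledSeries(stack@times[keep], v[keep], sensor = stack@sensor[keep],
                parcelId = sprintf("pixel_%d_%d", row, col))
}
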