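#' File interfaces
#'
#' Plain-text and TIFF interchange for the package's objects: sampled series
#' and season tables as CSV, scene stacks as one single-band TIFF per date
#' with a JSON manifest carrying dates, sensor tags, geotransform and CRS,
#' and parcel footprints as GeoJSON.
#'
#' @name pheno-io
NULL

#' Write / read sampled series as CSV
#'
#' Columns: parcel_id, date (ISO-8601), sensor, lai, lai_sd, day.
#'
#' @param series a \linkS4class{SampledSeries} or list of them
#' @param path CSV file path
#' @param epochYear first simulated year (renders the date column)
#' @return \code{writeSeriesCSV} returns \code{path} invisibly;
#'   \code{readSeriesCSV} returns a named list of \code{SampledSeries}.
#' @export
writeSeriesCSV <- function(series, path, epochYear = 2016) {
  if (is(series, "SampledSeries")) series <- list(series)
  df <- do.call(rbind, lapply(series, seriesAsDataFrame, epochYear = epochYear))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSeriesCSV
#' @export
readSeriesCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$parcel_id), function(d) {
    d <- d[order(d$day), ]
    sampledSeries(d$day, d$lai, sd = d$lai_sd, sensor = d$sensor,
                  parcelId = d$parcel_id[1])
  })
}

#' Write a seasons table as CSV
#'
#' @param seasons seasons data.frame
#' @param path CSV file path
#' @return \code{path}, invisibly
#' @export
writeSeasonsCSV <- function(seasons, path) {
  num <- vapply(seasons, is.numeric, logical(1))
  seasons[num] <- lapply(seasons[num], function(x) round(x, 6))
  utils::write.csv(seasons, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a scene stack as TIFF rasters plus a JSON manifest
#'
#' One 32-bit float TIFF per acquisition date (values are LAI; the files are
#' plain TIFF, georeferencing lives in the manifest as a geotransform and CRS
#' string) plus \code{manifest.json} recording dates, sensors, the parcel map
#' and grid geometry.
#'
#' @param stack a \linkS4class{SceneStack}
#' @param dir output directory (created if missing)
#' @param geotransform numeric length-6 affine (GDAL order); default places
#'   the grid at the origin with 30 m pixels
#' @param crs CRS description string
#' @return \code{writeSceneStack} returns \code{dir} invisibly;
#'   \code{readSceneStack} returns the restored \linkS4class{SceneStack}.
#' @export
writeSceneStack <- function(stack, dir,
                            geotransform = c(0, 30, 0, 0, 0, -30),
                            crs = "EPSG:32636") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack@lai)
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    files[k] <- sprintf("lai_day%05.0f.tif", stack@times[k])
    img <- stack@lai[, , k]
    tiff::writeTIFF(img / 10, file.path(dir, files[k]), bits.per.sample = 32)
  }
  manifest <- list(times = stack@times, sensor = stack@sensor,
                   files = files, scale = 10,
                   parcelMap = stack@parcelMap, parcelIds = stack@parcelIds,
                   geotransform = geotransform, crs = crs)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeSceneStack
#' @export
readSceneStack <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  imgs <- lapply(man$files, function(f) tiff::readTIFF(file.path(dir, f)) * man$scale)
  lai <- array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs)))
  new("SceneStack", lai = lai, times = as.numeric(man$times),
      sensor = man$sensor, parcelMap = as.matrix(man$parcelMap),
      parcelIds = man$parcelIds)
}

#' Write parcel footprints as GeoJSON
#'
#' Rectangular parcel footprints are reconstructed from the scene parcel map
#' and written as a FeatureCollection of polygons in grid coordinates scaled
#' by the geotransform.
#'
#' @param stack a \linkS4class{SceneStack}
#' @param path output GeoJSON path
#' @param geotransform numeric length-6 affine (GDAL order)
#' @param crop optional per-parcel crop labels
#' @return \code{path}, invisibly
#' @export
writeParcelsGeoJSON <- function(stack, path,
                                geotransform = c(0, 30, 0, 0, 0, -30),
                                crop = NULL) {
  gt <- geotransform
  xy <- function(col, row) c(gt[1] + col * gt[2] + row * gt[3],
                             gt[4] + col * gt[5] + row * gt[6])
  feats <- lapply(seq_along(stack@parcelIds), function(p) {
    idx <- which(stack@parcelMap == p, arr.ind = TRUE)
    r0 <- min(idx[, 1]) - 1; r1 <- max(idx[, 1]); c0 <- min(idx[, 2]) - 1; c1 <- max(idx[, 2])
    ring <- list(xy(c0, r0), xy(c1, r0), xy(c1, r1), xy(c0, r1), xy(c0, r0))
    props <- list(parcel_id = stack@parcelIds[p])
    if (!is.null(crop)) props$crop <- crop[p]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  doc <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = "EPSG:32636")),
              features = feats)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
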