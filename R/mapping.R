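#' Phenology mapping and per-crop evaluation
#'
#' Per-pixel phenology products (cropping frequency, summer/winter LSP maps,
#' vegetation mask) and the tabular evaluation layer: per-crop means and SDs
#' of SOS/EOS/LOS, season-detection accuracy against a planted record, and the
#' Area-LOS consistency regression.
#'
#' @name mapping-evaluation
NULL

#' Vegetation mask from an LAI scene stack
#'
#' A pixel is masked (non-vegetated) when its maximum LAI over time does not
#' exceed \code{threshold}.
#'
#' @param stack a \linkS4class{SceneStack}
#' @param threshold LAI threshold (default 1)
#' @return logical matrix, TRUE = masked
#' @export
vegetationMask <- function(stack, threshold = 1) {
  apply(stack@lai, c(1, 2), function(v) {
    m <- suppressWarnings(max(v, na.rm = TRUE))
    !is.finite(m) || m <= threshold
  })
}

#' Per-pixel seasons for a whole scene
#'
#' Runs gap-filling (optional) and season extraction pixel by pixel over the
#' unmasked part of a scene.
#'
#' @param stack a \linkS4class{SceneStack}
#' @param cfg a \code{\link{detectionConfig}}
#' @param gapfill if TRUE each pixel series is GPR gap-filled onto a regular
#'   grid before detection
#' @param gridSpacing grid spacing for gap-filling (days)
#' @param maskThreshold vegetation-mask LAI threshold
#' @param seed seed for GPR restarts
#' @return list: \code{seasons} (data.frame with \code{row}, \code{col}
#'   columns appended), \code{mask} (logical matrix)
#' @export
scenePhenology <- function(stack, cfg = detectionConfig(), gapfill = FALSE,
                           gridSpacing = 10, maskThreshold = 1, seed = 1) {
  mask <- vegetationMask(stack, maskThreshold)
  d <- dim(stack@lai)
  rows <- list()
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    if (mask[r, cc]) next
    ser <- pixelSeries(stack, r, cc)
    if (gapfill) ser <- gprGapfill(ser, gridSpacing, seed = seed)
    s <- extractPhenology(ser, cfg)
    if (nrow(s)) { s$row <- r; s$col <- cc; rows[[length(rows) + 1]] <- s }
  }
  seasons <- if (length(rows)) do.call(rbind, rows) else
    cbind(.emptySeasons(), row = integer(0), col = integer(0))
  list(seasons = seasons, mask = mask)
}

#' Cropping-frequency map
#'
#' Number of growth cycles whose SOS falls in \code{year} per pixel; masked
#' pixels are NA.
#'
#' @param sceneSeasons result of \code{\link{scenePhenology}}
#' @param year 0-based simulated-year index
#' @return integer matrix (NA on masked pixels)
#' @export
croppingFrequency <- function(sceneSeasons, year) {
  mask <- sceneSeasons$mask
  freq <- matrix(0L, nrow(mask), ncol(mask))
  freq[mask] <- NA_integer_
  s <- sceneSeasons$seasons
  s <- s[s$year == year, , drop = FALSE]
  if (nrow(s)) for (j in seq_len(nrow(s)))
    freq[s$row[j], s$col[j]] <- freq[s$row[j], s$col[j]] + 1L
  freq
}

#' Summer/winter LSP metric maps
#'
#' Per-pixel SOS/EOS/LOS/Area rasters for one year, split into summer and
#' winter season classes. A single-cropping pixel (one season that year) is
#' mapped with the same value in both map sets; pixels with no season of a
#' class stay NA.
#'
#' @param sceneSeasons result of \code{\link{scenePhenology}} (seasons must
#'   carry \code{season_class}; see \code{\link{assignCrop}})
#' @param year 0-based simulated-year index
#' @return nested list \code{[[class]][[metric]]} of matrices, classes
#'   \code{summer}/\code{winter}, metrics \code{sos_doy}, \code{eos_doy},
#'   \code{los}, \code{area}
#' @export
lspMaps <- function(sceneSeasons, year) {
  mask <- sceneSeasons$mask
  metrics <- c("sos_doy", "eos_doy", "los", "area")
  blank <- matrix(NA_real_, nrow(mask), ncol(mask))
  maps <- list(summer = lapply(metrics, function(m) blank),
               winter = lapply(metrics, function(m) blank))
  names(maps$summer) <- metrics; names(maps$winter) <- metrics
  s <- sceneSeasons$seasons
  s <- s[s$year == year, , drop = FALSE]
  if (nrow(s) == 0) return(maps)
  if (is.null(s$season_class)) stop("seasons must be classed (run assignCrop)")
  perPixel <- split(seq_len(nrow(s)), paste(s$row, s$col))
  for (ix in perPixel) {
    classes <- if (length(ix) == 1) c("summer", "winter") else NULL
    for (j in ix) {
      cls <- if (!is.null(classes)) classes else s$season_class[j]
      for (cl in cls) for (m in metrics)
        maps[[cl]][[m]][s$row[j], s$col[j]] <- s[[m]][j]
    }
  }
  maps
}

# wrap-aware (circular) mean and SD of 1-based DOYs on a 365-day year
.circularDoyStats <- function(doy) {
  ang <- (doy - 1) / 365 * 2 * pi
  mAng <- atan2(mean(sin(ang)), mean(cos(ang)))
  m <- (mAng / (2 * pi) * 365) %% 365 + 1
  dev <- ((doy - m + 182.5) %% 365) - 182.5
  list(mean = m, sd = if (length(doy) >= 2) stats::sd(dev) else NA_real_)
}

#' Per-crop LSP statistics
#'
#' Means and SDs of SOS DOY, EOS DOY and LOS per crop (and per any further
#' grouping columns present, e.g. collection and method). DOY statistics are
#' wrap-aware so winter clusters straddling 31 December do not average to
#' mid-year. Groups of size 1 report the mean with a missing SD. The overall
#' per-group summary averages the per-crop SDs (unweighted, rounded to the
#' nearest day).
#'
#' @param seasons seasons data.frame with \code{crop}, \code{sos_doy},
#'   \code{eos_doy}, \code{los}
#' @param by extra grouping columns (default \code{c("collection", "method")}
#'   intersected with what exists)
#' @return list: \code{per_crop} data.frame and \code{overall} data.frame of
#'   averaged SDs
#' @export
cropStats <- function(seasons, by = c("collection", "method")) {
  by <- intersect(by, names(seasons))
  grp <- interaction(c(list(seasons$crop), seasons[by]), drop = TRUE, sep = "|")
  rows <- lapply(split(seq_len(nrow(seasons)), grp), function(ix) {
    s <- seasons[ix, ]
    sosS <- .circularDoyStats(s$sos_doy); eosS <- .circularDoyStats(s$eos_doy)
    data.frame(crop = s$crop[1],
               s[1, by, drop = FALSE],
               n = length(ix),
               sos_mean = sosS$mean, sos_sd = sosS$sd,
               eos_mean = eosS$mean, eos_sd = eosS$sd,
               los_mean = mean(s$los),
               los_sd = if (length(ix) >= 2) stats::sd(s$los) else NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  perCrop <- do.call(rbind, rows)
  ogrp <- if (length(by)) interaction(perCrop[by], drop = TRUE, sep = "|")
          else factor(rep("all", nrow(perCrop)))
  overall <- do.call(rbind, lapply(split(seq_len(nrow(perCrop)), ogrp), function(ix) {
    data.frame(perCrop[ix[1], by, drop = FALSE],
               sos_sd = round(mean(perCrop$sos_sd[ix])),
               eos_sd = round(mean(perCrop$eos_sd[ix])),
               los_sd = round(mean(perCrop$los_sd[ix])),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(per_crop = perCrop, overall = overall)
}

#' Season-detection accuracy against a planted record
#'
#' Detected seasons are matched one-to-one to planted entries sharing parcel,
#' SOS-year and season class, greedily by proximity of SOS to the planting
#' day. Accuracy per crop is \code{100 * detected / planted}, rounded to the
#' nearest percent; a totals row sums the counts. Seasons with no plausible
#' planted match are tallied in \code{n_unmatched}.
#'
#' @param seasons classed seasons data.frame (needs \code{parcel_id},
#'   \code{year}, \code{season_class}, \code{sos})
#' @param planted planted record (\code{parcel_id}, \code{year},
#'   \code{season_class}, \code{crop}, \code{planting_day})
#' @return list of class \code{DetectionTable}: \code{per_crop} data.frame
#'   (crop, n_planted, n_detected, accuracy), \code{total} row,
#'   \code{n_unmatched}
#' @export
detectionAccuracy <- function(seasons, planted) {
  if (is.null(planted) || nrow(planted) == 0)
    stop("planted record is empty; accuracy is undefined")
  planted$.matched <- FALSE
  unmatched <- 0L
  if (nrow(seasons)) for (j in order(seasons$sos)) {
    cand <- which(!planted$.matched &
                    planted$parcel_id == seasons$parcel_id[j] &
                    planted$year == seasons$year[j] &
                    planted$season_class == seasons$season_class[j])
    if (length(cand) == 0) { unmatched <- unmatched + 1L; next }
    d <- abs(seasons$sos[j] - planted$planting_day[cand])
    planted$.matched[cand[which.min(d)]] <- TRUE
  }
  perCrop <- do.call(rbind, lapply(split(planted, planted$crop), function(p) {
    data.frame(crop = p$crop[1], n_planted = nrow(p),
               n_detected = sum(p$.matched),
               accuracy = round(100 * sum(p$.matched) / nrow(p)),
               stringsAsFactors = FALSE)
  }))
  rownames(perCrop) <- NULL
  total <- data.frame(crop = "total",
                      n_planted = sum(perCrop$n_planted),
                      n_detected = sum(perCrop$n_detected),
                      accuracy = round(100 * sum(perCrop$n_detected) /
                                         sum(perCrop$n_planted)))
  structure(list(per_crop = perCrop, total = total, n_unmatched = unmatched),
            class = "DetectionTable")
}

#' @export
print.DetectionTable <- function(x, ...) {
  print(rbind(x$per_crop, x$total), row.names = FALSE)
  if (x$n_unmatched > 0) cat("unmatched detections:", x$n_unmatched, "\n")
  invisible(x)
}

#' Area-LOS consistency regression
#'
#' Checks the proportionality of the seasonal integral to the season length:
#' Area is first divided by the mean peak LAI (putting it in days), then both
#' variables are z-scored and ordinary least squares is fitted. On the
#' standardized scale the slope equals the correlation coefficient.
#'
#' @param seasons seasons data.frame with \code{area}, \code{los},
#'   \code{v_peak}; at least 3 rows
#' @return list with \code{slope}, \code{intercept}, \code{r}, \code{n}
#' @export
areaLosRegression <- function(seasons) {
  if (nrow(seasons) < 3) stop("need at least 3 seasons for the regression")
  a <- seasons$area / mean(seasons$v_peak)
  l <- seasons$los
  if (stats::sd(a) == 0 || stats::sd(l) == 0)
    stop("degenerate variance: Area or LOS is constant")
  az <- (a - mean(a)) / stats::sd(a)
  lz <- (l - mean(l)) / stats::sd(l)
  fit <- stats::lm(az ~ lz)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(a, l), n = nrow(seasons))
}
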