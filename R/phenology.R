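#' Growing-season detection and land-surface-phenology metrics
#'
#' Detects up to two growing seasons per year from an LAI series using peak
#' prominence and minimum-separation rules, then extracts start of season
#' (SOS), end of season (EOS), length of season (LOS) and the seasonal
#' integral (Area) under either of two amplitude-threshold conventions:
#' \describe{
#'   \item{seasonal}{each season's threshold level is a fraction of its own
#'     amplitude (peak minus the mean of its two flanking minima);}
#'   \item{relative}{one fixed amplitude — mean of the kept peak values minus
#'     mean of the flanking minima over the whole series — sets the level for
#'     every season.}
#' }
#'
#' @name phenology
NULL

#' Detection configuration
#'
#' @param prominence_frac minimum peak prominence as a fraction of the series
#'   range (default 0.30; sensible values 0.10-0.30)
#' @param min_separation minimum days between kept peaks (default 90)
#' @param amplitude_frac SOS/EOS amplitude threshold fraction (default 0.30)
#' @param method "seasonal" or "relative"
#' @return list of class \code{DetectionConfig}
#' @export
detectionConfig <- function(prominence_frac = 0.30, min_separation = 90,
                            amplitude_frac = 0.30,
                            method = c("seasonal", "relative")) {
  stopifnot(prominence_frac > 0, prominence_frac < 1,
            amplitude_frac > 0, amplitude_frac < 1, min_separation > 0)
  structure(list(prominence_frac = prominence_frac,
                 min_separation = min_separation,
                 amplitude_frac = amplitude_frac,
                 method = match.arg(method)),
            class = "DetectionConfig")
}

# indices of strict local maxima (plateaus: first index); endpoints excluded
.localMaxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  idx <- integer(0)
  i <- 2
  while (i < n) {
    if (v[i] > v[i - 1]) {
      j <- i
      while (j < n && v[j + 1] == v[j]) j <- j + 1
      if (j < n && v[j + 1] < v[j]) idx <- c(idx, i)
      i <- j + 1
    } else i <- i + 1
  }
  idx
}

# prominence of peak at index i: drop to the higher of the two bases, where
# each base is the minimum between the peak and the nearest higher point (or
# the series end) on that side
.prominence <- function(v, i) {
  n <- length(v)
  left <- v[i]; j <- i - 1
  while (j >= 1 && v[j] <= v[i]) { left <- min(left, v[j]); j <- j - 1 }
  right <- v[i]; j <- i + 1
  while (j <= n && v[j] <= v[i]) { right <- min(right, v[j]); j <- j + 1 }
  v[i] - max(left, right)
}

#' Detect growing-season peaks
#'
#' Local maxima are screened by (1) prominence at least
#' \code{prominence_frac} of the series range and (2) a minimum time
#' separation: among peaks closer than \code{min_separation} days only the
#' highest survives (earlier wins ties). Endpoint maxima are never eligible
#' (they belong to incomplete cycles). Flanking minima are then located
#' between consecutive kept peaks and toward the series ends.
#'
#' @param series a \linkS4class{SampledSeries} of length >= 5
#' @param cfg a \code{\link{detectionConfig}}
#' @return data.frame of class \code{PeakSet}: one row per kept peak with
#'   \code{t_peak}, \code{v_peak}, \code{prominence}, \code{left_min_t},
#'   \code{left_min_v}, \code{right_min_t}, \code{right_min_v}. Zero rows if
#'   nothing passes.
#' @export
findSeasons <- function(series, cfg = detectionConfig()) {
  n <- length(series)
  if (n < 5) stop("series too short for season detection")
  t <- series@times; v <- series@values
  rng <- max(v) - min(v)
  cand <- .localMaxima(v)
  empty <- data.frame(t_peak = numeric(0), v_peak = numeric(0),
                      prominence = numeric(0),
                      left_min_t = numeric(0), left_min_v = numeric(0),
                      right_min_t = numeric(0), right_min_v = numeric(0))
  class(empty) <- c("PeakSet", "data.frame")
  if (rng <= 0 || length(cand) == 0) return(empty)
  prom <- vapply(cand, function(i) .prominence(v, i), numeric(1))
  keepP <- prom >= cfg$prominence_frac * rng
  cand <- cand[keepP]; prom <- prom[keepP]
  if (length(cand) == 0) return(empty)
  # min-separation: consider peaks highest-first (earlier breaks ties), keep
  # one only if no already-kept peak lies within min_separation days
  ord <- order(-v[cand], t[cand])
  kept <- integer(0)
  for (k in ord) {
    if (!any(abs(t[cand[kept]] - t[cand[k]]) < cfg$min_separation))
      kept <- c(kept, k)
  }
  kept <- sort(cand[kept])
  promKept <- prom[match(kept, cand)]
  # flanking minima between consecutive kept peaks / toward the ends
  bounds <- c(1, vapply(seq_len(length(kept) - 1), function(j) {
    seg <- kept[j]:kept[j + 1]
    seg[which.min(v[seg])]
  }, integer(1)), n)
  res <- lapply(seq_along(kept), function(j) {
    lseg <- bounds[j]:kept[j]
    rseg <- kept[j]:bounds[j + 1]
    li <- lseg[which.min(v[lseg])]
    ri <- rseg[which.min(v[rseg])]
    data.frame(t_peak = t[kept[j]], v_peak = v[kept[j]], prominence = promKept[j],
               left_min_t = t[li], left_min_v = v[li],
               right_min_t = t[ri], right_min_v = v[ri])
  })
  out <- do.call(rbind, res)
  class(out) <- c("PeakSet", "data.frame")
  out
}

# last upward crossing of `level` strictly before index range [from, to]
# (linear interpolation); NA if the curve never crosses
.crossUp <- function(t, v, level, from, to) {
  cross <- NA_real_
  for (i in from:(to - 1)) {
    if (v[i] < level && v[i + 1] >= level)
      cross <- t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  cross
}

.crossDown <- function(t, v, level, from, to) {
  for (i in from:(to - 1)) {
    if (v[i] >= level && v[i + 1] < level)
      return(t[i] + (v[i] - level) / (v[i] - v[i + 1]) * (t[i + 1] - t[i]))
  }
  NA_real_
}

.seasonRow <- function(series, pk, level_l, level_r, method, min_sep) {
  t <- series@times; v <- series@values
  iL <- which(t == pk$left_min_t)[1]; iP <- which(t == pk$t_peak)[1]
  iR <- which(t == pk$right_min_t)[1]
  if (level_l >= pk$v_peak || level_r >= pk$v_peak) return(NULL)
  sos <- .crossUp(t, v, level_l, iL, iP)
  eos <- .crossDown(t, v, level_r, iP, iR)
  if (is.na(sos) || is.na(eos)) return(NULL)   # incomplete or never reached
  data.frame(parcel_id = series@parcelId, method = method,
             t_peak = pk$t_peak, v_peak = pk$v_peak,
             sos = sos, eos = eos,
             sos_doy = doyFromDay(sos), eos_doy = doyFromDay(eos),
             year = epochYearIndex(sos), eos_year = epochYearIndex(eos),
             amplitude = NA_real_, stringsAsFactors = FALSE)
}

#' Extract seasons with the seasonal-amplitude threshold
#'
#' Per season, the amplitude is \code{v_peak - mean(left_min, right_min)};
#' SOS is the last upward crossing of
#' \code{left_min + amplitude_frac * amplitude} before the peak and EOS the
#' first downward crossing of \code{right_min + amplitude_frac * amplitude}
#' after it, both located by linear interpolation. Seasons whose crossings
#' fall outside the series (incomplete cycles) are discarded.
#'
#' @param series a \linkS4class{SampledSeries}
#' @param peaks a \code{PeakSet} from \code{\link{findSeasons}}
#' @param cfg a \code{\link{detectionConfig}}
#' @return data.frame of seasons with SOS/EOS (days and DOY), LOS and Area
#'   (see \code{\link{seasonMetrics}})
#' @export
seasonalThreshold <- function(series, peaks, cfg = detectionConfig()) {
  rows <- lapply(seq_len(nrow(peaks)), function(j) {
    pk <- peaks[j, ]
    amp <- pk$v_peak - mean(c(pk$left_min_v, pk$right_min_v))
    r <- .seasonRow(series, pk,
                    pk$left_min_v + cfg$amplitude_frac * amp,
                    pk$right_min_v + cfg$amplitude_frac * amp,
                    "seasonal", cfg$min_separation)
    if (!is.null(r)) r$amplitude <- amp
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- .emptySeasons()
  seasonMetrics(out, series)
}

#' Extract seasons with the relative-amplitude threshold
#'
#' One amplitude — mean of the kept peak values minus mean of all flanking
#' minima — is shared by every season; a season whose curve never reaches its
#' level is not detected.
#'
#' @inheritParams seasonalThreshold
#' @return data.frame of seasons (possibly fewer than the seasonal method
#'   finds when amplitudes are unequal)
#' @export
relativeThreshold <- function(series, peaks, cfg = detectionConfig()) {
  if (nrow(peaks) == 0) return(.emptySeasons())
  relAmp <- mean(peaks$v_peak) -
    mean(c(peaks$left_min_v, peaks$right_min_v))
  rows <- lapply(seq_len(nrow(peaks)), function(j) {
    pk <- peaks[j, ]
    r <- .seasonRow(series, pk,
                    pk$left_min_v + cfg$amplitude_frac * relAmp,
                    pk$right_min_v + cfg$amplitude_frac * relAmp,
                    "relative", cfg$min_separation)
    if (!is.null(r)) r$amplitude <- relAmp
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- .emptySeasons()
  seasonMetrics(out, series)
}

.emptySeasons <- function() {
  data.frame(parcel_id = character(0), method = character(0),
             t_peak = numeric(0), v_peak = numeric(0),
             sos = numeric(0), eos = numeric(0),
             sos_doy = numeric(0), eos_doy = numeric(0),
             year = numeric(0), eos_year = numeric(0),
             amplitude = numeric(0), los = numeric(0), area = numeric(0),
             stringsAsFactors = FALSE)
}

#' Length and area of detected seasons
#'
#' LOS is EOS minus SOS in absolute days. Area is the trapezoidal integral of
#' the LAI curve above the chord joining the curve values at SOS and EOS
#' (negative excursions floored at 0), in LAI-days.
#'
#' @param seasons data.frame with \code{sos}/\code{eos} columns (absolute days)
#' @param series the \linkS4class{SampledSeries} the seasons came from
#' @return \code{seasons} with \code{los} and \code{area} columns filled
#' @export
seasonMetrics <- function(seasons, series) {
  if (nrow(seasons) == 0) {
    seasons$los <- numeric(0); seasons$area <- numeric(0)
    return(seasons)
  }
  if (any(seasons$eos < seasons$sos)) stop("season with eos < sos")
  seasons$los <- seasons$eos - seasons$sos
  t <- series@times; v <- series@values
  seasons$area <- vapply(seq_len(nrow(seasons)), function(j) {
    s <- seasons$sos[j]; e <- seasons$eos[j]
    if (e == s) return(0)
    vs <- stats::approx(t, v, xout = s)$y
    ve <- stats::approx(t, v, xout = e)$y
    inner <- t[t > s & t < e]
    tt <- c(s, inner, e)
    vv <- c(vs, v[t > s & t < e], ve)
    chord <- vs + (ve - vs) * (tt - s) / (e - s)
    h <- pmax(vv - chord, 0)
    sum(diff(tt) * (utils::head(h, -1) + utils::tail(h, -1)) / 2)
  }, numeric(1))
  seasons
}

#' Classify and label a season by crop
#'
#' Seasons are classed summer when SOS falls in DOY 91-273 (April-September),
#' winter otherwise. The crop label comes from the planted record for that
#' parcel, year and class when available; otherwise the calendar crop whose
#' planting DOY is nearest before/around SOS (circular distance, planting at
#' or before SOS preferred) is used. A season with no candidate is labelled
#' \code{"unknown"}.
#'
#' @param seasons seasons data.frame (needs \code{sos_doy}, \code{year},
#'   \code{parcel_id})
#' @param calendar a \linkS4class{CropCalendar}
#' @param planted optional planted record (columns \code{parcel_id},
#'   \code{year}, \code{season_class}, \code{crop})
#' @return \code{seasons} with \code{season_class} and \code{crop} columns
#' @export
assignCrop <- function(seasons, calendar, planted = NULL) {
  if (nrow(seasons) == 0) {
    seasons$season_class <- character(0); seasons$crop <- character(0)
    return(seasons)
  }
  seasons$season_class <- ifelse(seasons$sos_doy >= 91 & seasons$sos_doy <= 273,
                                 "summer", "winter")
  e <- calendar@entries
  seasons$crop <- vapply(seq_len(nrow(seasons)), function(j) {
    if (!is.null(planted)) {
      hit <- planted$parcel_id == seasons$parcel_id[j] &
        planted$year == seasons$year[j] &
        planted$season_class == seasons$season_class[j]
      if (any(hit)) return(planted$crop[which(hit)[1]])
    }
    if (nrow(e) == 0) return("unknown")
    # circular "days since planting" distance; smallest non-negative wins
    lag <- (seasons$sos_doy[j] - e$planting_doy) %% 365
    e$crop[which.min(lag)]
  }, character(1))
  seasons
}

#' Run season detection end-to-end on one series
#'
#' Convenience wrapper: \code{\link{findSeasons}} then the configured
#' threshold method, then \code{\link{assignCrop}} when a calendar is given.
#'
#' @param series a \linkS4class{SampledSeries}
#' @param cfg a \code{\link{detectionConfig}}
#' @param calendar optional \linkS4class{CropCalendar} for crop labelling
#' @param planted optional planted record
#' @return seasons data.frame
#' @export
extractPhenology <- function(series, cfg = detectionConfig(), calendar = NULL,
                             planted = NULL) {
  peaks <- findSeasons(series, cfg)
  seasons <- if (cfg$method == "seasonal") seasonalThreshold(series, peaks, cfg)
             else relativeThreshold(series, peaks, cfg)
  if (!is.null(calendar)) seasons <- assignCrop(seasons, calendar, planted)
  seasons
}
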