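#' Synthetic cropland scenario generation
#'
#' Ground-truth crop LAI dynamics, sensor-sampled observations, raster scenes
#' and spectra-LAI training pairs emulating an irrigated Nile-Delta-style
#' single-/double-cropping system, so every downstream stage (retrieval,
#' fusion, smoothing, gap-filling, phenology, mapping) is testable without
#' external imagery. The time axis is continuous days since the epoch
#' (1 January of the first simulated year) on a 365-day-year convention.
#'
#' @name synthetic-data
NULL

# Scale RNG use under a fixed seed without disturbing the caller's stream.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
  })
  expr
}

#' Day-of-year from days since epoch
#'
#' 1-based DOY under the package's 365-day-year convention; the companion
#' \code{epochYearIndex} gives the 0-based year offset.
#'
#' @param day numeric days since epoch
#' @return numeric DOY in [1, 365] (\code{doyFromDay}) or integer year offset
#' @export
doyFromDay <- function(day) day - 365 * floor(day / 365) + 1

#' @rdname doyFromDay
#' @export
epochYearIndex <- function(day) floor(day / 365)

#' Length of season from wrapped day-of-year endpoints
#'
#' EOS earlier in the calendar than SOS means the season crossed 31 December;
#' LOS is then computed on the 365-day year.
#'
#' @param sos_doy,eos_doy 1-based day-of-year values
#' @return length of season in days
#' @examples
#' losFromDoys(294, 110)  # winter wheat: 181 days
#' @export
losFromDoys <- function(sos_doy, eos_doy) {
  ifelse(eos_doy >= sos_doy, eos_doy - sos_doy, eos_doy + 365 - sos_doy)
}

# One double-logistic season component evaluated at day t.
.doubleLogistic <- function(t, amp, t_green, rate_green, t_senesce, rate_senesce) {
  amp * (stats::plogis(rate_green * (t - t_green)) -
         stats::plogis(rate_senesce * (t - t_senesce)))
}

#' Ground-truth LAI curve for one crop season
#'
#' Builds a continuous day -> LAI function as a double-logistic pulse on a
#' constant base, anchored on the crop calendar: green-up inflection at
#' planting + 25% of the season span, senescence inflection at harvest - 15%.
#' Winter crops (harvest DOY < planting DOY) span the year boundary.
#'
#' @param crop crop name, must be present in \code{calendar}
#' @param year 0-based index of the simulated year the crop is planted in
#' @param calendar a \linkS4class{CropCalendar}
#' @param params list overriding defaults: \code{peak_lai}, \code{base_lai},
#'   \code{rate_green}, \code{rate_senesce} (1/day)
#' @param seed optional seed; when given, peak LAI is jittered by ~N(0, 0.15^2)
#' @return list of class \code{SeasonTruth}: the curve function plus the truth
#'   parameters (\code{sos_frac_cross} is filled by
#'   \code{\link{truthCrossing}} callers on demand)
#' @export
laiTruthCurve <- function(crop, year, calendar, params = list(), seed = NULL) {
  entry <- calendarEntry(calendar, crop)
  defaults <- list(
    rice = list(peak_lai = 4.5), maize = list(peak_lai = 4.0),
    wheat = list(peak_lai = 5.0), clover = list(peak_lai = 4.0))
  peak <- params$peak_lai %||%
    (defaults[[crop]]$peak_lai %||% 4.0)
  base <- params$base_lai %||% 0.2
  if (!is.null(seed)) peak <- peak + .withSeed(seed, stats::rnorm(1, 0, 0.15))
  peak <- max(peak, base)
  plant <- 365 * year + entry$planting_doy - 1
  harv0 <- entry$harvest_doy - 1
  harvest <- if (entry$harvest_doy > entry$planting_doy)
    365 * year + harv0 else 365 * (year + 1) + harv0
  span <- harvest - plant
  t_green <- params$t_green %||% (plant + 0.25 * span)
  t_senesce <- params$t_senesce %||% (harvest - 0.15 * span)
  rate_green <- params$rate_green %||% (12 / span)
  rate_senesce <- params$rate_senesce %||% (14 / span)
  amp_raw <- peak - base
  # normalize the pulse so its maximum equals peak - base exactly
  tt <- seq(plant, harvest, length.out = 2001)
  raw_max <- max(.doubleLogistic(tt, 1, t_green, rate_green, t_senesce, rate_senesce))
  amp <- if (raw_max > 0) amp_raw / raw_max else 0
  curve <- function(t) {
    pmax(base + .doubleLogistic(t, amp, t_green, rate_green, t_senesce, rate_senesce), 0)
  }
  t_peak <- tt[which.max(curve(tt))]
  structure(list(
    curve = curve, crop = crop, year = year,
    planting_day = plant, harvest_day = harvest,
    peak_lai = peak, base_lai = base, t_peak = t_peak,
    t_green = t_green, t_senesce = t_senesce,
    rate_green = rate_green, rate_senesce = rate_senesce),
    class = "SeasonTruth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sum several season truths into one multi-year parcel truth curve
#'
#' Season pulses add on the shared base level.
#'
#' @param seasons list of \code{SeasonTruth} objects (same \code{base_lai})
#' @return list of class \code{ParcelTruth} with the combined curve and the
#'   per-season truths
#' @export
parcelTruth <- function(seasons) {
  stopifnot(length(seasons) >= 1)
  base <- seasons[[1]]$base_lai
  curve <- function(t) {
    v <- rep(0, length(t))
    for (s in seasons) v <- v + (s$curve(t) - s$base_lai)
    pmax(v + base, 0)
  }
  structure(list(curve = curve, seasons = seasons, base_lai = base),
            class = "ParcelTruth")
}

#' Truth amplitude-crossing days of a season
#'
#' Days where the truth curve first (ascending) and last (descending) crosses
#' \code{base + frac * (peak - base)}, located by bisection to 1e-4 day.
#'
#' @param season a \code{SeasonTruth}
#' @param frac amplitude fraction (default 0.30)
#' @return list with \code{sos}, \code{eos} in days since epoch
#' @export
truthCrossing <- function(season, frac = 0.30) {
  level <- season$base_lai + frac * (season$peak_lai - season$base_lai)
  f <- function(t) season$curve(t) - level
  up <- stats::uniroot(f, c(season$planting_day, season$t_peak), tol = 1e-4)$root
  dn <- stats::uniroot(f, c(season$t_peak, season$harvest_day), tol = 1e-4)$root
  list(sos = up, eos = dn)
}

#' Acquisition schedule
#'
#' Nominal revisit with +/- jitter days and independent per-date cloud gap
#' dropout, emulating a 5-day (S2-like) or 16-day (L8-like) stream.
#'
#' @param sensor sensor tag
#' @param nominal_revisit days between acquisitions, > 0
#' @param jitter uniform jitter half-width in days
#' @param gap_prob probability an acquisition is lost to cloud, in [0, 1]
#' @return list of class \code{AcquisitionSchedule}
#' @export
acquisitionSchedule <- function(sensor, nominal_revisit, jitter = 1, gap_prob = 0) {
  stopifnot(nominal_revisit > 0, gap_prob >= 0, gap_prob <= 1, jitter >= 0)
  structure(list(sensor = sensor, nominal_revisit = nominal_revisit,
                 jitter = jitter, gap_prob = gap_prob),
            class = "AcquisitionSchedule")
}

#' Draw the acquisition dates of a schedule
#'
#' @param schedule an \code{\link{acquisitionSchedule}}
#' @param t0,t1 time window in days since epoch
#' @param seed integer seed
#' @return strictly increasing numeric days (may be empty if all are dropped)
#' @export
scheduleDates <- function(schedule, t0, t1, seed) {
  .withSeed(seed, {
    nominal <- seq(t0, t1, by = schedule$nominal_revisit)
    d <- nominal + stats::runif(length(nominal), -schedule$jitter, schedule$jitter)
    keep <- stats::runif(length(d)) >= schedule$gap_prob
    d <- sort(d[keep])
    if (length(d) > 1) d <- d[c(TRUE, diff(d) > 1e-9)]
    d
  })
}

#' Sample a truth curve through a sensor schedule
#'
#' @param truth a \code{SeasonTruth}, \code{ParcelTruth} or plain function
#'   day -> LAI
#' @param schedule an \code{\link{acquisitionSchedule}}
#' @param t0,t1 observation window in days since epoch
#' @param noise_sd additive Gaussian observation noise SD (LAI), >= 0
#' @param seed integer seed (dates and noise are both derived from it)
#' @param parcelId parcel identifier for the output series
#' @return A \linkS4class{SampledSeries}; errors if every date was dropped.
#' @export
sampleSeries <- function(truth, schedule, t0, t1, noise_sd = 0, seed = 1,
                         parcelId = "parcel") {
  stopifnot(noise_sd >= 0)
  f <- if (is.function(truth)) truth else truth$curve
  d <- scheduleDates(schedule, t0, t1, seed)
  if (length(d) == 0)
    stop("schedule produced an empty series (gap_prob = ", schedule$gap_prob, ")")
  v <- f(d)
  if (noise_sd > 0)
    v <- v + .withSeed(seed + 1L, stats::rnorm(length(d), 0, noise_sd))
  sampledSeries(d, pmax(v, 0), sd = noise_sd, sensor = schedule$sensor,
                parcelId = parcelId)
}

#' Build a multi-year cropping scenario for a set of parcels
#'
#' Each parcel is assigned a rotation: double-cropping parcels grow a summer
#' crop (rice or maize) and a winter crop (wheat or clover) every year;
#' single-cropping parcels grow one crop per year. Returns the per-parcel
#' truth curves and the per-season truth table used as reference ("planted
#' record") by the evaluation stage.
#'
#' @param nParcels number of parcels
#' @param years number of simulated years
#' @param calendar a \linkS4class{CropCalendar}
#' @param doubleFrac fraction of parcels under double-cropping rotation
#' @param seed integer seed
#' @return list with \code{truths} (named list of \code{ParcelTruth}) and
#'   \code{planted} (data.frame: parcel_id, year, season_class, crop,
#'   planting_day, sos_true, eos_true, peak_lai)
#' @export
simulateScenario <- function(nParcels = 8, years = 2,
                             calendar = nileDeltaCalendar(),
                             doubleFrac = 0.6, seed = 1) {
  .withSeed(seed, {
    summerCrops <- c("rice", "maize"); winterCrops <- c("wheat", "clover")
    truths <- list(); planted <- list()
    for (p in seq_len(nParcels)) {
      pid <- sprintf("P%03d", p)
      isDouble <- stats::runif(1) < doubleFrac
      seasons <- list()
      for (y in seq_len(years) - 1L) {
        crops <- if (isDouble) c(sample(summerCrops, 1), sample(winterCrops, 1))
                 else sample(c(summerCrops, winterCrops), 1)
        for (cr in crops) {
          s <- laiTruthCurve(cr, y, calendar,
                             seed = sample.int(.Machine$integer.max / 2, 1))
          seasons[[length(seasons) + 1]] <- s
          cross <- truthCrossing(s, 0.30)
          planted[[length(planted) + 1]] <- data.frame(
            parcel_id = pid, year = y,
            season_class = if (cr %in% summerCrops) "summer" else "winter",
            crop = cr, planting_day = s$planting_day,
            sos_true = cross$sos, eos_true = cross$eos,
            peak_lai = s$peak_lai, stringsAsFactors = FALSE)
        }
      }
      truths[[pid]] <- parcelTruth(seasons)
    }
    list(truths = truths, planted = do.call(rbind, planted))
  })
}

#' Render a raster scene stack from parcel truths
#'
#' Lays rectangular parcels on a pixel grid; pixels inside a parcel carry that
#' parcel's sampled series (noise applied at parcel level by default, so the
#' pixel average reproduces the parcel series); background pixels sit at a low
#' constant LAI below the vegetation-mask threshold.
#'
#' @param truths named list of \code{ParcelTruth} (names = parcel ids)
#' @param schedule an \code{\link{acquisitionSchedule}}
#' @param t0,t1 observation window (days since epoch)
#' @param gridDim c(rows, cols); must be large enough for the parcel layout
#' @param noise_sd observation noise SD
#' @param noise_level "parcel" (one draw shared by a parcel's pixels) or
#'   "pixel" (independent per pixel)
#' @param background_lai constant background LAI (default 0.1)
#' @param seed integer seed
#' @return list: \code{stack} (a \linkS4class{SceneStack}), \code{truth}
#'   (data.frame of per-parcel truth season counts and crossings)
#' @export
renderScene <- function(truths, schedule, t0, t1, gridDim = c(12, 12),
                        noise_sd = 0, noise_level = c("parcel", "pixel"),
                        background_lai = 0.1, seed = 1) {
  noise_level <- match.arg(noise_level)
  if (any(gridDim < 1)) stop("zero-area grid")
  nP <- length(truths)
  pids <- names(truths)
  # tile parcels as equal rectangles over the top rows of the grid
  perRow <- ceiling(sqrt(nP))
  # keep at least one background row and column for the vegetation mask
  ph <- max(1L, (gridDim[1] - 1L) %/% perRow)
  pw <- max(1L, (gridDim[2] - 1L) %/% perRow)
  if (perRow * ph >= gridDim[1] || perRow * pw >= gridDim[2])
    stop("grid too small for ", nP, " parcels")
  parcelMap <- matrix(0L, gridDim[1], gridDim[2])
  for (p in seq_len(nP)) {
    r0 <- ((p - 1) %/% perRow) * ph; c0 <- ((p - 1) %% perRow) * pw
    parcelMap[r0 + seq_len(ph), c0 + seq_len(pw)] <- p
  }
  d <- scheduleDates(schedule, t0, t1, seed)
  if (length(d) == 0) stop("schedule produced no acquisition dates")
  lai <- array(background_lai, dim = c(gridDim[1], gridDim[2], length(d)))
  truthRows <- list()
  for (p in seq_len(nP)) {
    tr <- truths[[p]]
    v <- tr$curve(d)
    if (noise_sd > 0 && noise_level == "parcel")
      v <- v + .withSeed(seed + p, stats::rnorm(length(d), 0, noise_sd))
    idx <- which(parcelMap == p, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      vp <- v
      if (noise_sd > 0 && noise_level == "pixel")
        vp <- v + .withSeed(seed + p * 1000L + k, stats::rnorm(length(d), 0, noise_sd))
      lai[idx[k, 1], idx[k, 2], ] <- pmax(vp, 0)
    }
    for (s in tr$seasons) {
      cross <- truthCrossing(s, 0.30)
      truthRows[[length(truthRows) + 1]] <- data.frame(
        parcel_id = pids[p], crop = s$crop, year = s$year,
        sos_true = cross$sos, eos_true = cross$eos,
        peak_lai = s$peak_lai, stringsAsFactors = FALSE)
    }
  }
  stack <- new("SceneStack", lai = lai, times = d,
               sensor = rep(schedule$sensor, length(d)),
               parcelMap = parcelMap, parcelIds = pids)
  list(stack = stack, truth = do.call(rbind, truthRows))
}

# band-set definitions (center wavelengths, nm)
.BAND_SETS <- list(
  "S2-10band" = list(
    names = c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12"),
    wavelengths = c(490, 560, 665, 705, 740, 783, 842, 865, 1610, 2190)),
  "L8-6band" = list(
    names = c("B2", "B3", "B4", "B5", "B6", "B7"),
    wavelengths = c(480, 560, 655, 865, 1610, 2200)))

# columns of the 10-band dialect matching the 6 shared L8 bands
.S2_TO_L8 <- c(1L, 2L, 3L, 8L, 9L, 10L)

#' Band-set description
#'
#' @param dialect "S2-10band" or "L8-6band"
#' @return list with \code{dialect}, \code{names}, \code{wavelengths}
#' @export
bandSet <- function(dialect = c("S2-10band", "L8-6band")) {
  dialect <- match.arg(dialect)
  c(list(dialect = dialect), .BAND_SETS[[dialect]])
}

# Monotone saturating forward model: reflectance_b(LAI) =
# r_inf + (r0 - r_inf) * exp(-k * LAI). Visible bands darken with LAI,
# NIR brightens, SWIR darkens; parameters fixed per band so retrieval
# parameter recovery is well-posed (NIR is exactly invertible at zero noise).
.forwardParams <- function(dialect) {
  ws <- .BAND_SETS[[dialect]]$wavelengths
  r0 <- ifelse(ws < 700, 0.12, ifelse(ws < 1000, 0.18, 0.30))
  rinf <- ifelse(ws < 700, 0.03, ifelse(ws < 1000, 0.55, 0.10))
  k <- ifelse(ws < 700, 0.9, ifelse(ws < 1000, 0.55, 0.7))
  list(r0 = r0, rinf = rinf, k = k)
}

#' Forward-model reflectance spectra from LAI
#'
#' @param lai numeric LAI vector
#' @param dialect band dialect
#' @return matrix (length(lai) x nbands) of reflectances
#' @export
laiToReflectance <- function(lai, dialect = "S2-10band") {
  if (!dialect %in% names(.BAND_SETS)) stop("unknown band_set '", dialect, "'")
  p <- .forwardParams(dialect)
  R <- matrix(0, length(lai), length(p$r0))
  for (b in seq_along(p$r0))
    R[, b] <- p$rinf[b] + (p$r0[b] - p$rinf[b]) * exp(-p$k[b] * lai)
  colnames(R) <- .BAND_SETS[[dialect]]$names
  R
}

#' Generate paired spectra-LAI training data
#'
#' LAI drawn uniformly on [0, 6], pushed through the fixed monotone forward
#' model per band, plus Gaussian reflectance noise.
#'
#' @param n number of pairs (>= 10)
#' @param dialect "S2-10band" or "L8-6band"
#' @param noise_sd reflectance noise SD
#' @param seed integer seed
#' @return list with \code{reflectance} (n x nbands matrix, named columns) and
#'   \code{lai} (length-n vector)
#' @export
spectraLaiPairs <- function(n = 218, dialect = "S2-10band", noise_sd = 0.01,
                            seed = 1) {
  if (n < 10) stop("need n >= 10 training pairs")
  if (!dialect %in% names(.BAND_SETS)) stop("unknown band_set '", dialect, "'")
  .withSeed(seed, {
    lai <- stats::runif(n, 0, 6)
    R <- laiToReflectance(lai, dialect)
    if (noise_sd > 0) R <- R + matrix(stats::rnorm(length(R), 0, noise_sd), nrow = n)
    colnames(R) <- .BAND_SETS[[dialect]]$names
    list(reflectance = R, lai = lai, dialect = dialect)
  })
}
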