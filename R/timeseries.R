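#' Time-series collection construction
#'
#' Builds the four analysis collections from two single-sensor LAI streams:
#' \itemize{
#'   \item \code{S30}, \code{L30}: each sensor's series, Savitzky-Golay
#'     smoothed;
#'   \item \code{SL30_SG}: the two streams merged by date union, then
#'     SG-smoothed;
#'   \item \code{SL30_GPR}: the merged stream gap-filled with a 1-D GPR onto a
#'     regular 10-day grid, with predictive uncertainty.
#' }
#'
#' @name lai-collections
NULL

#' Spatially average a scene stack over one parcel
#'
#' Per-date mean over the pixels belonging to the parcel; dates where every
#' pixel is NA are dropped.
#'
#' @param stack a \linkS4class{SceneStack}
#' @param parcel parcel id (name) or integer index into the parcel map
#' @return A \linkS4class{SampledSeries}
#' @export
parcelAverage <- function(stack, parcel) {
  p <- if (is.character(parcel)) match(parcel, stack@parcelIds) else parcel
  pid <- if (is.character(parcel)) parcel else stack@parcelIds[parcel]
  if (is.na(p) || !any(stack@parcelMap == p))
    stop("no pixels belong to parcel '", parcel, "'")
  idx <- which(stack@parcelMap == p, arr.ind = TRUE)
  vals <- vapply(seq_along(stack@times), function(k) {
    v <- stack@lai[cbind(idx, k)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  keep <- !is.na(vals)
  sampledSeries(stack@times[keep], vals[keep], sensor = stack@sensor[keep],
                parcelId = pid)
}

#' Merge two sensor streams into one series
#'
#' Union of acquisition dates sorted ascending; observations falling on the
#' same day (within \code{tol}) are averaged and tagged \code{"both"}.
#' Commutative and idempotent.
#'
#' @param a,b \linkS4class{SampledSeries} for the same parcel
#' @param tol coincidence tolerance in days (default 0.5)
#' @return merged \linkS4class{SampledSeries}
#' @export
mergeStreams <- function(a, b, tol = 0.5) {
  if (a@parcelId != b@parcelId)
    stop("cannot merge series of different parcels: '", a@parcelId,
         "' vs '", b@parcelId, "'")
  if (length(b) == 0) return(a)
  if (length(a) == 0) return(b)
  t <- c(a@times, b@times); v <- c(a@values, b@values)
  s <- c(a@sensor, b@sensor); e <- c(a@sd, b@sd)
  o <- order(t); t <- t[o]; v <- v[o]; s <- s[o]; e <- e[o]
  # collapse runs of near-coincident dates
  grp <- cumsum(c(TRUE, diff(t) > tol))
  tm <- tapply(t, grp, mean); vm <- tapply(v, grp, mean)
  em <- tapply(e, grp, function(z) if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
  sm <- tapply(s, grp, function(z) {
    u <- unique(z); if (length(u) == 1) u else "both"
  })
  sampledSeries(as.numeric(tm), as.numeric(vm), sd = as.numeric(em),
                sensor = as.character(sm), parcelId = a@parcelId)
}

#' Savitzky-Golay configuration
#'
#' @param span odd window length in observations (default 7)
#' @param degree polynomial order (default 2); must be < span
#' @return list of class \code{SGConfig}
#' @export
sgConfig <- function(span = 7, degree = 2) {
  if (span %% 2 != 1) stop("span must be odd")
  if (span <= degree) stop("span must exceed the polynomial degree")
  structure(list(span = span, degree = degree), class = "SGConfig")
}

#' Savitzky-Golay smoothing of an irregular series
#'
#' Each value is replaced by the value at its own date of the least-squares
#' polynomial of order \code{degree} fitted over a window of \code{span}
#' consecutive observations centered on it. The window is counted in
#' observations (not days), which is the natural reading for unevenly spaced
#' acquisitions; the fit itself uses the actual time coordinate. At the series
#' ends the window shrinks symmetrically to the largest odd span that fits
#' (never below \code{degree + 1}). Dates are unchanged.
#'
#' @param series a \linkS4class{SampledSeries}
#' @param cfg an \code{\link{sgConfig}}
#' @return smoothed \linkS4class{SampledSeries}
#' @export
savgolSmooth <- function(series, cfg = sgConfig()) {
  n <- length(series)
  if (n < cfg$degree + 1)
    stop("series of length ", n, " too short for degree-", cfg$degree, " fit")
  t <- series@times; v <- series@values
  out <- numeric(n)
  half <- (cfg$span - 1) %/% 2
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)            # symmetric shrink at edges
    while (2 * h + 1 < cfg$degree + 1) h <- h + 1   # keep fit determined
    lo <- max(1, i - h); hi <- min(n, i + h)
    tw <- t[lo:hi] - t[i]; vw <- v[lo:hi]
    X <- outer(tw, 0:cfg$degree, "^")
    beta <- qr.coef(qr(X), vw)
    out[i] <- beta[1]
  }
  sampledSeries(t, out, sd = series@sd, sensor = series@sensor,
                parcelId = series@parcelId)
}

#' GPR gap-filling onto a regular grid
#'
#' Fits a 1-D GPR (time-domain squared-exponential kernel) to the series and
#' predicts mean and standard deviation on a regular grid of spacing
#' \code{gridSpacing} days starting at the first observation and covering the
#' observed range.
#'
#' @param series a \linkS4class{SampledSeries} of length >= 5
#' @param gridSpacing grid step in days (default 10)
#' @param seed seed for the hyperparameter restarts
#' @return A \linkS4class{SampledSeries} on the regular grid, with predictive
#'   sd filled in and sensor tag \code{"gpr"}.
#' @export
gprGapfill <- function(series, gridSpacing = 10, seed = 1) {
  n <- length(series)
  if (n < 5) stop("need at least 5 observations to gap-fill (parcel '",
                  series@parcelId, "')")
  m <- tryCatch(
    fitGPR(matrix(series@times, ncol = 1), series@values, seed = seed),
    error = function(e) stop("GPR gap-fill failed for parcel '",
                             series@parcelId, "': ", conditionMessage(e)))
  grid <- seq(series@times[1], series@times[n], by = gridSpacing)
  pr <- gprPredict(m, matrix(grid, ncol = 1))
  sampledSeries(grid, pmax(pr$mean, 0), sd = sqrt(pr$variance),
                sensor = "gpr", parcelId = series@parcelId)
}

#' Build the four analysis collections for one parcel
#'
#' @param s2 the dense-revisit sensor series
#' @param l8 the sparse-revisit sensor series
#' @param sg an \code{\link{sgConfig}}
#' @param gridSpacing GPR gap-fill grid spacing in days
#' @param seed seed for the GPR fit
#' @return named list of \linkS4class{SampledSeries}: \code{S30}, \code{L30},
#'   \code{SL30_SG}, \code{SL30_GPR}
#' @export
buildCollections <- function(s2, l8, sg = sgConfig(), gridSpacing = 10, seed = 1) {
  if (length(s2) == 0 || length(l8) == 0) stop("both input streams must be non-empty")
  merged <- mergeStreams(s2, l8)
  list(S30 = savgolSmooth(s2, sg),
       L30 = savgolSmooth(l8, sg),
       SL30_SG = savgolSmooth(merged, sg),
       SL30_GPR = gprGapfill(merged, gridSpacing = gridSpacing, seed = seed))
}
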