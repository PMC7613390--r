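# Shared fixtures: all synthetic, built in code at test time.

# A deterministic double-cropping parcel truth (rice summer + wheat winter,
# fixed peak LAIs, no jitter), over `years` simulated years.
cleanDoubleTruth <- function(years = 1, cal = nileDeltaCalendar()) {
  seasons <- list()
  for (y in seq_len(years) - 1L) {
    seasons[[length(seasons) + 1]] <- laiTruthCurve("rice", y, cal,
      params = list(peak_lai = 4.5))
    seasons[[length(seasons) + 1]] <- laiTruthCurve("wheat", y, cal,
      params = list(peak_lai = 5.0))
  }
  parcelTruth(seasons)
}

# Symmetric triangular series: min `lo`, peak `hi`, rising over [t0, t0+w/2],
# falling to t0+w, padded flat at `lo` on both sides.
triangleSeries <- function(lo = 0, hi = 2, t0 = 100, w = 100, step = 5,
                           pad = 50) {
  t <- seq(t0 - pad, t0 + w + pad, by = step)
  up <- t0 + w / 2
  v <- ifelse(t <= t0 | t >= t0 + w, lo,
              ifelse(t <= up, lo + (hi - lo) * (t - t0) / (w / 2),
                     lo + (hi - lo) * (t0 + w - t) / (w / 2)))
  sampledSeries(t, v, parcelId = "tri")
}

# Dense-grid oracle for an amplitude-crossing day of an arbitrary curve:
# scan at 0.01-day resolution, return first up-crossing and last down-crossing.
denseCrossings <- function(curveFn, level, t0, t1) {
  tt <- seq(t0, t1, by = 0.01)
  v <- curveFn(tt)
  above <- v >= level
  up <- which(!above[-length(above)] & above[-1])
  dn <- which(above[-length(above)] & !above[-1])
  list(up = if (length(up)) tt[up[1] + 1] else NA_real_,
       dn = if (length(dn)) tt[dn[length(dn)]] else NA_real_)
}
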