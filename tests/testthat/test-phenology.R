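cal <- nileDeltaCalendar()

test_that("peak screening applies prominence and minimum-separation rules", {
  # strictly constant series: no peaks
  flat <- sampledSeries(seq(0, 200, 10), rep(1, 21), parcelId = "p")
  expect_equal(nrow(findSeasons(flat)), 0)

  # two peaks 60 days apart (< 90), heights 3 and 4: only the higher kept
  t <- seq(0, 200, 10)
  v <- 0.2 + 3 * exp(-((t - 70) / 18)^2) + 4 * exp(-((t - 130) / 18)^2)
  pk <- findSeasons(sampledSeries(t, v, parcelId = "p"),
                    detectionConfig(min_separation = 90))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$t_peak, 130)

  # equal heights within the separation window: the earlier peak wins
  v2 <- 0.2 + 3 * exp(-((t - 70) / 18)^2) + 3 * exp(-((t - 130) / 18)^2)
  pk2 <- findSeasons(sampledSeries(t, v2, parcelId = "p"),
                     detectionConfig(min_separation = 90))
  expect_equal(pk2$t_peak, 70)

  # endpoint maxima are not seasons
  rising <- sampledSeries(t, t / 50, parcelId = "p")
  expect_equal(nrow(findSeasons(rising)), 0)
})

test_that("double-cropping detection agrees with an exhaustive scan oracle", {
  truth <- cleanDoubleTruth(2)
  sched <- acquisitionSchedule("S2", 5, 0, 0)
  s <- sampleSeries(truth, sched, 0, 930, seed = 1, parcelId = "p")
  cfg <- detectionConfig()
  pk <- findSeasons(s, cfg)
  expect_equal(nrow(pk), 4)   # 2 crops x 2 years

  # oracle: enumerate every local maximum, apply both rules exhaustively
  t <- seriesTimes(s); v <- seriesValues(s)
  locmax <- which(diff(sign(diff(v))) < 0) + 1
  rng <- max(v) - min(v)
  prom <- vapply(locmax, function(i) {
    l <- if (i > 1) min(v[max(which(v[1:(i - 1)] > v[i]), 1):i]) else v[i]
    r <- if (i < length(v))
      min(v[i:min(c(which(v > v[i] & seq_along(v) > i), length(v)))]) else v[i]
    v[i] - max(l, r)
  }, numeric(1))
  cand <- locmax[prom >= cfg$prominence_frac * rng]
  keep <- c()
  for (i in cand[order(-v[cand])])
    if (!any(abs(t[keep] - t[i]) < cfg$min_separation)) keep <- c(keep, i)
  expect_setequal(pk$t_peak, t[sort(keep)])
})

test_that("seasonal threshold on a triangle gives similar-triangles SOS/EOS", {
  s <- triangleSeries(lo = 0, hi = 2, t0 = 100, w = 100)
  pk <- findSeasons(s, detectionConfig())
  seas <- seasonalThreshold(s, pk, detectionConfig(amplitude_frac = 0.30))
  expect_equal(nrow(seas), 1)
  # rise covers 50 days; 0.6 LAI is 30% up it -> SOS at 115, EOS at 185
  expect_equal(seas$sos, 115, tolerance = 1e-8)
  expect_equal(seas$eos, 185, tolerance = 1e-8)
  expect_equal(seas$los, 70, tolerance = 1e-8)
})

test_that("SOS tracks the dense-grid truth crossing on a smooth season", {
  truth <- cleanDoubleTruth(1)
  rice <- truth$seasons[[1]]
  s <- sampleSeries(truth, acquisitionSchedule("S2", 10, 0, 0), 0, 500,
                    seed = 2, parcelId = "p")
  seas <- seasonalThreshold(s, findSeasons(s), detectionConfig())
  riceSeas <- seas[which.min(abs(seas$t_peak - rice$t_peak)), ]
  expect_lt(abs(riceSeas$sos - truthCrossing(rice, 0.30)$sos), 5)
})

test_that("incomplete trailing seasons are excluded", {
  truth <- cleanDoubleTruth(1)
  # stop sampling at day 400: wheat (EOS ~ day 477) cannot complete
  s <- sampleSeries(truth, acquisitionSchedule("S2", 5, 0, 0), 0, 400,
                    seed = 3, parcelId = "p")
  seas <- seasonalThreshold(s, findSeasons(s), detectionConfig())
  expect_equal(nrow(seas), 1)
  expect_lt(abs(seas$t_peak - truth$seasons[[1]]$t_peak), 20)
})

test_that("relative threshold coincides with seasonal on equal amplitudes and drops weak seasons", {
  # two identical seasons -> methods agree
  t <- seq(0, 400, 5)
  v <- 0.2 + 3 * exp(-((t - 100) / 25)^2) + 3 * exp(-((t - 300) / 25)^2)
  s <- sampledSeries(t, v, parcelId = "p")
  cfg <- detectionConfig()
  pk <- findSeasons(s, cfg)
  a <- seasonalThreshold(s, pk, cfg); b <- relativeThreshold(s, pk, cfg)
  expect_equal(a$sos, b$sos, tolerance = 1e-9)
  expect_equal(a$eos, b$eos, tolerance = 1e-9)

  # single season -> both methods agree too
  v1 <- 0.2 + 3 * exp(-((t - 200) / 25)^2)
  s1 <- sampledSeries(t, v1, parcelId = "p")
  pk1 <- findSeasons(s1, cfg)
  a1 <- seasonalThreshold(s1, pk1, cfg); b1 <- relativeThreshold(s1, pk1, cfg)
  expect_equal(a1$sos, b1$sos, tolerance = 1e-9)

  # strongly unequal amplitudes (1 vs 6): the weak season's curve never
  # reaches the fixed relative level, so the relative method misses it
  vU <- 0.2 + 1 * exp(-((t - 100) / 25)^2) + 6 * exp(-((t - 300) / 25)^2)
  sU <- sampledSeries(t, vU, parcelId = "p")
  cfgU <- detectionConfig(prominence_frac = 0.1)
  pkU <- findSeasons(sU, cfgU)
  expect_equal(nrow(pkU), 2)
  aU <- seasonalThreshold(sU, pkU, cfgU)
  bU <- relativeThreshold(sU, pkU, cfgU)
  expect_lt(nrow(bU), nrow(aU))
  # dense verification: the weak peak (1.2) sits below min + 0.3 * relAmp
  relAmp <- mean(c(1.2, 6.2)) - 0.2
  expect_lt(1.2, 0.2 + 0.30 * relAmp)
})

test_that("LOS and Area follow the stated conventions", {
  # winter wrap: printed mean SOS 294, EOS 110 next year -> LOS 181
  expect_equal(losFromDoys(294, 110), 181)
  expect_equal(losFromDoys(100, 180), 80)

  # triangular season, SOS/EOS at the base: area = 1/2 * base * height
  s <- triangleSeries(lo = 0, hi = 2, t0 = 100, w = 100)
  seas <- data.frame(sos = 100, eos = 200)
  out <- seasonMetrics(seas, s)
  expect_equal(out$area, 100, tolerance = 1e-9)
  expect_equal(out$los, 100)

  # degenerate SOS = EOS
  z <- seasonMetrics(data.frame(sos = 120, eos = 120), s)
  expect_equal(z$los, 0); expect_equal(z$area, 0)
  expect_error(seasonMetrics(data.frame(sos = 120, eos = 100), s), "eos")
})

test_that("detected seasons are strictly ordered in time", {
  truth <- cleanDoubleTruth(2)
  s <- sampleSeries(truth, acquisitionSchedule("S2", 5, 1, 0.1), 0, 930,
                    noise_sd = 0.15, seed = 5, parcelId = "p")
  sm <- savgolSmooth(s)
  pk <- findSeasons(sm)
  seas <- seasonalThreshold(sm, pk, detectionConfig())
  for (j in seq_len(nrow(seas))) {
    i <- which.min(abs(pk$t_peak - seas$t_peak[j]))
    expect_lt(pk$left_min_t[i], seas$sos[j])
    expect_lt(seas$sos[j], seas$t_peak[j])
    expect_lt(seas$t_peak[j], seas$eos[j])
  }
})

test_that("lowering the amplitude threshold widens the season", {
  for (r in 1:20) {
    set.seed(200 + r)
    amp <- runif(1, 2, 5); width <- runif(1, 20, 35)
    t <- seq(0, 365, 5)
    v <- 0.2 + amp * exp(-((t - 180) / width)^2)
    s <- sampledSeries(t, v, parcelId = "p")
    pk <- findSeasons(s)
    lo <- seasonalThreshold(s, pk, detectionConfig(amplitude_frac = 0.15))
    hi <- seasonalThreshold(s, pk, detectionConfig(amplitude_frac = 0.30))
    expect_lt(lo$sos, hi$sos)
    expect_gt(lo$eos, hi$eos)
  }
})

test_that("crop assignment classes seasons and falls back to the calendar", {
  seas <- data.frame(parcel_id = "p", year = 0,
                     sos_doy = c(165, 300), sos = c(164, 299),
                     stringsAsFactors = FALSE)
  out <- assignCrop(seas, cal)
  expect_equal(out$season_class, c("summer", "winter"))
  # DOY 165: rice planted DOY 135 is the nearest preceding planting
  expect_equal(out$crop[1], "rice")
  # DOY 300: clover (DOY 274) precedes; wheat (314) has not been planted yet
  expect_equal(out$crop[2], "clover")

  # planted record takes precedence over the calendar rule
  planted <- data.frame(parcel_id = "p", year = 0, season_class = "summer",
                        crop = "maize", stringsAsFactors = FALSE)
  out2 <- assignCrop(seas, cal, planted)
  expect_equal(out2$crop, c("maize", "clover"))
})
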