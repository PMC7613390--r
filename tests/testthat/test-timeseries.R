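test_that("parcel averaging matches an explicit mask-and-mean loop", {
  truth <- list(A = cleanDoubleTruth(1), B = cleanDoubleTruth(1))
  sched <- acquisitionSchedule("S2", 10, gap_prob = 0)
  sc <- renderScene(truth, sched, 0, 400, gridDim = c(10, 10),
                    noise_sd = 0.2, noise_level = "pixel", seed = 2)
  st <- sc$stack
  avg <- parcelAverage(st, "A")
  # oracle: loop over pixels flagged for parcel 1
  for (k in c(1, 10, 20)) {
    acc <- c()
    for (r in 1:10) for (cc in 1:10)
      if (st@parcelMap[r, cc] == 1) acc <- c(acc, st@lai[r, cc, k])
    expect_equal(seriesValues(avg)[k], mean(acc), tolerance = 1e-12)
  }
  expect_error(parcelAverage(st, "Z"), "Z")
})

test_that("parcel averaging degenerate cases: single pixel and constant offset", {
  st <- new("SceneStack",
            lai = array(c(1, 3, 1.5, 3.5, 2, 4), dim = c(2, 1, 3)),
            times = c(0, 10, 20), sensor = rep("S2", 3),
            parcelMap = matrix(c(1L, 2L), 2, 1), parcelIds = c("a", "b"))
  expect_equal(seriesValues(parcelAverage(st, "a")), c(1, 1.5, 2))
  # two pixels v and v+2 in one parcel -> mean v+1
  st2 <- new("SceneStack",
             lai = array(c(1, 3, 1.5, 3.5, 2, 4), dim = c(2, 1, 3)),
             times = c(0, 10, 20), sensor = rep("S2", 3),
             parcelMap = matrix(c(1L, 1L), 2, 1), parcelIds = "a")
  expect_equal(seriesValues(parcelAverage(st2, "a")), c(2, 2.5, 3))
})

test_that("stream merging is a sorted union with same-day averaging", {
  a <- sampledSeries(seq(0, 90, 10), 1:10, sensor = "S2", parcelId = "p")
  b <- sampledSeries(seq(3, 63, 10), 2:8, sensor = "L8", parcelId = "p")
  m <- mergeStreams(a, b)
  expect_equal(length(m), 17)                   # disjoint 10 + 7
  expect_true(all(diff(seriesTimes(m)) > 0))

  empty <- sampledSeries(numeric(0), numeric(0), sensor = character(0),
                         parcelId = "p")
  expect_equal(seriesValues(mergeStreams(a, empty)), seriesValues(a))

  # same-day coincidence averages and tags "both"
  c2 <- sampledSeries(c(0, 20), c(3, 5), sensor = "L8", parcelId = "p")
  mc <- mergeStreams(a, c2)
  expect_equal(seriesValues(mc)[1], mean(c(1, 3)))
  expect_equal(seriesSensor(mc)[1], "both")

  expect_error(mergeStreams(a, sampledSeries(1, 1, parcelId = "q")), "parcel")

  # commutative; idempotent on its own output
  m2 <- mergeStreams(b, a)
  expect_equal(seriesTimes(m), seriesTimes(m2))
  expect_equal(seriesValues(m), seriesValues(m2))
  mm <- mergeStreams(m, m)
  expect_equal(seriesTimes(mm), seriesTimes(m))
  expect_equal(seriesValues(mm), seriesValues(m))
})

test_that("merged noiseless streams lie on the truth curve", {
  truth <- cleanDoubleTruth(1)
  sA <- sampleSeries(truth, acquisitionSchedule("S2", 5, 1, 0), 0, 400,
                     seed = 4, parcelId = "p")
  sB <- sampleSeries(truth, acquisitionSchedule("L8", 16, 1, 0), 0, 400,
                     seed = 5, parcelId = "p")
  m <- mergeStreams(sA, sB)
  # merged points at unshared dates equal the truth; coincident days averaged
  # from the same curve also equal the truth at the averaged date (within the
  # curve's variation across the sub-day tolerance window)
  expect_equal(seriesValues(m), truth$curve(seriesTimes(m)), tolerance = 0.02)
})

test_that("SG filter reproduces polynomials and matches a direct LSQ oracle", {
  # degree-2 filter leaves quadratics (in time) unchanged, constants trivially
  t <- seq(0, 70, 5)
  quad <- sampledSeries(t, 0.3 + 0.1 * t - 0.002 * t^2, parcelId = "p")
  sm <- savgolSmooth(quad, sgConfig(7, 2))
  expect_equal(seriesValues(sm), seriesValues(quad), tolerance = 1e-10)

  const <- sampledSeries(t, rep(2, length(t)), parcelId = "p")
  expect_equal(seriesValues(savgolSmooth(const)), rep(2, length(t)))

  # interior point of a random irregular 15-point series: explicit LSQ oracle
  set.seed(6)
  ti <- sort(runif(15, 0, 150)); vi <- runif(15, 0, 4)
  s <- sampledSeries(ti, vi, parcelId = "p")
  out <- savgolSmooth(s, sgConfig(7, 2))
  i <- 8
  w <- (i - 3):(i + 3)
  fit <- lm(vi[w] ~ poly(ti[w], 2, raw = TRUE))
  oracle <- sum(coef(fit) * ti[i]^(0:2))
  expect_equal(seriesValues(out)[i], oracle, tolerance = 1e-10)

  expect_error(savgolSmooth(sampledSeries(c(0, 1), c(1, 2), parcelId = "p"),
                            sgConfig(7, 2)), "short")
})

test_that("SG filter agrees with signal::sgolayfilt on evenly spaced interiors", {
  skip_if_not_installed("signal")
  t <- seq(0, 200, 5)
  set.seed(7)
  v <- 2 + sin(t / 20) + rnorm(length(t), 0, 0.1)
  out <- savgolSmooth(sampledSeries(t, v, parcelId = "p"), sgConfig(7, 2))
  ref <- signal::sgolayfilt(v, p = 2, n = 7)
  interior <- 4:(length(t) - 3)
  expect_equal(seriesValues(out)[interior], ref[interior], tolerance = 1e-8)
})

test_that("SG smoothing does not increase the error of noisy series", {
  truth <- cleanDoubleTruth(1)
  sched <- acquisitionSchedule("S2", 5, 1, 0.1)
  improved <- 0
  for (r in 1:20) {
    s <- sampleSeries(truth, sched, 0, 500, noise_sd = 0.25, seed = 100 + r,
                      parcelId = "p")
    tv <- truth$curve(seriesTimes(s))
    mseRaw <- mean((seriesValues(s) - tv)^2)
    mseSm <- mean((seriesValues(savgolSmooth(s)) - tv)^2)
    if (mseSm <= mseRaw) improved <- improved + 1
  }
  expect_equal(improved, 20)
})

test_that("GPR gap-fill reconstructs gaps and inflates uncertainty inside them", {
  # noiseless sinusoid, period 200 days, 10-day sampling with a 40-day gap
  t <- seq(0, 400, 10)
  gap <- t > 180 & t < 220
  tg <- t[!gap]
  s <- sampledSeries(tg, 2 + sin(2 * pi * tg / 200), parcelId = "p")
  out <- gprGapfill(s, gridSpacing = 10, seed = 8)
  gt <- seriesTimes(out)
  expect_equal(diff(gt), rep(10, length(gt) - 1))
  inGap <- gt > 180 & gt < 220
  err <- abs(seriesValues(out)[inGap] - (2 + sin(2 * pi * gt[inGap] / 200)))
  expect_lt(max(err), 0.05)   # < 5% of unit amplitude

  # interpolation regime: predictions at observation dates track observations
  atObs <- seriesValues(out)[match(tg[tg %% 10 == 0], gt)]
  expect_lt(max(abs(atObs - seriesValues(s)[tg %% 10 == 0])), 1e-3)

  # a 60-day gap carries more predictive sd than observed dates
  gap2 <- t > 160 & t < 220
  s2 <- sampledSeries(t[!gap2], 2 + sin(2 * pi * t[!gap2] / 200), parcelId = "p")
  out2 <- gprGapfill(s2, gridSpacing = 10, seed = 8)
  g2 <- seriesTimes(out2)
  sdGap <- max(seriesSd(out2)[g2 > 160 & g2 < 220])
  sdObs <- median(seriesSd(out2)[g2 <= 160 | g2 >= 220])
  expect_gt(sdGap, sdObs)

  expect_error(gprGapfill(sampledSeries(1:3, 1:3, parcelId = "p")), "at least 5")
})

test_that("the four collections are built consistently", {
  truth <- cleanDoubleTruth(2)
  s2 <- sampleSeries(truth, acquisitionSchedule("S2", 5, 1, 0.1), 0, 930,
                     noise_sd = 0.1, seed = 9, parcelId = "p")
  l8 <- sampleSeries(truth, acquisitionSchedule("L8", 16, 1, 0.1), 0, 930,
                     noise_sd = 0.1, seed = 10, parcelId = "p")
  coll <- buildCollections(s2, l8, seed = 11)
  expect_named(coll, c("S30", "L30", "SL30_SG", "SL30_GPR"))
  expect_equal(diff(seriesTimes(coll$SL30_GPR)),
               rep(10, length(coll$SL30_GPR) - 1))

  # identical inputs: SL30_SG equals S30 (merging identical values averages
  # them back onto the same dates)
  collSame <- buildCollections(s2, s2, seed = 11)
  expect_equal(seriesValues(collSame$SL30_SG), seriesValues(collSame$S30),
               tolerance = 1e-10)

  # all four collections agree on the season count of a clean 2-year truth
  counts <- vapply(coll, function(s)
    nrow(findSeasons(s, detectionConfig())), numeric(1))
  expect_true(all(counts == 4))
})
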