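test_that("rupture extraction recovers a planted tether event", {
  cv <- simulateRetractionCurve(ruptureForce = 120, ruptureLength = 80,
                                springConstant = 0.05, noiseSd = 0)
  ev <- extractRupture(getSegment(cv, "retract"), 0.05, minForce = 20,
                       curveId = "c1")
  expect_equal(ev$ruptureForce, 120, tolerance = 1e-2)
  expect_equal(ev$ruptureLength, 80, tolerance = 1e-2)
  expect_identical(ev$curveId, "c1")
})

test_that("noise-only retractions yield no event; uncorrected baselines error", {
  cv <- simulateRetractionCurve(ruptureForce = NULL, noiseSd = 5,
                                nSamples = 600, pullRange = 500, seed = 5)
  expect_null(extractRupture(getSegment(cv, "retract"), 0.05, minForce = 20))

  seg <- flatSegment(n = 200, offset = 40, label = "retract")
  expect_error(extractRupture(seg, 0.05), "baseline")
})

test_that("with two dips the global force minimum defines the event", {
  # construct in the piezo domain: minima placed so the separations at the
  # dips are exactly 30 nm (-60 pN) and 90 nm (-140 pN); brute-force min
  # over samples is the oracle
  kpn <- 50
  z <- seq(1000, 800, by = -0.4)
  pull <- 1000 - z
  f <- rep(0, length(z))
  dip <- function(f, centrePull, depth, halfWidthSamples = 10) {
    ic <- which.min(abs(pull - centrePull))
    for (o in -halfWidthSamples:halfWidthSamples)
      f[ic + o] <- -depth * (1 - abs(o) / (halfWidthSamples + 1))
    f
  }
  f <- dip(f, 30 + 60 / kpn, 60)
  f <- dip(f, 90 + 140 / kpn, 140)
  seg <- FDSegment("retract", z, f)
  ev <- extractRupture(seg, 0.05, minForce = 20)
  iMin <- which.min(f)  # brute-force oracle
  expect_equal(ev$ruptureForce, -f[iMin])
  expect_equal(ev$ruptureForce, 140)
  expect_equal(ev$ruptureLength, 90, tolerance = 1e-9)
})

test_that("control thresholds are the medians of the negative-control distributions", {
  ctrl <- makeEvents(c(10, 20, 30, 40, 50), c(5, 15, 25, 35, 45),
                     probe = "anti_IgG")
  thr <- controlThresholds(ctrl)
  expect_equal(thr@forceThreshold, 30)
  expect_equal(thr@lengthThreshold, 25)

  ctrl2 <- makeEvents(c(10, 20), c(5, 15), probe = "anti_IgG")
  expect_equal(controlThresholds(ctrl2)@lengthThreshold, 10)  # even-n midpoint

  empty <- makeEvents(numeric(0), numeric(0), probe = "anti_IgG",
                      nCurvesTotal = 10)
  expect_error(controlThresholds(empty), "pool controls")
  expect_error(controlThresholds(makeEvents(10, 10, probe = "anti_FN")),
               "anti_IgG")
})

test_that("density maps are normalised histograms honouring the thresholds", {
  thr <- new("TetherThresholds", forceThreshold = 0, lengthThreshold = 0)
  grid <- list(lengthEdges = c(0, 50, 100), logForceEdges = c(0, 1.5, 3))
  # all four events in one bin
  es <- makeEvents(rep(10, 4), rep(25, 4))
  d <- densityMap(es, thr, grid)
  expect_equal(densityValues(d), matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(d@nEvents, 4L)

  # nothing retained -> all-zero grid
  thrHigh <- new("TetherThresholds", forceThreshold = 1e6, lengthThreshold = 0)
  d0 <- densityMap(es, thrHigh, grid)
  expect_equal(sum(densityValues(d0)), 0)
  expect_equal(d0@nEvents, 0L)

  # uniform sampling: per-bin density within binomial tolerance
  set.seed(99)
  n <- 1e4
  ev <- makeEvents(10^runif(n, 0, 3), runif(n, 0, 100))
  g10 <- list(lengthEdges = seq(0, 100, 10), logForceEdges = seq(0, 3, 0.3))
  du <- densityMap(ev, thr, g10)
  p <- 0.01
  expect_true(all(abs(densityValues(du) - p) <= 4 * sqrt(p * (1 - p) / n)))
  expect_equal(sum(densityValues(du)), 1, tolerance = 1e-12)
})

test_that("significance mask applies the smoothed density-ratio rule", {
  # identical sample and control densities: nothing significant
  cnt <- matrix(rpois(100, 5) + 1, 10, 10)
  g <- gridFromCounts(cnt)
  m <- significantMask(g, g)
  expect_false(any(maskValues(m)))

  # 3x3 block at 3x control density survives; matches the independent
  # majority-vote median-filter oracle applied to the raw ratio rule
  ctrlCnt <- matrix(20, 10, 10)
  sampCnt <- ctrlCnt
  sampCnt[4:6, 4:6] <- 60
  gs <- gridFromCounts(sampCnt); gc <- gridFromCounts(ctrlCnt)
  m2 <- significantMask(gs, gc, ratio = 2, kernelSize = 3)
  raw <- gs@density > 2 * (gc@density + 1 / gc@nEvents)
  expect_identical(maskValues(m2), medianFilterOracle(raw, 3))
  expect_true(all(maskValues(m2)[5, 5]))
  expect_false(any(maskValues(m2)[-(4:6), ]))

  # isolated single significant bin is removed by the median filter
  sampIso <- ctrlCnt; sampIso[2, 2] <- 200
  m3 <- significantMask(gridFromCounts(sampIso), gc)
  expect_false(any(maskValues(m3)))

  gBad <- gridFromCounts(matrix(1, 5, 5))
  expect_error(significantMask(gs, gBad), "congruent")
})

test_that("median filtering follows strict-majority voting with FALSE padding", {
  set.seed(7)
  for (k in c(3L, 5L)) {
    m <- matrix(runif(400) < 0.4, 20, 20)
    gs <- gridFromCounts(matrix(1, 20, 20))
    filt <- MechanoProbe:::.medianFilterBool(m, k)
    expect_identical(filt, medianFilterOracle(m, k))
  }
})

test_that("event classification equals per-event re-binning against the mask", {
  set.seed(21)
  ev <- makeEvents(10^runif(200, 1, 3), runif(200, 5, 120))
  thr <- new("TetherThresholds", forceThreshold = 30, lengthThreshold = 15)
  grid <- list(lengthEdges = seq(10, 110, length.out = 11),
               logForceEdges = seq(1.2, 2.8, length.out = 11))
  mask <- matrix(FALSE, 10, 10)
  mask[3:7, 4:9] <- TRUE
  sm <- new("SignificanceMask", mask = mask, kernelSize = 3L,
            lengthEdges = grid$lengthEdges, logForceEdges = grid$logForceEdges)
  got <- classifyEvents(ev, thr, sm)

  # brute-force oracle: loop every event, re-bin, look up the mask
  keep <- logical(0); nOut <- 0L
  for (i in seq_len(200)) {
    fo <- events(ev)$ruptureForce[i]; le <- events(ev)$ruptureLength[i]
    if (!(fo > 30 && le > 15)) next
    iL <- findInterval(le, grid$lengthEdges, rightmost.closed = TRUE)
    iF <- findInterval(log10(fo), grid$logForceEdges, rightmost.closed = TRUE)
    if (iL < 1 || iL > 10 || iF < 1 || iF > 10) { nOut <- nOut + 1L; next }
    keep <- c(keep, mask[iL, iF])
  }
  expect_equal(nrow(events(got)), sum(keep))
  expect_equal(attr(got, "nUnclassified"), nOut)

  # all-false and all-true masks
  smF <- new("SignificanceMask", mask = mask & FALSE, kernelSize = 3L,
             lengthEdges = grid$lengthEdges, logForceEdges = grid$logForceEdges)
  expect_equal(nrow(events(classifyEvents(ev, thr, smF))), 0L)
  smT <- new("SignificanceMask", mask = mask | TRUE, kernelSize = 3L,
             lengthEdges = grid$lengthEdges, logForceEdges = grid$logForceEdges)
  gotT <- classifyEvents(ev, thr, smT)
  retained <- sum(events(ev)$ruptureForce > 30 & events(ev)$ruptureLength > 15)
  expect_equal(nrow(events(gotT)) + attr(gotT, "nUnclassified"), retained)
})

test_that("tether summaries average per-sample log10 forces with SEM across samples", {
  mk <- function(meanLog, id) makeEvents(rep(10^meanLog, 3), rep(50, 3),
                                         sampleId = id)
  s <- summarizeTethering(list(mk(2.0, "a"), mk(2.2, "b"), mk(2.4, "c")))
  expect_equal(s$overallMean, 2.2)
  expect_equal(s$sem, 0.2 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$nSamples, 3L)
  expect_false(s$noSignificantBinding)

  one <- summarizeTethering(list(mk(2.1, "a")))
  expect_equal(one$sem, 0)
  expect_true(one$singleSample)

  emptySet <- makeEvents(numeric(0), numeric(0), nCurvesTotal = 5)
  none <- summarizeTethering(list(emptySet, emptySet))
  expect_true(none$noSignificantBinding)
  expect_true(is.na(none$overallMean))
})
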