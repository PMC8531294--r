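test_that("deflection-to-force conversion obeys Hooke's law with unit handling", {
  expect_equal(deflectionToForce(10, 0.05), 500)
  expect_equal(deflectionToForce(2.5, 0.2), 500)
  expect_equal(deflectionToForce(0, 0.3), 0)
  # sign preserved and linear: f(a*d) = a*f(d)
  d <- c(-5, -1, 0, 2, 7.5)
  expect_equal(deflectionToForce(3 * d, 0.04), 3 * deflectionToForce(d, 0.04))
  expect_equal(sign(deflectionToForce(d, 0.1)), sign(d))
  expect_error(deflectionToForce(NaN, 0.05), "finite")
  expect_error(deflectionToForce(1, -0.05), "positive")
})

test_that("segment and curve validity invariants are enforced", {
  expect_error(FDSegment("approach", c(0, 1), c(1, 2, 3)), "equal length")
  expect_error(FDSegment("approach", c(0, 2, 1), c(0, 0, 0)), "increasing")
  expect_error(FDSegment("retract", c(0, 1, 2), c(0, 0, 0)), "decreasing")
  expect_error(FDSegment("sideways", c(0, 1), c(0, 0)), "label")
  seg <- FDSegment("approach", c(0, 1, 2), c(0, 0, 1))
  expect_error(ForceCurve("c1", springConstant = -1, segments = list(seg)),
               "springConstant")
  expect_error(ForceCurve("c1", springConstant = 0.05,
                          segments = list(seg, seg)), "one segment per label")
  cv <- ForceCurve("c1", springConstant = 0.05, segments = list(seg))
  expect_s4_class(cv, "ForceCurve")
  expect_identical(getSegment(cv, "approach")@label, "approach")
  expect_error(getSegment(cv, "retract"), "no 'retract' segment")
})

test_that("baseline correction removes constant offsets and planted tilts", {
  # constant offset: fit-region mean exactly 0 afterwards
  seg <- flatSegment(n = 100, offset = 3)
  out <- baselineCorrect(seg)
  idx <- order(out$segment@piezoHeight)[1:30]
  expect_equal(mean(out$segment@force[idx]), 0, tolerance = 1e-12)
  expect_equal(out$model@intercept, 3)
  expect_equal(out$model@slope, 0, tolerance = 1e-15)

  # planted tilt + noise: recovered slope matches the least-squares oracle
  seg <- flatSegment(n = 400, offset = 10, slope = 0.02, noiseSd = 5, seed = 7)
  out <- baselineCorrect(seg, fitRegionFraction = 0.3)
  fitIdx <- order(seg@piezoHeight)[1:120]
  oracle <- lm(seg@force[fitIdx] ~ seg@piezoHeight[fitIdx])
  expect_equal(out$model@slope, unname(coef(oracle)[2]), tolerance = 1e-10)
  se <- summary(oracle)$coefficients[2, 2]
  expect_lt(abs(out$model@slope - 0.02), 3 * se)

  # idempotence: a second pass changes nothing beyond numerical tolerance
  out2 <- baselineCorrect(out$segment)
  expect_equal(out2$segment@force, out$segment@force, tolerance = 1e-9)
})

test_that("baseline correction rejects degenerate fit regions", {
  small <- FDSegment("approach", seq_len(5), rep(0, 5))
  expect_error(baselineCorrect(small, 0.6), "at least 10")
  expect_error(baselineCorrect(flatSegment(100), 0), "fitRegionFraction")
})

test_that("tip-sample separation implements the AFM contact geometry", {
  k <- 0.05
  # piezo advanced 100 nm past contact with 20 nm deflection -> delta = 80 nm
  seg <- FDSegment("approach", c(900, 950, 1100),
                   c(0, 0, deflectionToForce(20, k)))
  sep <- tipSampleSeparation(seg, k, contactPoint = 1000)
  expect_equal(sep[3], -80)  # negative separation = indentation depth

  # zero force everywhere: separation equals piezo displacement from the
  # closest-approach reference
  seg0 <- flatSegment(n = 50)
  expect_equal(tipSampleSeparation(seg0, k),
               max(seg0@piezoHeight) - seg0@piezoHeight)

  # generator round-trip: noise-free Hertz curve returns the exact
  # indentation array used by the forward model
  sc <- indentationScenario(E_true = 750, noiseSd = 0, nSamples = 200)
  cv <- simulateIndentationCurve(sc)
  seg <- getSegment(cv, "approach")
  sep <- tipSampleSeparation(seg, sc$springConstant,
                             contactPoint = sc$contactPoint)
  delta <- pmax(-sep, 0)
  trueDelta <- seq(0, sc$maxDelta, length.out = 100)
  expect_equal(delta[101:200], trueDelta, tolerance = 1e-9)
  expect_error(tipSampleSeparation(seg), "springConstant")
})

test_that("force-curve files round-trip losslessly through the TSV dialect", {
  sc <- indentationScenario(E_true = 750, noiseSd = 10, nSamples = 60, seed = 3)
  cv <- simulateIndentationCurve(sc, curveId = "rt1", sampleId = "gelA")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeForceCurve(cv, path)
  back <- readForceCurve(path)
  expect_identical(back@curveId, "rt1")
  expect_identical(back@sampleId, "gelA")
  expect_equal(back@springConstant, cv@springConstant)
  expect_equal(back@beadRadius, cv@beadRadius)
  s0 <- getSegment(cv, "approach"); s1 <- back@segments[[1]]
  expect_equal(s1@piezoHeight, s0@piezoHeight)
  expect_equal(s1@force, s0@force)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# curve_id=x", "# oops-no-equals-sign",
               "segment\tpiezo_height_nm\tforce_pN"), bad)
  expect_error(readForceCurve(bad), "line 2")
  expect_error(readForceCurve(file.path(tempdir(), "absent.tsv")), "not found")
})
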