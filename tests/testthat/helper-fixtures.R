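# Small fixture builders shared across test files.

# Flat approach segment at a constant force offset (plus optional tilt/noise),
# piezo heights strictly increasing.
flatSegment <- function(n = 100, offset = 0, slope = 0, noiseSd = 0,
                        label = "approach", seed = 42) {
  z <- seq(0, 1000, length.out = n)
  f <- offset + slope * z
  if (noiseSd > 0) { set.seed(seed); f <- f + rnorm(n, 0, noiseSd) }
  if (label == "retract") { z <- rev(z); f <- rev(f) }
  FDSegment(label, z, f)
}

# Event set built from bare force/length vectors.
makeEvents <- function(force, length, sampleId = "s1", probe = "anti_FN",
                       stiffnessClass = "soft", substrate = "sub",
                       specific = NULL, nCurvesTotal = NULL) {
  ev <- data.frame(curveId = sprintf("c%03d", seq_along(force)),
                   ruptureForce = force, ruptureLength = length)
  if (!is.null(specific)) ev$specific <- specific
  if (is.null(nCurvesTotal)) nCurvesTotal <- nrow(ev)
  EventSet(ev, sampleId = sampleId, probe = probe, substrate = substrate,
           stiffnessClass = stiffnessClass, nCurvesTotal = nCurvesTotal)
}

# Density grid with prescribed counts on a fixed unit grid.
gridFromCounts <- function(counts, nEvents = sum(counts)) {
  nL <- nrow(counts); nF <- ncol(counts)
  new("DensityGrid", lengthEdges = seq(0, nL, by = 1),
      logForceEdges = seq(0, nF, by = 1),
      density = if (sum(counts) > 0) counts / sum(counts) else counts * 0,
      nEvents = as.integer(nEvents))
}

# Independent majority-vote median filter used as an oracle against the
# implementation (explicit per-cell neighbourhood loop, FALSE outside).
medianFilterOracle <- function(m, k = 3L) {
  h <- (k - 1L) %/% 2L
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    votes <- 0L
    for (di in -h:h) for (dj in -h:h) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) && m[ii, jj])
        votes <- votes + 1L
    }
    out[i, j] <- votes > (k * k) %/% 2L
  }
  out
}

# Independent exhaustive Hertz contact-scan oracle: every sample as a
# candidate contact point, E by explicit origin-regression of force on
# delta^1.5, scored by full-segment RMS (zero before contact, fitted power
# law after, extrapolated beyond the fit window).
hertzScanOracle <- function(seg, springConstant, beadRadius,
                            poissonRatio = 0.5, maxIndentation = NULL,
                            minPts = 5L) {
  if (is.null(maxIndentation)) maxIndentation <- 0.1 * beadRadius * 1000
  z <- seg@piezoHeight; f <- seg@force; n <- length(z)
  defl <- f / (springConstant * 1000)
  unit <- (4 / 3) / (1 - poissonRatio^2) * sqrt(beadRadius * 1e-6) *
    (1e-9)^1.5 * 1e12
  bestRms <- Inf; bestE <- NA_real_; bestZc <- NA_real_
  for (i in seq_len(n)) {
    zc <- z[i]
    num <- 0; den <- 0; m <- 0L
    delta <- (z - zc) - defl
    for (j in seq_len(n)) {
      if (z[j] > zc && delta[j] > 0 && delta[j] <= maxIndentation) {
        xj <- delta[j]^1.5
        num <- num + xj * f[j]; den <- den + xj^2; m <- m + 1L
      }
    }
    if (m < minPts || den == 0) next
    b <- num / den
    if (b <= 0) next
    ss <- 0
    for (j in seq_len(n)) {
      pr <- if (z[j] > zc && delta[j] > 0) b * delta[j]^1.5 else 0
      ss <- ss + (f[j] - pr)^2
    }
    rms <- sqrt(ss / n)
    if (rms < bestRms) { bestRms <- rms; bestE <- b / unit; bestZc <- zc }
  }
  list(E = bestE, contactPoint = bestZc, rms = bestRms)
}
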