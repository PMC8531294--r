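#' Convert cantilever deflection to force
#'
#' Hooke's law for the calibrated cantilever: a deflection in nm times the
#' spring constant in N/m gives the force in nN, reported here in pN
#' (1 N/m = 1000 pN/nm). The sign of the deflection is preserved, so
#' repulsive (upward) deflections give positive forces and adhesive pulls
#' negative forces.
#'
#' @param deflection numeric vector, nm.
#' @param springConstant single positive number, N/m.
#' @return numeric vector, force in pN.
#' @examples
#' deflectionToForce(10, 0.05)   # 500 pN
#' @export
deflectionToForce <- function(deflection, springConstant) {
  if (length(springConstant) != 1L || !is.finite(springConstant) ||
      springConstant <= 0)
    stop("springConstant must be a single positive finite number (N/m)")
  if (anyNA(deflection) || any(!is.finite(deflection)))
    stop("deflection must be finite")
  deflection * springConstant * 1000
}

# Indices of the far-from-surface fit region: piezo height increases toward
# the surface, so the far end is the low-height end of the segment.
.baselineRegion <- function(segment, fitRegionFraction) {
  n <- length(segment@force)
  nFit <- max(10L, as.integer(floor(fitRegionFraction * n)))
  if (floor(fitRegionFraction * n) < 10L)
    stop(sprintf(
      "baseline fit region has %d samples; need at least 10 (segment has %d)",
      as.integer(floor(fitRegionFraction * n)), n))
  order(segment@piezoHeight)[seq_len(nFit)]
}

#' Remove the free-cantilever baseline from a segment
#'
#' Fits a straight line (force vs piezo height) on the far-from-surface end
#' of the segment, where the cantilever is free, and subtracts it from the
#' whole segment. After correction the mean force over the fit region is
#' zero up to the residual noise. Used before any Hertz fitting or rupture
#' extraction so that forces are measured relative to zero load.
#'
#' @param segment an [FDSegment] (approach or retract).
#' @param fitRegionFraction fraction of samples, taken from the
#'   far-from-surface (low piezo height) end, used to fit the baseline.
#'   Default 0.3.
#' @return list with `segment` (corrected [FDSegment]) and `model`
#'   (a [BaselineModel]).
#' @export
baselineCorrect <- function(segment, fitRegionFraction = 0.3) {
  stopifnot(is(segment, "FDSegment"))
  if (fitRegionFraction <= 0 || fitRegionFraction > 1)
    stop("fitRegionFraction must be in (0, 1]")
  idx <- .baselineRegion(segment, fitRegionFraction)
  z <- segment@piezoHeight[idx]
  f <- segment@force[idx]
  if (diff(range(z)) == 0)
    stop("baseline fit region has zero piezo-height extent; cannot fit a slope")
  fit <- stats::lm.fit(cbind(1, z), f)
  coefs <- fit$coefficients
  pred <- coefs[1] + coefs[2] * segment@piezoHeight
  corrected <- FDSegment(segment@label, segment@piezoHeight, segment@force - pred)
  model <- new("BaselineModel", intercept = unname(coefs[1]),
               slope = unname(coefs[2]),
               fitRegionFraction = fitRegionFraction,
               residualRms = sqrt(mean(fit$residuals^2)),
               nFit = length(idx))
  list(segment = corrected, model = model)
}

# Checks that a segment looks baseline-corrected: the far-region mean force
# must be consistent with zero given its scatter.
.assertBaselined <- function(segment, fitRegionFraction = 0.3, what = "segment") {
  idx <- .baselineRegion(segment, fitRegionFraction)
  f <- segment@force[idx]
  tol <- max(1e-9, 5 * stats::sd(f) / sqrt(length(f)))
  if (abs(mean(f)) > tol)
    stop(sprintf(
      "%s does not look baseline-corrected (far-region mean force %.3g pN exceeds tolerance %.3g pN); run baselineCorrect() first",
      what, mean(f), tol))
  invisible(TRUE)
}

#' Tip-sample separation from a corrected segment
#'
#' Converts piezo height and force into the distance between the tip apex
#' and the sample surface. With piezo height z increasing toward the
#' surface, deflection d = force / spring constant, and a reference height
#' `contactPoint` at which the free tip touches the surface, the separation
#' is \eqn{s = (z_c - z) + d}. In contact on approach the separation is
#' negative and the indentation depth is \eqn{\delta = -s = (z - z_c) - d}.
#' With zero force everywhere the separation is simply the piezo
#' displacement from the reference.
#'
#' @param segment a baseline-corrected [FDSegment].
#' @param springConstant N/m.
#' @param contactPoint reference piezo height (nm). Defaults to the maximum
#'   piezo height of the segment (closest approach), appropriate for retract
#'   segments that start at the surface.
#' @return numeric vector of separations, nm (negative = indentation).
#' @export
tipSampleSeparation <- function(segment, springConstant, contactPoint = NULL) {
  stopifnot(is(segment, "FDSegment"))
  if (missing(springConstant) || length(springConstant) != 1L ||
      !is.finite(springConstant) || springConstant <= 0)
    stop("a positive springConstant (N/m) is required")
  if (is.null(contactPoint)) contactPoint <- max(segment@piezoHeight)
  d <- segment@force / (springConstant * 1000)  # nm
  (contactPoint - segment@piezoHeight) + d
}
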