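#' @import methods
NULL

.SEGMENT_LABELS <- c("approach", "dwell", "retract")
.PROBE_LEVELS <- c("anti_FN", "anti_IgG", "none")

#' Force-distance curve segment
#'
#' One contiguous segment (approach, dwell or retract) of a calibrated
#' force-distance curve. Piezo height is in nm and increases toward the
#' sample surface; force is in pN with the repulsive (indentation) direction
#' positive, so adhesive tether loads on retraction are negative. Samples are
#' stored in acquisition order, which makes piezo height strictly increasing
#' on approach segments and strictly decreasing on retract segments.
#'
#' @slot label character, one of `"approach"`, `"dwell"`, `"retract"`.
#' @slot piezoHeight numeric vector, piezo height in nm.
#' @slot force numeric vector, force in pN, same length as `piezoHeight`.
#' @export
setClass("FDSegment",
  representation(label = "character", piezoHeight = "numeric", force = "numeric"))

setValidity("FDSegment", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !object@label %in% .SEGMENT_LABELS)
    msg <- c(msg, sprintf("label must be one of %s",
                          paste(.SEGMENT_LABELS, collapse = ", ")))
  n <- length(object@piezoHeight)
  if (length(object@force) != n)
    msg <- c(msg, "piezoHeight and force must have equal length")
  if (n < 2L)
    msg <- c(msg, "a segment needs at least 2 samples")
  if (anyNA(object@piezoHeight) || anyNA(object@force) ||
      any(!is.finite(object@piezoHeight)) || any(!is.finite(object@force)))
    msg <- c(msg, "piezoHeight and force must be finite")
  if (length(object@label) == 1L && n >= 2L &&
      object@label %in% c("approach", "retract")) {
    d <- diff(object@piezoHeight)
    if (object@label == "approach" && !all(d > 0))
      msg <- c(msg, "approach piezoHeight must be strictly increasing (toward surface)")
    if (object@label == "retract" && !all(d < 0))
      msg <- c(msg, "retract piezoHeight must be strictly decreasing (away from surface)")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FDSegment-class
#' @param label segment label.
#' @param piezoHeight piezo height samples, nm.
#' @param force force samples, pN.
#' @export
FDSegment <- function(label, piezoHeight, force) {
  new("FDSegment", label = as.character(label),
      piezoHeight = as.numeric(piezoHeight), force = as.numeric(force))
}

#' Calibrated force-distance curve
#'
#' A single AFM force-distance curve with probe metadata and its ordered
#' segments. The cantilever spring constant is in N/m; the bead radius (for
#' spherical colloidal probes) in um, `NA` for pyramidal tips.
#'
#' @slot curveId character identifier.
#' @slot sampleId character, the physical sample (gel/experiment) probed.
#' @slot probe character, `"anti_FN"`, `"anti_IgG"` or `"none"`.
#' @slot substrate character label, e.g. `"stembond_soft"`.
#' @slot springConstant numeric, N/m, > 0.
#' @slot beadRadius numeric, um, or `NA` for non-spherical tips.
#' @slot segments list of [FDSegment] objects, at most one per label.
#' @export
setClass("ForceCurve",
  representation(curveId = "character", sampleId = "character",
                 probe = "character", substrate = "character",
                 springConstant = "numeric", beadRadius = "numeric",
                 segments = "list"))

setValidity("ForceCurve", function(object) {
  msg <- character()
  for (s in c("curveId", "sampleId", "probe", "substrate"))
    if (length(slot(object, s)) != 1L) msg <- c(msg, sprintf("%s must be length 1", s))
  if (length(object@probe) == 1L && !object@probe %in% .PROBE_LEVELS)
    msg <- c(msg, sprintf("probe must be one of %s", paste(.PROBE_LEVELS, collapse = ", ")))
  if (length(object@springConstant) != 1L || !is.finite(object@springConstant) ||
      object@springConstant <= 0)
    msg <- c(msg, "springConstant must be a single positive number (N/m)")
  if (length(object@beadRadius) != 1L ||
      (!is.na(object@beadRadius) && object@beadRadius <= 0))
    msg <- c(msg, "beadRadius must be a single positive number (um) or NA")
  if (!all(vapply(object@segments, is, logical(1), "FDSegment")))
    msg <- c(msg, "segments must all be FDSegment objects")
  labs <- vapply(object@segments, function(s) s@label, character(1))
  if (anyDuplicated(labs))
    msg <- c(msg, "at most one segment per label")
  if (length(msg)) msg else TRUE
})

#' @rdname ForceCurve-class
#' @param curveId,sampleId,probe,substrate,springConstant,beadRadius see slots.
#' @param segments list of [FDSegment] objects.
#' @export
ForceCurve <- function(curveId, sampleId = "s1", probe = "none",
                       substrate = "unknown", springConstant,
                       beadRadius = NA_real_, segments = list()) {
  new("ForceCurve", curveId = as.character(curveId),
      sampleId = as.character(sampleId), probe = as.character(probe),
      substrate = as.character(substrate),
      springConstant = as.numeric(springConstant),
      beadRadius = as.numeric(beadRadius), segments = segments)
}

#' Linear baseline model for a force segment
#'
#' @slot intercept pN, at piezo height 0.
#' @slot slope pN/nm.
#' @slot fitRegionFraction fraction of samples (far-from-surface end) used.
#' @slot residualRms pN, RMS of fit residuals.
#' @slot nFit number of samples in the fit region.
#' @export
setClass("BaselineModel",
  representation(intercept = "numeric", slope = "numeric",
                 fitRegionFraction = "numeric", residualRms = "numeric",
                 nFit = "integer"))

setValidity("BaselineModel", function(object) {
  msg <- character()
  if (object@residualRms < 0) msg <- c(msg, "residualRms must be >= 0")
  if (object@fitRegionFraction <= 0 || object@fitRegionFraction > 1)
    msg <- c(msg, "fitRegionFraction must be in (0, 1]")
  if (object@nFit < 10L) msg <- c(msg, "baseline fit region must contain >= 10 samples")
  if (length(msg)) msg else TRUE
})

#' Hertz-model fit of an approach segment
#'
#' @slot youngsModulus Pa.
#' @slot contactPoint nm (piezo height at tip-surface contact).
#' @slot poissonRatio unitless, in [0, 0.5].
#' @slot beadRadius um.
#' @slot residualRms pN over the fitted region.
#' @slot nPointsInContact number of in-contact samples used.
#' @slot curveId originating curve, `""` when fit from a bare segment.
#' @export
setClass("HertzFit",
  representation(youngsModulus = "numeric", contactPoint = "numeric",
                 poissonRatio = "numeric", beadRadius = "numeric",
                 residualRms = "numeric", nPointsInContact = "integer",
                 curveId = "character"))

setValidity("HertzFit", function(object) {
  msg <- character()
  if (object@youngsModulus <= 0) msg <- c(msg, "youngsModulus must be > 0")
  if (object@poissonRatio < 0 || object@poissonRatio > 0.5)
    msg <- c(msg, "poissonRatio must be in [0, 0.5]")
  if (object@nPointsInContact < 5L) msg <- c(msg, "need >= 5 in-contact points")
  if (length(msg)) msg else TRUE
})

#' Set of rupture events for one sample and probe
#'
#' Events are stored as a data.frame with columns `curveId`,
#' `ruptureForce` (pN, positive magnitude) and `ruptureLength` (nm);
#' synthetic sets may carry an additional logical `specific` column with the
#' generator's hidden truth labels. Curves that produced no event still count
#' toward `nCurvesTotal`.
#'
#' @slot events data.frame of rupture events.
#' @slot sampleId character.
#' @slot probe `"anti_FN"` (sample) or `"anti_IgG"` (negative control).
#' @slot substrate character label.
#' @slot stiffnessClass `"soft"` or `"stiff"`; soft and stiff substrates are
#'   always analysed separately.
#' @slot nCurvesTotal total number of curves acquired (>= number of events).
#' @export
setClass("EventSet",
  representation(events = "data.frame", sampleId = "character",
                 probe = "character", substrate = "character",
                 stiffnessClass = "character", nCurvesTotal = "integer"))

setValidity("EventSet", function(object) {
  msg <- character()
  ev <- object@events
  need <- c("curveId", "ruptureForce", "ruptureLength")
  if (!all(need %in% names(ev)))
    msg <- c(msg, "events must have columns curveId, ruptureForce, ruptureLength")
  else {
    if (nrow(ev) && any(ev$ruptureForce <= 0))
      msg <- c(msg, "ruptureForce must be > 0 (positive magnitude)")
    if (nrow(ev) && any(ev$ruptureLength < 0))
      msg <- c(msg, "ruptureLength must be >= 0")
  }
  if (!object@probe %in% c("anti_FN", "anti_IgG"))
    msg <- c(msg, "probe must be anti_FN or anti_IgG")
  if (!object@stiffnessClass %in% c("soft", "stiff"))
    msg <- c(msg, "stiffnessClass must be soft or stiff")
  if (object@nCurvesTotal < nrow(ev))
    msg <- c(msg, "nCurvesTotal must be >= number of events")
  if (length(msg)) msg else TRUE
})

#' @rdname EventSet-class
#' @param events data.frame with columns curveId, ruptureForce, ruptureLength.
#' @param sampleId,probe,substrate,stiffnessClass,nCurvesTotal see slots.
#' @export
EventSet <- function(events, sampleId = "s1", probe = "anti_FN",
                     substrate = "unknown", stiffnessClass = "soft",
                     nCurvesTotal = nrow(events)) {
  new("EventSet", events = as.data.frame(events), sampleId = as.character(sampleId),
      probe = as.character(probe), substrate = as.character(substrate),
      stiffnessClass = as.character(stiffnessClass),
      nCurvesTotal = as.integer(nCurvesTotal))
}

#' Rupture thresholds from a negative-control population
#'
#' Both thresholds are set at the median of the negative-control (anti-IgG
#' probe) distributions; downstream, events are retained only when they
#' exceed both.
#'
#' @slot forceThreshold pN.
#' @slot lengthThreshold nm.
#' @export
setClass("TetherThresholds",
  representation(forceThreshold = "numeric", lengthThreshold = "numeric"))

setValidity("TetherThresholds", function(object) {
  if (!is.finite(object@forceThreshold) || object@forceThreshold < 0 ||
      !is.finite(object@lengthThreshold) || object@lengthThreshold < 0)
    "thresholds must be finite and >= 0" else TRUE
})

#' Binned 2-D event density on (rupture length, log10 rupture force)
#'
#' The density matrix has rupture-length bins as rows and log10 rupture-force
#' bins as columns, and sums to 1 over occupied bins (all zeros for an empty
#' event set). `nEvents` is the number of events binned (used for the
#' one-pseudo-event floor in [significantMask()]).
#'
#' @slot lengthEdges nm bin edges, strictly increasing.
#' @slot logForceEdges log10(pN) bin edges, strictly increasing.
#' @slot density matrix, `length(lengthEdges)-1` x `length(logForceEdges)-1`.
#' @slot nEvents number of events represented.
#' @export
setClass("DensityGrid",
  representation(lengthEdges = "numeric", logForceEdges = "numeric",
                 density = "matrix", nEvents = "integer"))

setValidity("DensityGrid", function(object) {
  msg <- character()
  if (any(diff(object@lengthEdges) <= 0) || any(diff(object@logForceEdges) <= 0))
    msg <- c(msg, "bin edges must be strictly increasing")
  d <- object@density
  if (nrow(d) != length(object@lengthEdges) - 1L ||
      ncol(d) != length(object@logForceEdges) - 1L)
    msg <- c(msg, "density shape must match bin edges")
  if (any(d < 0)) msg <- c(msg, "density must be >= 0")
  s <- sum(d)
  if (!(abs(s) < 1e-9 || abs(s - 1) < 1e-9))
    msg <- c(msg, "density must sum to 0 (empty) or 1")
  if (length(msg)) msg else TRUE
})

#' Boolean significance mask over a density grid
#'
#' @slot mask logical matrix, congruent with the density grid it was
#'   computed from.
#' @slot kernelSize odd integer, side of the median-filter kernel.
#' @slot lengthEdges,logForceEdges bin edges copied from the grid, so the
#'   mask can re-bin events on its own.
#' @export
setClass("SignificanceMask",
  representation(mask = "matrix", kernelSize = "integer",
                 lengthEdges = "numeric", logForceEdges = "numeric"))

setValidity("SignificanceMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (object@kernelSize %% 2L != 1L || object@kernelSize < 1L)
    msg <- c(msg, "kernelSize must be a positive odd integer")
  if (nrow(object@mask) != length(object@lengthEdges) - 1L ||
      ncol(object@mask) != length(object@logForceEdges) - 1L)
    msg <- c(msg, "mask shape must match bin edges")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FDSegment", function(object) {
  cat(sprintf("FDSegment '%s': %d samples, piezo %.1f..%.1f nm, force %.1f..%.1f pN\n",
              object@label, length(object@force),
              min(object@piezoHeight), max(object@piezoHeight),
              min(object@force), max(object@force)))
})

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf("ForceCurve '%s' (sample %s, probe %s, substrate %s)\n",
              object@curveId, object@sampleId, object@probe, object@substrate))
  cat(sprintf("  k = %g N/m, bead radius = %s um, segments: %s\n",
              object@springConstant,
              ifelse(is.na(object@beadRadius), "NA", format(object@beadRadius)),
              paste(vapply(object@segments, function(s) s@label, character(1)),
                    collapse = ", ")))
})

setMethod("show", "HertzFit", function(object) {
  cat(sprintf("HertzFit: E = %.4g Pa, contact at %.1f nm, nu = %g, %d points, RMS %.3g pN\n",
              object@youngsModulus, object@contactPoint, object@poissonRatio,
              object@nPointsInContact, object@residualRms))
})

setMethod("show", "EventSet", function(object) {
  cat(sprintf("EventSet: %d events / %d curves (sample %s, probe %s, %s %s)\n",
              nrow(object@events), object@nCurvesTotal, object@sampleId,
              object@probe, object@stiffnessClass, object@substrate))
})

setMethod("show", "DensityGrid", function(object) {
  cat(sprintf("DensityGrid: %d x %d bins, %d events, mass %.3f\n",
              nrow(object@density), ncol(object@density), object@nEvents,
              sum(object@density)))
})

setMethod("show", "SignificanceMask", function(object) {
  cat(sprintf("SignificanceMask: %d x %d bins, %d significant, kernel %d\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              object@kernelSize))
})
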