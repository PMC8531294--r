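#' Accessors for MechanoProbe classes
#'
#' Small accessor generics: `events()` returns the event data.frame of an
#' [EventSet], `segments()` the segment list of a [ForceCurve],
#' `getSegment()` one segment by label, `probeType()`, `sampleId()` and
#' `substrateLabel()` the corresponding metadata, `youngsModulus()` the
#' fitted modulus of a [HertzFit], `densityValues()` / `maskValues()` the
#' matrix payloads of [DensityGrid] / [SignificanceMask].
#'
#' @param x object.
#' @param label segment label for `getSegment`.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setMethod("events", "EventSet", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setMethod("segments", "ForceCurve", function(x) x@segments)

#' @rdname accessors
#' @export
setGeneric("getSegment", function(x, label) standardGeneric("getSegment"))
#' @rdname accessors
#' @export
setMethod("getSegment", "ForceCurve", function(x, label) {
  labs <- vapply(x@segments, function(s) s@label, character(1))
  i <- match(label, labs)
  if (is.na(i)) stop(sprintf("curve '%s' has no '%s' segment", x@curveId, label))
  x@segments[[i]]
})

#' @rdname accessors
#' @export
setGeneric("probeType", function(x) standardGeneric("probeType"))
#' @rdname accessors
#' @export
setMethod("probeType", "EventSet", function(x) x@probe)
#' @rdname accessors
#' @export
setMethod("probeType", "ForceCurve", function(x) x@probe)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "EventSet", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "ForceCurve", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("substrateLabel", function(x) standardGeneric("substrateLabel"))
#' @rdname accessors
#' @export
setMethod("substrateLabel", "EventSet", function(x) x@substrate)
#' @rdname accessors
#' @export
setMethod("substrateLabel", "ForceCurve", function(x) x@substrate)

#' @rdname accessors
#' @export
setGeneric("youngsModulus", function(x) standardGeneric("youngsModulus"))
#' @rdname accessors
#' @export
setMethod("youngsModulus", "HertzFit", function(x) x@youngsModulus)

#' @rdname accessors
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
#' @rdname accessors
#' @export
setMethod("densityValues", "DensityGrid", function(x) x@density)

#' @rdname accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))
#' @rdname accessors
#' @export
setMethod("maskValues", "SignificanceMask", function(x) x@mask)
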