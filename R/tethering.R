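#' Extract the rupture event from a retraction segment
#'
#' The rupture force is the magnitude of the most negative (most adhesive)
#' force on the baseline-corrected retract segment — the minimal value of
#' the vertical deflection — and the rupture length is the tip-sample
#' separation at that minimum. Curves whose largest adhesion magnitude is
#' below `minForce` are treated as event-free noise and return `NULL`.
#'
#' @param retract a baseline-corrected retract [FDSegment].
#' @param springConstant N/m.
#' @param minForce pN; minimum adhesion magnitude to call an event.
#'   Default 20.
#' @param curveId identifier carried into the event row.
#' @return one-row data.frame (`curveId`, `ruptureForce`, `ruptureLength`)
#'   or `NULL` when no event exceeds `minForce`.
#' @export
extractRupture <- function(retract, springConstant, minForce = 20,
                           curveId = "curve") {
  stopifnot(is(retract, "FDSegment"))
  if (retract@label != "retract") stop("extractRupture needs a retract segment")
  .assertBaselined(retract, what = "retract segment")
  i <- which.min(retract@force)
  fmin <- retract@force[i]
  if (-fmin < minForce) return(NULL)
  sep <- tipSampleSeparation(retract, springConstant)[i]
  data.frame(curveId = as.character(curveId),
             ruptureForce = -fmin,
             ruptureLength = max(sep, 0))
}

#' Thresholds from the negative-control event population
#'
#' Rupture-force and rupture-length thresholds are set at the medians of the
#' negative-control (anti-IgG probe) distributions; events must exceed both
#' to be considered further, ruling out non-specific probe-surface
#' interactions.
#'
#' @param control an [EventSet] with probe `"anti_IgG"`, or a list of such
#'   sets (pooled).
#' @return a [TetherThresholds].
#' @export
controlThresholds <- function(control) {
  if (is(control, "EventSet")) control <- list(control)
  stopifnot(all(vapply(control, is, logical(1), "EventSet")))
  probes <- vapply(control, probeType, character(1))
  if (!all(probes == "anti_IgG"))
    stop("thresholds must come from negative-control (anti_IgG) event sets")
  ev <- do.call(rbind, lapply(control, events))
  if (is.null(ev) || nrow(ev) == 0L)
    stop("control event set is empty; pool controls across experiments before setting thresholds")
  new("TetherThresholds",
      forceThreshold = stats::median(ev$ruptureForce),
      lengthThreshold = stats::median(ev$ruptureLength))
}

# Events strictly exceeding both thresholds.
.retainEvents <- function(ev, thresholds) {
  ev[ev$ruptureForce > thresholds@forceThreshold &
     ev$ruptureLength > thresholds@lengthThreshold, , drop = FALSE]
}

#' Grid specification for tether density maps
#'
#' Builds the shared binning used for sample and control density maps:
#' `nBins` x `nBins` bins spanning the pooled (sample and control) retained
#' range on (rupture length in nm, log10 rupture force in pN), padded by
#' `pad` on each side.
#'
#' @param eventSets list of [EventSet]s whose retained events define the
#'   range.
#' @param thresholds a [TetherThresholds].
#' @param nBins bins per axis, default 30.
#' @param pad fractional range padding, default 0.05.
#' @return list with `lengthEdges` and `logForceEdges`.
#' @export
tetherGrid <- function(eventSets, thresholds, nBins = 30L, pad = 0.05) {
  if (is(eventSets, "EventSet")) eventSets <- list(eventSets)
  ev <- do.call(rbind, lapply(eventSets, events))
  ret <- .retainEvents(ev, thresholds)
  if (nrow(ret) == 0L) stop("no events pass the thresholds; cannot define a grid")
  padRange <- function(x) {
    r <- range(x)
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1)  # degenerate: all events identical
    r + c(-1, 1) * pad * w
  }
  lr <- padRange(ret$ruptureLength)
  fr <- padRange(log10(ret$ruptureForce))
  list(lengthEdges = seq(lr[1], lr[2], length.out = nBins + 1L),
       logForceEdges = seq(fr[1], fr[2], length.out = nBins + 1L))
}

# Bin index per event (row = length bin, col = log10 force bin); 0 when the
# event falls outside the grid.
.binEvents <- function(ev, grid) {
  nL <- length(grid$lengthEdges) - 1L
  nF <- length(grid$logForceEdges) - 1L
  iL <- findInterval(ev$ruptureLength, grid$lengthEdges, rightmost.closed = TRUE)
  iF <- findInterval(log10(ev$ruptureForce), grid$logForceEdges, rightmost.closed = TRUE)
  ok <- iL >= 1L & iL <= nL & iF >= 1L & iF <= nF
  list(row = ifelse(ok, iL, 0L), col = ifelse(ok, iF, 0L), inside = ok)
}

#' 2-D density map of rupture events
#'
#' Normalised 2-D histogram of the threshold-passing events on
#' (rupture length, log10 rupture force). The density sums to 1 over
#' occupied bins; when no events are retained an all-zero grid is returned.
#'
#' @param eventSets an [EventSet] or list of them (pooled, e.g. all
#'   replicate samples of one substrate).
#' @param thresholds a [TetherThresholds]; only events strictly exceeding
#'   both thresholds are binned.
#' @param grid grid specification from [tetherGrid()].
#' @return a [DensityGrid].
#' @export
densityMap <- function(eventSets, thresholds, grid) {
  if (is(eventSets, "EventSet")) eventSets <- list(eventSets)
  ev <- do.call(rbind, lapply(eventSets, events))
  ret <- .retainEvents(ev, thresholds)
  if (nrow(ret) && any(ret$ruptureForce <= 0))
    stop("rupture forces must be positive to take log10")
  nL <- length(grid$lengthEdges) - 1L
  nF <- length(grid$logForceEdges) - 1L
  counts <- matrix(0, nL, nF)
  if (nrow(ret)) {
    b <- .binEvents(ret, grid)
    inside <- b$inside
    if (any(inside)) {
      idx <- (b$col[inside] - 1L) * nL + b$row[inside]
      tab <- tabulate(idx, nbins = nL * nF)
      counts <- matrix(tab, nL, nF)
    }
  }
  total <- sum(counts)
  new("DensityGrid", lengthEdges = grid$lengthEdges,
      logForceEdges = grid$logForceEdges,
      density = if (total > 0) counts / total else counts,
      nEvents = as.integer(total))
}

# 2-D boolean median filter: majority vote over a k x k neighbourhood with
# FALSE padding beyond the border; ties (impossible for odd k on the full
# window, possible only by convention changes) resolve toward FALSE via the
# strict majority rule.
.medianFilterBool <- function(m, kernelSize = 3L) {
  k <- as.integer(kernelSize)
  if (k %% 2L != 1L || k < 1L) stop("kernelSize must be a positive odd integer")
  if (k == 1L) return(m)
  h <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  padded <- matrix(0L, nr + 2L * h, nc + 2L * h)
  padded[h + seq_len(nr), h + seq_len(nc)] <- m * 1L
  out <- matrix(0L, nr, nc)
  for (di in seq_len(k) - 1L) for (dj in seq_len(k) - 1L)
    out <- out + padded[di + seq_len(nr), dj + seq_len(nc)]
  out > (k * k) %/% 2L
}

#' Significance mask from sample vs control densities
#'
#' Marks the grid regions where the sample event density exceeds `ratio`
#' times the control density, then smooths the raw mask with a 2-D median
#' filter. The control density enters with one pseudo-event of add-one
#' smoothing, `control + 1/nControlRetained`, acknowledging the Poisson
#' uncertainty of a finitely sampled control map: in bins the control never
#' sampled the criterion becomes a floor of `ratio / nControlRetained` (a
#' single stray sample event cannot become significant merely because the
#' control is empty there), and in sparsely sampled control bins a chance
#' ratio exceedance of one or two events is likewise discounted. Where the
#' control is well sampled the smoothing is negligible.
#'
#' @param sample a [DensityGrid] for the sample (anti-FN probe) events.
#' @param control a congruent [DensityGrid] for the negative control.
#' @param ratio density ratio defining significance, default 2.
#' @param kernelSize odd median-filter kernel side, default 3.
#' @return a [SignificanceMask].
#' @export
significantMask <- function(sample, control, ratio = 2, kernelSize = 3L) {
  stopifnot(is(sample, "DensityGrid"), is(control, "DensityGrid"))
  if (!isTRUE(all.equal(sample@lengthEdges, control@lengthEdges)) ||
      !isTRUE(all.equal(sample@logForceEdges, control@logForceEdges)))
    stop("sample and control grids are not congruent")
  pseudo <- if (control@nEvents > 0) 1 / control@nEvents else Inf
  raw <- sample@density > ratio * (control@density + pseudo)
  smoothed <- .medianFilterBool(raw, kernelSize)
  new("SignificanceMask", mask = smoothed, kernelSize = as.integer(kernelSize),
      lengthEdges = sample@lengthEdges, logForceEdges = sample@logForceEdges)
}

#' Classify events as significant binding events
#'
#' Retains the events of `eventSet` that pass both thresholds and whose
#' (rupture length, log10 rupture force) bin is marked significant in the
#' mask. Events falling outside the grid range are counted as unclassified
#' and reported via the `"nUnclassified"` attribute.
#'
#' @param eventSet an [EventSet].
#' @param thresholds a [TetherThresholds].
#' @param mask a [SignificanceMask] (carries its own grid).
#' @return an [EventSet] containing the significant subset, with attribute
#'   `nUnclassified`.
#' @export
classifyEvents <- function(eventSet, thresholds, mask) {
  stopifnot(is(eventSet, "EventSet"), is(mask, "SignificanceMask"))
  ev <- events(eventSet)
  ret <- .retainEvents(ev, thresholds)
  grid <- list(lengthEdges = mask@lengthEdges, logForceEdges = mask@logForceEdges)
  keep <- logical(nrow(ret))
  nUnclassified <- 0L
  if (nrow(ret)) {
    b <- .binEvents(ret, grid)
    nUnclassified <- sum(!b$inside)
    ins <- b$inside
    keep[ins] <- mask@mask[cbind(b$row[ins], b$col[ins])]
  }
  out <- EventSet(ret[keep, , drop = FALSE], sampleId = eventSet@sampleId,
                  probe = eventSet@probe, substrate = eventSet@substrate,
                  stiffnessClass = eventSet@stiffnessClass,
                  nCurvesTotal = eventSet@nCurvesTotal)
  attr(out, "nUnclassified") <- nUnclassified
  out
}

#' Summarise significant tethering events across replicate samples
#'
#' Per-sample mean of log10 rupture force over the significant events, the
#' overall mean of the sample means, and the standard error of the mean
#' across samples. Samples with zero significant events contribute no mean
#' (they are reported in `nSignificantPerSample` but excluded from the
#' averages); when every sample is empty the result flags
#' `noSignificantBinding` instead of raising an error, mirroring substrates
#' on which no significant binding events are measured.
#'
#' @param sampleSets list of [EventSet]s of significant events, one per
#'   independent sample.
#' @return list with `perSampleMeanLog10Force`, `overallMean`, `sem`,
#'   `nSamples` (samples with >= 1 significant event),
#'   `nSignificantPerSample` (named counts, all samples) and
#'   `noSignificantBinding` flag; `sem` is 0 with `singleSample = TRUE`
#'   when only one sample has events.
#' @export
summarizeTethering <- function(sampleSets) {
  if (is(sampleSets, "EventSet")) sampleSets <- list(sampleSets)
  stopifnot(length(sampleSets) >= 1L,
            all(vapply(sampleSets, is, logical(1), "EventSet")))
  counts <- vapply(sampleSets, function(s) nrow(events(s)), integer(1))
  names(counts) <- vapply(sampleSets, sampleId, character(1))
  nonEmpty <- which(counts > 0L)
  if (length(nonEmpty) == 0L)
    return(list(perSampleMeanLog10Force = numeric(0), overallMean = NA_real_,
                sem = NA_real_, nSamples = 0L,
                nSignificantPerSample = counts, noSignificantBinding = TRUE,
                singleSample = FALSE))
  means <- vapply(sampleSets[nonEmpty],
                  function(s) mean(log10(events(s)$ruptureForce)), numeric(1))
  names(means) <- names(counts)[nonEmpty]
  n <- length(means)
  list(perSampleMeanLog10Force = means,
       overallMean = mean(means),
       sem = if (n > 1L) stats::sd(means) / sqrt(n) else 0,
       nSamples = n,
       nSignificantPerSample = counts,
       noSignificantBinding = FALSE,
       singleSample = n == 1L)
}
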