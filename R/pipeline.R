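#' Run the ECM-tethering characterisation study end to end
#'
#' For each stiffness class the stages run in order: pool the class's
#' negative controls and set the force/length thresholds at their medians;
#' build the shared grid and the sample and control density maps (per
#' substrate, samples pooled); derive the significance mask (density ratio
#' with median-filter smoothing); classify each replicate sample's events;
#' and summarise the significant events per substrate. Soft and stiff
#' substrates are never pooled.
#'
#' @param samples named list (per substrate) of lists of [EventSet]s, one
#'   per replicate sample.
#' @param controls named list (per stiffness class, `"soft"`/`"stiff"`) of
#'   lists of control [EventSet]s.
#' @param params list of stage parameters: `ratio` (default 2),
#'   `kernelSize` (3), `nBins` (30), `pad` (0.05).
#' @param outputDir optional directory; when given, every table is written
#'   as TSV with a provenance header carrying the full parameter set (plus
#'   `extraProvenance`), the density grids and masks as TSV matrices with
#'   edge headers. Re-running with identical inputs and parameters
#'   reproduces the files byte-identically.
#' @param extraProvenance named list merged into the provenance headers
#'   (e.g. the simulation seed).
#' @return named list per substrate with `thresholds`, `sampleDensity`,
#'   `controlDensity`, `mask`, `significant` (list of [EventSet]s),
#'   `summary` (from [summarizeTethering()]) and `nUnclassified`.
#' @export
runTetheringStudy <- function(samples, controls, params = list(),
                              outputDir = NULL, extraProvenance = list()) {
  p <- utils::modifyList(list(ratio = 2, kernelSize = 3L, nBins = 30L,
                              pad = 0.05), params)
  if (is.null(names(samples)) || is.null(names(controls)))
    stop("samples and controls must be named lists")
  classOf <- function(sets) unique(vapply(sets, function(s) s@stiffnessClass,
                                          character(1)))
  results <- list()
  for (substrate in names(samples)) {
    sampleSets <- samples[[substrate]]
    cls <- classOf(sampleSets)
    if (length(cls) != 1L)
      stop(sprintf("substrate '%s' mixes stiffness classes", substrate))
    if (!cls %in% names(controls))
      stop(sprintf("no '%s' control provided for substrate '%s' (controls: %s)",
                   cls, substrate, paste(names(controls), collapse = ", ")))
    controlSets <- controls[[cls]]
    thr <- controlThresholds(controlSets)
    grid <- tetherGrid(c(sampleSets, controlSets), thr,
                       nBins = p$nBins, pad = p$pad)
    dSample <- densityMap(sampleSets, thr, grid)
    dControl <- densityMap(controlSets, thr, grid)
    mask <- significantMask(dSample, dControl, ratio = p$ratio,
                            kernelSize = p$kernelSize)
    sig <- lapply(sampleSets, classifyEvents, thresholds = thr, mask = mask)
    results[[substrate]] <- list(
      thresholds = thr, sampleDensity = dSample, controlDensity = dControl,
      mask = mask, significant = sig, summary = summarizeTethering(sig),
      nUnclassified = sum(vapply(sig, function(s)
        attr(s, "nUnclassified"), integer(1))))
  }
  if (!is.null(outputDir))
    .writeTetheringBundle(results, outputDir, p, extraProvenance)
  invisible(results)
}

# Serialises matrices with their bin edges as commented header lines.
.writeGridTSV <- function(values, lengthEdges, logForceEdges, path, prov) {
  prov <- c(prov, list(length_edges_nm = lengthEdges,
                       log10_force_edges = logForceEdges))
  df <- as.data.frame(values)
  names(df) <- sprintf("fbin%02d", seq_len(ncol(df)))
  writeProvenanceTSV(df, path, prov)
}

.writeTetheringBundle <- function(results, outputDir, params, extra) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(params, extra)
  for (substrate in names(results)) {
    r <- results[[substrate]]
    pfx <- file.path(outputDir, substrate)
    sprov <- c(prov, list(substrate = substrate,
                          force_threshold_pN = r$thresholds@forceThreshold,
                          length_threshold_nm = r$thresholds@lengthThreshold))
    .writeGridTSV(r$sampleDensity@density, r$sampleDensity@lengthEdges,
                  r$sampleDensity@logForceEdges,
                  paste0(pfx, "_sample_density.tsv"), sprov)
    .writeGridTSV(r$controlDensity@density, r$controlDensity@lengthEdges,
                  r$controlDensity@logForceEdges,
                  paste0(pfx, "_control_density.tsv"), sprov)
    .writeGridTSV(1L * r$mask@mask, r$mask@lengthEdges, r$mask@logForceEdges,
                  paste0(pfx, "_mask.tsv"), sprov)
    for (i in seq_along(r$significant))
      writeEventTable(r$significant[[i]],
                      sprintf("%s_significant_%s.tsv", pfx,
                              sampleId(r$significant[[i]])))
    s <- r$summary
    writeProvenanceTSV(
      data.frame(substrate = substrate,
                 overall_mean_log10_force = s$overallMean,
                 sem = s$sem, n_samples = s$nSamples,
                 no_significant_binding = s$noSignificantBinding),
      paste0(pfx, "_summary.tsv"), sprov)
  }
  invisible(outputDir)
}

#' Run the substrate-stiffness characterisation study
#'
#' Fits the Hertz model to every curve's approach segment (after baseline
#' correction) and summarises Young's modulus per gel and pooled. Curves
#' whose fit fails (no contact found, too few samples) are logged with the
#' reason and excluded; a gel whose every curve fails is flagged.
#'
#' @param curves list of [ForceCurve]s; gel ids are taken from their
#'   `sampleId`.
#' @param poissonRatio default 0.5.
#' @param maxIndentation nm; `NULL` for the per-curve default (10% of bead
#'   radius).
#' @param params unused stage parameters recorded in provenance.
#' @param outputDir optional directory for provenance-headed TSV output
#'   (per-curve fits and the summary).
#' @param extraProvenance named list merged into provenance headers.
#' @return list with `fits` (data.frame: curveId, gel, youngsModulus,
#'   contactPoint, residualRms, nPointsInContact), `summary` (from
#'   [summarizeModulus()]), `rejected` (data.frame curveId/reason) and
#'   `failedGels`.
#' @export
runStiffnessStudy <- function(curves, poissonRatio = 0.5,
                              maxIndentation = NULL, params = list(),
                              outputDir = NULL, extraProvenance = list()) {
  stopifnot(length(curves) >= 1L)
  fits <- list(); gels <- character(); rej <- list()
  for (cv in curves) {
    res <- tryCatch({
      seg <- getSegment(cv, "approach")
      seg <- baselineCorrect(seg)$segment
      fitHertz(seg, springConstant = cv@springConstant,
               beadRadius = cv@beadRadius, poissonRatio = poissonRatio,
               maxIndentation = maxIndentation)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rej[[length(rej) + 1L]] <- data.frame(curveId = cv@curveId,
                                            reason = conditionMessage(res))
    } else {
      fits[[length(fits) + 1L]] <- res
      gels <- c(gels, cv@sampleId)
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(curveId = character(0), reason = character(0))
  if (length(fits) == 0L)
    stop("no curve could be fitted; see reasons: ",
         paste(unique(rejected$reason), collapse = "; "))
  summary <- summarizeModulus(fits, gels)
  allGels <- unique(vapply(curves, function(cv) cv@sampleId, character(1)))
  failedGels <- setdiff(allGels, gels)
  fitDf <- data.frame(
    curveId = vapply(fits, function(f) f@curveId, character(1)),
    gel = gels,
    youngsModulus = vapply(fits, youngsModulus, numeric(1)),
    contactPoint = vapply(fits, function(f) f@contactPoint, numeric(1)),
    residualRms = vapply(fits, function(f) f@residualRms, numeric(1)),
    nPointsInContact = vapply(fits, function(f) f@nPointsInContact, integer(1)))
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    prov <- c(list(poisson_ratio = poissonRatio,
                   max_indentation_nm = if (is.null(maxIndentation)) "default_0.1R"
                   else maxIndentation),
              params, extraProvenance)
    writeProvenanceTSV(fitDf, file.path(outputDir, "hertz_fits.tsv"), prov)
    writeProvenanceTSV(
      data.frame(mean_E_Pa = summary$meanE, sd_E_Pa = summary$sdE,
                 n_indentations = summary$nIndentations,
                 n_gels = summary$nGels),
      file.path(outputDir, "modulus_summary.tsv"), prov)
    writeProvenanceTSV(rejected, file.path(outputDir, "rejected_curves.tsv"),
                       prov)
  }
  list(fits = fitDf, summary = summary, rejected = rejected,
       failedGels = failedGels)
}
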