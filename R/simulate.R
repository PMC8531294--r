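#' Indentation scenario for synthetic approach curves
#'
#' Bundles the physical parameters of a simulated Hertzian indentation.
#' Defaults mirror colloidal-probe AFM on soft polyacrylamide gels: a
#' 37.28 um diameter bead (radius 18.64 um), spring constant 0.05 N/m and
#' an incompressible gel (nu = 0.5); for stiff gels use radius 5.14 um
#' (10.28 um bead) and k in 0.1-0.3 N/m.
#'
#' @param E_true true Young's modulus, Pa.
#' @param beadRadius um.
#' @param poissonRatio default 0.5.
#' @param springConstant N/m.
#' @param contactPoint piezo height of tip-surface contact, nm.
#' @param noiseSd Gaussian force noise, pN.
#' @param nSamples samples per curve (half pre-, half post-contact).
#' @param maxDelta maximum indentation reached, nm; default 10% of the bead
#'   radius (Hertz validity regime).
#' @param seed integer seed; fixes the noise exactly.
#' @return validated scenario list.
#' @export
indentationScenario <- function(E_true = 750, beadRadius = 18.64,
                                poissonRatio = 0.5, springConstant = 0.05,
                                contactPoint = 1000, noiseSd = 0,
                                nSamples = 600L, maxDelta = NULL,
                                seed = 1L) {
  if (E_true <= 0) stop("E_true must be > 0")
  if (beadRadius <= 0 || springConstant <= 0)
    stop("physical parameters must be positive")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (nSamples < 50L) stop("nSamples must be >= 50")
  if (is.null(maxDelta)) maxDelta <- 0.1 * beadRadius * 1000
  structure(list(E_true = E_true, beadRadius = beadRadius,
                 poissonRatio = poissonRatio, springConstant = springConstant,
                 contactPoint = contactPoint, noiseSd = noiseSd,
                 nSamples = as.integer(nSamples), maxDelta = maxDelta,
                 seed = as.integer(seed)),
            class = "IndentationScenario")
}

#' Simulate a Hertzian approach curve
#'
#' Forward model of the approach segment: zero force before the contact
#' point, Hertz force past it, with the piezo height of each in-contact
#' sample advanced by both the indentation and the cantilever deflection
#' (z = contact + delta + F/k), so the noise-free curve satisfies the Hertz
#' equation exactly in terms of tip-sample separation. Gaussian force noise
#' is added afterwards. Pre-contact span equals the indentation span, and
#' the scenario metadata is embedded in the returned [ForceCurve].
#'
#' @param scenario an [indentationScenario()].
#' @param curveId,sampleId,substrate identifiers for the returned curve.
#' @return a [ForceCurve] with a single approach segment.
#' @export
simulateIndentationCurve <- function(scenario, curveId = "sim_indent",
                                     sampleId = "gel1",
                                     substrate = "hydrogel") {
  stopifnot(inherits(scenario, "IndentationScenario"))
  s <- scenario
  kpn <- s$springConstant * 1000
  nPost <- s$nSamples %/% 2L
  nPre <- s$nSamples - nPost
  delta <- seq(0, s$maxDelta, length.out = nPost)
  f0 <- hertzForce(delta, s$E_true, s$poissonRatio, s$beadRadius)
  zPost <- s$contactPoint + delta + f0 / kpn
  zPre <- seq(s$contactPoint - s$maxDelta, s$contactPoint,
              length.out = nPre + 1L)[seq_len(nPre)]
  z <- c(zPre, zPost)
  force <- c(rep(0, nPre), f0)
  if (s$noiseSd > 0)
    force <- force + .withSeed(s$seed, stats::rnorm(length(force), 0, s$noiseSd))
  ForceCurve(curveId = curveId, sampleId = sampleId, probe = "none",
             substrate = substrate, springConstant = s$springConstant,
             beadRadius = s$beadRadius,
             segments = list(FDSegment("approach", z, force)))
}

#' Simulate a retraction curve with one planted tether rupture
#'
#' The tether is modelled as a linear effective spring loaded from zero
#' separation: while engaged, the tether force is -F_r * s / L_r, where s is
#' the tip-sample separation, and the tether ruptures when s reaches the
#' rupture length L_r (at which point the force is -F_r and the piezo has
#' retracted by L_r + F_r/k). After rupture the force returns to the free
#' baseline. With `ruptureForce = NULL` a pure-noise, event-free curve is
#' produced.
#'
#' @param ruptureForce planted rupture force magnitude, pN, or `NULL`.
#' @param ruptureLength planted rupture length, nm.
#' @param springConstant N/m.
#' @param noiseSd Gaussian force noise, pN.
#' @param nSamples samples in the retract segment.
#' @param pullRange piezo retraction range, nm; default covers twice the
#'   rupture distance plus 100 nm.
#' @param seed integer seed.
#' @param curveId identifier.
#' @return a [ForceCurve] with a single retract segment (piezo height
#'   decreasing, acquisition order).
#' @export
simulateRetractionCurve <- function(ruptureForce = 120, ruptureLength = 80,
                                    springConstant = 0.05, noiseSd = 0,
                                    nSamples = 800L, pullRange = NULL,
                                    seed = 1L, curveId = "sim_retract") {
  kpn <- springConstant * 1000
  ruptureDist <- if (is.null(ruptureForce)) 0 else
    ruptureLength + ruptureForce / kpn
  if (is.null(pullRange)) pullRange <- 2 * ruptureDist + 100
  zStart <- 2000
  z <- seq(zStart, zStart - pullRange, length.out = nSamples)
  pull <- zStart - z
  force <- rep(0, nSamples)
  if (!is.null(ruptureForce)) {
    if (ruptureForce <= 0 || ruptureLength <= 0)
      stop("ruptureForce and ruptureLength must be positive")
    engaged <- pull <= ruptureDist
    sEng <- pull / (1 + ruptureForce / (ruptureLength * kpn))
    force[engaged] <- -(ruptureForce / ruptureLength) * sEng[engaged]
  }
  if (noiseSd > 0)
    force <- force + .withSeed(seed, stats::rnorm(nSamples, 0, noiseSd))
  ForceCurve(curveId = curveId, sampleId = "s1", probe = "anti_FN",
             substrate = "hydrogel", springConstant = springConstant,
             segments = list(FDSegment("retract", z, force)))
}

#' Tether-rupture scenario
#'
#' Describes one probed substrate in a tethering experiment: how many
#' curves are acquired per sample, how often a curve yields no event, what
#' fraction of events are specific (antibody-ECM) tether ruptures, and the
#' lognormal (force, length) distributions of the specific and non-specific
#' populations. Non-specific force and length are positively correlated on
#' the log scale (`nonspecCorr`), as weak adhesions break both early and
#' weakly. The acquisition scale mirrors force-mapping practice (hundreds
#' of curves per sample, grids of 10 x 10 over several regions, 500 pN
#' setpoint).
#'
#' @param label scenario label.
#' @param substrate substrate name.
#' @param stiffnessClass `"soft"` or `"stiff"`; classes are always analysed
#'   separately.
#' @param probe `"anti_FN"` or `"anti_IgG"`.
#' @param nCurves curves acquired per sample.
#' @param noEventProb probability a curve yields no rupture event.
#' @param specificFraction fraction of events from the specific population.
#' @param specForceMedian,specForceSdLog lognormal rupture-force parameters
#'   (median pN, sd of log) of the specific population.
#' @param specLengthMedian,specLengthSdLog same for rupture length (nm).
#' @param nonspecForceMedian,nonspecForceSdLog,nonspecLengthMedian,nonspecLengthSdLog
#'   non-specific population parameters.
#' @param nonspecCorr log-scale correlation of non-specific force and
#'   length.
#' @param setpoint approach force setpoint, pN (metadata).
#' @return validated scenario list.
#' @export
tetherScenario <- function(label = "sample", substrate = "stembond_soft",
                           stiffnessClass = "soft", probe = "anti_FN",
                           nCurves = 600L, noEventProb = 0.2,
                           specificFraction = 0.45,
                           specForceMedian = 300, specForceSdLog = 0.10,
                           specLengthMedian = 80, specLengthSdLog = 0.08,
                           nonspecForceMedian = 30, nonspecForceSdLog = 0.45,
                           nonspecLengthMedian = 15, nonspecLengthSdLog = 0.45,
                           nonspecCorr = 0.9, setpoint = 500) {
  if (specificFraction < 0 || specificFraction > 1)
    stop("specificFraction must be in [0, 1]")
  if (noEventProb < 0 || noEventProb > 1) stop("noEventProb must be in [0, 1]")
  if (min(specForceMedian, specLengthMedian, nonspecForceMedian,
          nonspecLengthMedian) <= 0)
    stop("distribution medians must be positive")
  if (abs(nonspecCorr) >= 1) stop("nonspecCorr must be in (-1, 1)")
  structure(list(label = label, substrate = substrate,
                 stiffnessClass = stiffnessClass, probe = probe,
                 nCurves = as.integer(nCurves), noEventProb = noEventProb,
                 specificFraction = specificFraction,
                 specForceMedian = specForceMedian,
                 specForceSdLog = specForceSdLog,
                 specLengthMedian = specLengthMedian,
                 specLengthSdLog = specLengthSdLog,
                 nonspecForceMedian = nonspecForceMedian,
                 nonspecForceSdLog = nonspecForceSdLog,
                 nonspecLengthMedian = nonspecLengthMedian,
                 nonspecLengthSdLog = nonspecLengthSdLog,
                 nonspecCorr = nonspecCorr, setpoint = setpoint),
            class = "TetherScenario")
}

# Draws one sample's worth of events from a scenario. Assumes the caller
# manages the RNG stream (see simulateTetherStudy / .withSeed).
.drawEventSet <- function(scenario, sampleId) {
  s <- scenario
  nEvents <- stats::rbinom(1, s$nCurves, 1 - s$noEventProb)
  if (nEvents == 0) {
    ev <- data.frame(curveId = character(0), ruptureForce = numeric(0),
                     ruptureLength = numeric(0), specific = logical(0))
  } else {
    isSpec <- stats::runif(nEvents) < s$specificFraction
    nS <- sum(isSpec); nN <- nEvents - nS
    force <- numeric(nEvents); len <- numeric(nEvents)
    if (nS > 0) {
      force[isSpec] <- stats::rlnorm(nS, log(s$specForceMedian), s$specForceSdLog)
      len[isSpec] <- stats::rlnorm(nS, log(s$specLengthMedian), s$specLengthSdLog)
    }
    if (nN > 0) {
      z1 <- stats::rnorm(nN)
      z2 <- s$nonspecCorr * z1 + sqrt(1 - s$nonspecCorr^2) * stats::rnorm(nN)
      force[!isSpec] <- exp(log(s$nonspecForceMedian) + s$nonspecForceSdLog * z1)
      len[!isSpec] <- exp(log(s$nonspecLengthMedian) + s$nonspecLengthSdLog * z2)
    }
    ev <- data.frame(curveId = sprintf("%s_%s_c%04d", s$label, sampleId,
                                       seq_len(nEvents)),
                     ruptureForce = force, ruptureLength = len,
                     specific = isSpec)
  }
  EventSet(ev, sampleId = sampleId, probe = s$probe, substrate = s$substrate,
           stiffnessClass = s$stiffnessClass, nCurvesTotal = s$nCurves)
}

#' Default tether-study scenarios
#'
#' The packaged synthetic study contrasting covalently tethering
#' ("stembond") hydrogels with conventional crosslinker-functionalised
#' ("sulfosanpah") ones: specific ruptures on stembond gels are strong
#' (median 300 pN) and long (median 80 nm); on soft sulfo-SANPAH gels they
#' are equally long but markedly weaker (median 120 pN); on stiff
#' sulfo-SANPAH gels ruptures are control-like — very short and weak — so
#' no specific population is planted and the classifier should report no
#' significant binding. Negative controls (anti-IgG probe) share the
#' non-specific population of their stiffness class and are sampled densely
#' (690 curves/sample) so the control density map is well resolved.
#'
#' @return list with `samples` (three [tetherScenario()]s) and `controls`
#'   (one per stiffness class).
#' @export
defaultTetherScenarios <- function() {
  list(
    samples = list(
      stembond_soft = tetherScenario(
        label = "stembond_soft", substrate = "stembond_soft",
        stiffnessClass = "soft", probe = "anti_FN",
        specificFraction = 0.40),
      sulfosanpah_soft = tetherScenario(
        label = "sulfosanpah_soft", substrate = "sulfosanpah_soft",
        stiffnessClass = "soft", probe = "anti_FN",
        specificFraction = 0.40, specForceMedian = 120, specLengthMedian = 80),
      sulfosanpah_stiff = tetherScenario(
        label = "sulfosanpah_stiff", substrate = "sulfosanpah_stiff",
        stiffnessClass = "stiff", probe = "anti_FN",
        nCurves = 600L, noEventProb = 0.15, specificFraction = 0,
        nonspecForceSdLog = 0.4, nonspecLengthMedian = 8,
        nonspecLengthSdLog = 0.35)),
    controls = list(
      soft = tetherScenario(
        label = "control_soft", substrate = "control_soft",
        stiffnessClass = "soft", probe = "anti_IgG",
        nCurves = 690L, noEventProb = 0.1, specificFraction = 0),
      stiff = tetherScenario(
        label = "control_stiff", substrate = "control_stiff",
        stiffnessClass = "stiff", probe = "anti_IgG",
        nCurves = 690L, noEventProb = 0.1, specificFraction = 0,
        nonspecForceSdLog = 0.4, nonspecLengthMedian = 8,
        nonspecLengthSdLog = 0.35)))
}

#' Simulate a full tethering study
#'
#' Draws `nSamples` independent replicate samples (experiments) for every
#' sample and control scenario. The hidden truth labels (`specific` column)
#' are retained in every event table for downstream evaluation. The whole
#' study is a pure function of (`scenarios`, `nSamples`, `seed`).
#'
#' @param seed integer seed.
#' @param nSamples independent samples per scenario, default 4.
#' @param scenarios as returned by [defaultTetherScenarios()].
#' @return list with `samples` (list per scenario label of [EventSet]
#'   lists) and `controls` (same, per stiffness class).
#' @export
simulateTetherStudy <- function(seed = 1L, nSamples = 4L,
                                scenarios = defaultTetherScenarios()) {
  stopifnot(nSamples >= 1L)
  .withSeed(seed, {
    draw <- function(sc) lapply(seq_len(nSamples), function(i)
      .drawEventSet(sc, sprintf("rep%d", i)))
    list(samples = lapply(scenarios$samples, draw),
         controls = lapply(scenarios$controls, draw))
  })
}

#' Expression-table scenario
#'
#' Planted per-cluster log2 fold-change shifts with Gaussian noise.
#' Default shifts are calibrated so the expected direction fractions match
#' the signature this pipeline is built to detect: with noise sd 0.3, the
#' pre-implantation shift `0.3*qnorm(0.80)` makes 80% of pre-implantation
#' genes up on soft, the post-implantation shift `-0.3*qnorm(0.85)` makes
#' 85% down, ERK-activated genes are ~90% down and ERK-suppressed ~85% up.
#'
#' @param nGenes total genes.
#' @param clusterSizes named integer vector of cluster sizes (remaining
#'   genes get cluster `"none"`).
#' @param clusterShifts named numeric vector of mean log2fc shifts.
#' @param noiseSd Gaussian sd of per-gene log2fc around its shift.
#' @param sigFraction fraction of genes assigned `padj < 0.05`.
#' @param condition condition label.
#' @param seed integer seed.
#' @return validated scenario list.
#' @export
signatureScenario <- function(nGenes = 5000L,
                              clusterSizes = c(pre_implantation = 200L,
                                               post_implantation = 200L,
                                               naive = 50L, formative = 50L,
                                               general = 50L,
                                               erk_activated = 150L,
                                               erk_suppressed = 150L),
                              clusterShifts = c(pre_implantation = 0.3 * stats::qnorm(0.80),
                                                post_implantation = -0.3 * stats::qnorm(0.85),
                                                naive = 0.25, formative = -0.25,
                                                general = 0,
                                                erk_activated = -0.3 * stats::qnorm(0.90),
                                                erk_suppressed = 0.3 * stats::qnorm(0.85)),
                              noiseSd = 0.3, sigFraction = 0.8,
                              condition = "S+L 48h", seed = 1L) {
  if (sum(clusterSizes) > nGenes)
    stop("cluster sizes exceed the number of genes")
  bad <- setdiff(names(clusterSizes), .CLUSTER_LEVELS)
  if (length(bad))
    stop(sprintf("unknown cluster(s) in clusterSizes: %s", paste(bad, collapse = ", ")))
  if (!all(names(clusterSizes) %in% names(clusterShifts)))
    stop("every sized cluster needs a shift")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (sigFraction < 0 || sigFraction > 1) stop("sigFraction must be in [0, 1]")
  structure(list(nGenes = as.integer(nGenes), clusterSizes = clusterSizes,
                 clusterShifts = clusterShifts, noiseSd = noiseSd,
                 sigFraction = sigFraction, condition = condition,
                 seed = as.integer(seed)),
            class = "SignatureScenario")
}

#' Simulate an expression table with planted cluster shifts
#'
#' Per-gene log2 fold change is the cluster shift plus Gaussian noise;
#' adjusted p-values are assigned so that the requested fraction of genes
#' is significant (`padj < 0.05`), uniformly within the significant and
#' non-significant strata. Byte-identical for identical scenarios (seed
#' contract).
#'
#' @param scenario a [signatureScenario()].
#' @return expression table data.frame (see [validateExpressionTable()]).
#' @export
simulateExpressionTable <- function(scenario) {
  stopifnot(inherits(scenario, "SignatureScenario"))
  s <- scenario
  cluster <- rep("none", s$nGenes)
  shift <- rep(0, s$nGenes)
  at <- 1L
  for (cl in names(s$clusterSizes)) {
    n <- s$clusterSizes[[cl]]
    if (n > 0) {
      cluster[at:(at + n - 1L)] <- cl
      shift[at:(at + n - 1L)] <- s$clusterShifts[[cl]]
      at <- at + n
    }
  }
  .withSeed(s$seed, {
    log2fc <- shift + stats::rnorm(s$nGenes, 0, s$noiseSd)
    nSig <- round(s$sigFraction * s$nGenes)
    sig <- sample.int(s$nGenes, nSig)
    padj <- stats::runif(s$nGenes, 0.05, 1)
    padj[sig] <- stats::runif(nSig, 0, 0.05 * (1 - 1e-9))
    validateExpressionTable(data.frame(
      gene_id = sprintf("g%05d", seq_len(s$nGenes)),
      log2fc = log2fc, padj = padj, cluster = cluster,
      condition = s$condition, stringsAsFactors = FALSE))
  })
}
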