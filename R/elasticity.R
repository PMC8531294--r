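#' Hertz contact force for a spherical indenter
#'
#' For a rigid sphere of radius R indenting an elastic half-space of Young's
#' modulus E and Poisson ratio nu to depth delta, the Hertz model gives
#' \deqn{F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}.}
#' Inputs are in the package's working units (nm, um, Pa); the result is in
#' pN. The force is monotone increasing in delta, E and R and scales as
#' \eqn{\delta^{3/2}}.
#'
#' @param indentation numeric vector, indentation depth delta in nm (>= 0).
#' @param E Young's modulus, Pa.
#' @param poissonRatio Poisson ratio, default 0.5 (incompressible hydrogel).
#' @param beadRadius probe bead radius, um.
#' @return force in pN.
#' @examples
#' hertzForce(500, 1000, 0.5, 18.64)  # ~2714 pN
#' @export
hertzForce <- function(indentation, E, poissonRatio = 0.5, beadRadius) {
  if (any(indentation < 0)) stop("indentation must be >= 0")
  if (E <= 0) stop("E must be > 0")
  if (beadRadius <= 0) stop("beadRadius must be > 0")
  if (poissonRatio < 0 || poissonRatio > 0.5)
    stop("poissonRatio must be in [0, 0.5]")
  (4 / 3) * E / (1 - poissonRatio^2) * sqrt(beadRadius * 1e-6) *
    (indentation * 1e-9)^1.5 * 1e12
}

# pN per nm^{3/2} for E = 1 Pa; the Hertz force is linear in E at fixed
# geometry, so E_hat = slope / .hertzUnitSlope(...).
.hertzUnitSlope <- function(poissonRatio, beadRadius) {
  hertzForce(1, 1, poissonRatio, beadRadius)
}

#' Fit the Hertz model to an approach segment
#'
#' Joint estimation of the contact point and Young's modulus. Candidate
#' contact points are taken on the acquisition grid (every sampled piezo
#' height); for each candidate the indentation of the in-contact points is
#' computed as piezo-travel-past-contact minus cantilever deflection, and E
#' follows from a linear least-squares fit of force against
#' \eqn{\delta^{3/2}} through the origin, restricted to
#' \eqn{\delta \le} `maxIndentation` (the Hertz validity window). Candidates
#' are scored by the residual RMS over the entire segment — zero force
#' before the candidate contact, the fitted power law after it (extrapolated
#' beyond the fit window) — so every candidate is judged on the same
#' samples; the minimiser wins.
#'
#' Errors with class `"noContactError"` when no candidate yields a positive
#' modulus with a residual improvement over the flat (zero-force) model;
#' warns when the best contact point sits at the edge of the grid.
#'
#' @param approach a baseline-corrected approach [FDSegment], or a
#'   [ForceCurve] whose approach segment is used (spring constant and bead
#'   radius then come from the curve metadata).
#' @param springConstant N/m (ignored when `approach` is a [ForceCurve]).
#' @param beadRadius um (ignored when `approach` is a [ForceCurve] carrying
#'   one).
#' @param poissonRatio default 0.5.
#' @param maxIndentation nm; default 10% of the bead radius (Hertz validity
#'   regime).
#' @param minContactPoints minimum number of in-contact samples, default 5.
#' @return a [HertzFit].
#' @export
fitHertz <- function(approach, springConstant = NULL, beadRadius = NULL,
                     poissonRatio = 0.5, maxIndentation = NULL,
                     minContactPoints = 5L) {
  curveId <- ""
  if (is(approach, "ForceCurve")) {
    springConstant <- approach@springConstant
    if (is.null(beadRadius) && !is.na(approach@beadRadius))
      beadRadius <- approach@beadRadius
    curveId <- approach@curveId
    approach <- getSegment(approach, "approach")
  }
  stopifnot(is(approach, "FDSegment"))
  if (approach@label != "approach") stop("fitHertz needs an approach segment")
  if (is.null(springConstant)) stop("springConstant is required")
  if (is.null(beadRadius)) stop("beadRadius (um) is required")
  if (is.null(maxIndentation)) maxIndentation <- 0.1 * beadRadius * 1000
  z <- approach@piezoHeight
  f <- approach@force
  n <- length(z)
  if (n < 50L) stop("approach segment must have at least 50 samples")
  kpn <- springConstant * 1000            # pN/nm
  defl <- f / kpn
  unitSlope <- .hertzUnitSlope(poissonRatio, beadRadius)
  rmsFlat <- sqrt(mean(f^2))

  best <- list(rms = Inf, i = NA_integer_, E = NA_real_, nIn = 0L)
  for (i in seq_len(n - minContactPoints)) {
    zc <- z[i]
    delta <- (z - zc) - defl
    incl <- z > zc & delta > 0 & delta <= maxIndentation
    nIn <- sum(incl)
    if (nIn < minContactPoints) next
    x <- delta[incl]^1.5
    y <- f[incl]
    b <- sum(x * y) / sum(x * x)
    if (!is.finite(b) || b <= 0) next
    pred <- rep(0, n)
    inContact <- z > zc & delta > 0
    pred[inContact] <- b * delta[inContact]^1.5
    rms <- sqrt(mean((f - pred)^2))
    if (rms < best$rms)
      best <- list(rms = rms, i = i, E = b / unitSlope, nIn = nIn,
                   signal = max(pred))
  }
  # contact requires both an RMS improvement over the flat model and a
  # fitted contact force that stands clear of the residual noise
  if (!is.finite(best$rms) || best$rms > 0.95 * rmsFlat + 1e-12 ||
      best$signal < 5 * best$rms)
    stop(structure(class = c("noContactError", "error", "condition"),
                   list(message = "no contact point found: no candidate improves on the flat (zero-force) model with positive modulus",
                        call = sys.call(-1))))
  if (best$i == 1L || best$i == n - minContactPoints)
    warning("best contact point lies at the edge of the candidate grid; fit may be unreliable")
  new("HertzFit", youngsModulus = best$E, contactPoint = z[best$i],
      poissonRatio = poissonRatio, beadRadius = beadRadius,
      residualRms = best$rms, nPointsInContact = as.integer(best$nIn),
      curveId = curveId)
}

#' Summarise Young's modulus fits per gel and pooled
#'
#' Pools indentations across gels the way moduli are conventionally reported
#' for hydrogel batches: mean and standard deviation over all indentations,
#' with per-gel means alongside and all counts recorded.
#'
#' @param fits list of [HertzFit] objects.
#' @param gelIds character vector, one gel id per fit.
#' @return list with `meanE`, `sdE` (Pa, pooled over indentations),
#'   `nIndentations`, `nGels`, `perGel` (data.frame gel/meanE/n) and
#'   `singleFit` flag (TRUE when only one indentation, in which case
#'   `sdE` is 0).
#' @export
summarizeModulus <- function(fits, gelIds = rep("gel1", length(fits))) {
  if (length(fits) == 0L) stop("no fits to summarise")
  if (length(gelIds) != length(fits)) stop("one gelId per fit required")
  E <- vapply(fits, youngsModulus, numeric(1))
  perGel <- aggregate(list(meanE = E), by = list(gel = as.character(gelIds)), FUN = mean)
  perGel$n <- as.vector(table(as.character(gelIds))[perGel$gel])
  list(meanE = mean(E),
       sdE = if (length(E) > 1L) stats::sd(E) else 0,
       nIndentations = length(E),
       nGels = nrow(perGel),
       perGel = perGel,
       singleFit = length(E) == 1L)
}
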