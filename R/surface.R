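#' Surface density of ECM anchorage points from co-factor concentration
#'
#' The number of anchorage molecules in a unit cubic volume follows from the
#' molar concentration; the molecules on one face of that cube give the
#' surface density
#' \deqn{\sigma = (N_A \cdot [\mathrm{AHA}])^{2/3} \cdot 10^{-10}}
#' in sites/um^2, where \eqn{N_A} is the Avogadro constant and
#' \eqn{[\mathrm{AHA}]} the molar concentration (mol/L) of the
#' 6-acrylamidohexanoic acid co-factor. The interface takes mM (the
#' concentrations used in practice are 16, 48 and 80 mM); sigma scales as
#' concentration^(2/3), so going from 16 to 80 mM multiplies the density by
#' 5^(2/3) = 2.92, i.e. approximately triples it.
#'
#' @param concentration_mM numeric vector, co-factor concentration in mM
#'   (>= 0).
#' @return surface density, sites/um^2.
#' @examples
#' ligandSurfaceDensity(48)                              # ~9.4e4 sites/um^2
#' ligandSurfaceDensity(80) / ligandSurfaceDensity(16)   # 5^(2/3) ~ 2.92
#' @export
ligandSurfaceDensity <- function(concentration_mM) {
  if (any(!is.finite(concentration_mM)) || any(concentration_mM < 0))
    stop("concentration must be finite and >= 0 (mM)")
  NA_avogadro <- 6.02214076e23
  molar <- concentration_mM / 1000
  (NA_avogadro * molar)^(2 / 3) * 1e-10
}

#' Tabulate ligand surface densities
#'
#' Convenience wrapper returning a data.frame of concentrations, densities
#' and fold change relative to the first concentration.
#'
#' @param concentrations_mM numeric vector, mM.
#' @return data.frame with columns `concentration_mM`,
#'   `sigma_sites_per_um2`, `fold_vs_first`.
#' @export
ligandDensityTable <- function(concentrations_mM = c(16, 48, 80)) {
  sigma <- ligandSurfaceDensity(concentrations_mM)
  data.frame(concentration_mM = concentrations_mM,
             sigma_sites_per_um2 = sigma,
             fold_vs_first = sigma / sigma[1])
}
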