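# MechanoProbe

MechanoProbe is an R package for quantifying the mechanical
microenvironment that functionalised polyacrylamide hydrogels present to
cells, and the transcriptional signature that substrate stiffness leaves
on cells cultured on them. It is aimed at labs characterising
stem-cell-culture substrates by AFM force spectroscopy: how stiff is the
gel, how strongly is the extracellular matrix (ECM) tethered to it, how
many covalent anchorage points does the functionalisation chemistry
provide, and does a gene set respond systematically to soft versus stiff
substrates.

Four quantitative cores, each validated against seeded synthetic data
with known ground truth:

- **Substrate stiffness.** Hertz contact model for a spherical indenter,
  `F = (4/3)·E/(1−ν²)·√R·δ^{3/2}`, fitted to baseline-corrected approach
  segments with a joint grid-scan estimate of the contact point and
  Young's modulus `E`; per-gel and pooled mean ± SD summaries.
- **ECM tethering strength.** Rupture events (force = magnitude of the
  minimal vertical deflection on retraction; length = tip–sample
  separation at that minimum) classified as specific antibody–ECM
  ruptures by a density-ratio criterion against anti-IgG negative
  controls: median thresholds, 2-D density maps on (rupture length,
  log₁₀ rupture force), sample > 2 × control with add-one smoothing of
  the control density, median-filter mask smoothing, and per-sample mean
  log₁₀ rupture force ± SEM.
- **Ligand surface density.** `σ = (N_A·[AHA])^{2/3}·10⁻¹⁰` sites/µm²
  from the molar concentration of the 6-acrylamidohexanoic acid (AHA)
  co-factor whose carboxyl groups anchor ECM proteins.
- **Stiffness signature statistics.** Cumulative log₂ fold change per
  gene cluster (|log₂fc| > 0.2), up/down direction fractions among
  significant genes, ERK-target concordance, and a random-gene-set
  permutation test for systematic soft-vs-stiff regulation.

Seeded generators (`simulateIndentationCurve`, `simulateRetractionCurve`,
`simulateTetherStudy`, `simulateExpressionTable`) produce force curves,
event populations and expression tables with hidden truth labels; the
study drivers (`runStiffnessStudy`, `runTetheringStudy`) tie the stages
together and write byte-reproducible TSV bundles with provenance headers.

## Worked example

Fit a synthetic 750 Pa soft-gel indentation, then run the packaged
tethering study:

```r
library(MechanoProbe)

sc  <- indentationScenario(E_true = 750, noiseSd = 10, seed = 42)
cv  <- simulateIndentationCurve(sc)
seg <- baselineCorrect(getSegment(cv, "approach"))$segment
fitHertz(seg, springConstant = 0.05, beadRadius = 18.64)
#> HertzFit: E = 750.4 Pa, contact at 1000.0 nm, nu = 0.5, 299 points, RMS 10.8 pN

st  <- simulateTetherStudy(seed = 1)
res <- runTetheringStudy(st$samples, st$controls)
res$stembond_soft$summary$overallMean          # 2.478 (log10 pN ~ 300 pN)
res$sulfosanpah_soft$summary$overallMean       # 2.081 (log10 pN ~ 120 pN)
res$sulfosanpah_stiff$summary$noSignificantBinding  # TRUE

ligandDensityTable(c(16, 48, 80))
#>   concentration_mM sigma_sites_per_um2 fold_vs_first
#> 1               16            45280.78      1.000000
#> 2               48            94187.82      2.080084
#> 3               80           132401.81      2.924018
```

The Hertz fit recovers the planted modulus to a fraction of a percent at
10 pN noise. In the tethering study, covalently tethering gels show a
mean significant rupture force of 10^2.478 ≈ 300 pN against ≈ 120 pN on
soft conventional-crosslinker gels, and the control-like stiff
conventional-crosslinker arm correctly reports no significant binding.
Raising the co-factor concentration from 16 to 80 mM multiplies the
anchorage-point density by 5^(2/3) ≈ 2.92 — approximately a tripling.

## Package layout

- `R/` — S4 classes (`ForceCurve`, `EventSet`, `DensityGrid`, …),
  analysis operations, generators, study drivers, TSV dialects.
- `tests/testthat/` — unit, property and end-to-end acceptance tests,
  including independent brute-force oracles for the Hertz contact scan,
  the median filter and event classification.
- `vignettes/mechanoprobe-methods.Rmd` — models, assumptions, parameter
  defaults, generator design and known limitations.
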