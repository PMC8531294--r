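---
title: "MechanoProbe: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MechanoProbe: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(MechanoProbe)
```

MechanoProbe quantifies two mechanical properties of functionalised
polyacrylamide hydrogels from AFM force-distance curves — substrate
stiffness and the strength with which extracellular-matrix (ECM) proteins
are tethered to the gel — and the transcriptional signature that substrate
stiffness imprints on cells cultured on such gels. This vignette explains
the models behind each stage, the tunable parameters and their defaults,
what the synthetic-data generators emulate (and what they deliberately do
not), and the numerical choices made where the underlying procedure leaves
room for interpretation.

## Conventions and units

All analyses work in nm (piezo height, deflection, separation, rupture
length), pN (force), N/m (spring constant; 1 N/m = 1000 pN/nm), µm (bead
radius) and Pa (Young's modulus). Forces pushing the cantilever away from
the surface (indentation) are positive; adhesive tether loads on
retraction are negative; rupture forces are reported as positive
magnitudes. Piezo height increases toward the surface and segments are
stored in acquisition order, so approach segments are strictly increasing
and retract segments strictly decreasing in piezo height. Raw-voltage to
nm conversion (optical-lever sensitivity) is assumed to have happened
upstream in the instrument software; the file reader ingests calibrated
nm/pN tables.

## Baseline correction and contact geometry

Every analysis starts from a baseline-corrected segment: a straight line
fitted on the far-from-surface 30% of samples (where the cantilever is
free) is subtracted from the whole segment, so force is measured relative
to zero load. The 30% default balances leverage for the line fit against
contamination by the contact region; the fit region must contain at least
10 samples. The operation is idempotent up to numerical noise.

Tip-sample separation follows the standard AFM geometry: with piezo
height $z$, contact height $z_c$ and deflection $d = F/k$,

$$s = (z_c - z) + d,$$

so that in contact the indentation depth is $\delta = -s = (z - z_c) - d$.
This is exact for calibrated curves and needs no fixed-point iteration.

## Substrate stiffness: Hertz model

For a rigid sphere of radius $R$ on an elastic half-space,

$$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}.$$

`fitHertz()` estimates the contact point and $E$ jointly. Candidate
contact points are restricted to the acquisition grid (every sampled piezo
height): this keeps the estimator deterministic and checkable against an
exhaustive-scan oracle, and sub-sample contact precision is irrelevant at
realistic noise levels (~10 pN). For each candidate, $E$ follows from an
origin-constrained least-squares fit of force on $\delta^{3/2}$ over the
Hertz validity window $\delta \le$ 10% of the bead radius
(`maxIndentation`). Candidates are compared by the residual RMS over the
*entire* segment — zero force before the candidate contact point, the
fitted power law after it, extrapolated beyond the fit window. Scoring
all candidates on the same samples is essential: scoring each candidate
only on its own fit window would let a candidate that excludes the
high-force region win on a noise-only subset.

A fit is rejected with a no-contact error unless the best candidate both
improves on the flat zero-force model and produces a maximal fitted
contact force at least five residual-RMS above the noise; this cleanly
rejects event-free noise segments, where chance fluctuations across ~100
candidates would otherwise manufacture a tiny spurious modulus.

Defaults: Poisson ratio $\nu = 0.5$ (incompressible hydrogel, standard
for polyacrylamide); bead radius 18.64 µm and $k = 0.05$ N/m for soft
gels, 5.14 µm and 0.2 N/m for stiff ones (colloidal-probe geometries for
these stiffness regimes). Pyramidal-tip (Sneddon) models, viscoelasticity
and bottom-effect corrections are out of scope.

Moduli are summarised per batch as mean ± SD pooled over all
indentations (with per-gel means reported alongside), the conventional
reporting for hydrogel batches probed at several locations over replicate
gels.

## ECM tethering: rupture events and the density-ratio classifier

Rupture events are extracted from baseline-corrected retract segments:
the rupture force is the magnitude of the most negative force (the
minimal vertical deflection) and the rupture length is the tip-sample
separation at that minimum. Anchoring the length at the global force
minimum (rather than at final detachment) matches the deflection-minimum
definition of the force; multi-rupture decomposition, worm-like-chain
contour fitting and loading-rate analysis are not attempted. Curves whose
largest adhesion is below `minForce` (default 20 pN) yield no event.

Specific antibody-ECM ruptures are separated from non-specific adhesion
by comparison with negative-control probes (anti-IgG):

1. force and length thresholds are set at the medians of the control
   distributions, and only events strictly exceeding both survive —
   the thresholds exist to rule out non-specific interactions, so all
   downstream steps operate on the filtered population;
2. sample and control densities are binned on (rupture length,
   log10 rupture force) — force on the log scale, length linear — on a
   shared 30 × 30 grid spanning the pooled retained range padded by 5%;
3. bins where the sample density exceeds twice the control density are
   marked, and the raw mask is smoothed with a 3 × 3 majority-vote median
   filter (FALSE-padded borders, strict majority so ties fall toward
   non-significance);
4. events landing in marked bins are the significant binding events, and
   their per-sample mean log10 rupture force is summarised across
   replicate samples (overall mean of sample means ± SEM). Averaging on
   the log10 scale matches the scale on which rupture forces are
   compared and displayed.

The ratio rule needs care where the control map is finitely sampled. The
control density enters the comparison with one pseudo-event of add-one
smoothing, `control + 1/n_control`: in bins the control never sampled
this reduces to a floor of `ratio/n_control` (a single stray sample event
cannot become significant just because the control is empty there), and
in bins the control sampled only once or twice it discounts chance ratio
exceedances that are within the Poisson noise of the control map. Where
the control is well sampled the smoothing is negligible. Without it,
null-vs-null comparisons at realistic event counts (hundreds of retained
events on a 900-bin grid) retain small clusters of spurious bins through
the median filter in a substantial fraction of runs; with it, both
calibration studies below come out clean.

Soft and stiff substrates are always analysed separately (their own
controls, grids and masks), reflecting the different probe-sample
interaction areas at a fixed setpoint. Samples with zero significant
events are reported as "no significant binding" rather than erroring.

## Ligand surface density

The surface density of covalent ECM anchorage points contributed by the
6-acrylamidohexanoic acid (AHA) co-factor is estimated from its molar
concentration by counting molecules in a unit cube and taking the face of
that cube:

$$\sigma = (N_A \cdot [\mathrm{AHA}])^{2/3} \cdot 10^{-10}
\ \text{sites/µm}^2,$$

with the interface in mM. The estimator scales exactly as
concentration$^{2/3}$, so increasing AHA from 16 to 80 mM multiplies the
density by $5^{2/3} \approx 2.92$ — approximately a tripling.
Incorporation efficiency and saturation at high AHA are not modelled.

## Stiffness-signature statistics

Differential-expression estimation (log2 fold change soft/stiff, adjusted
p) is an upstream input; the package computes the statistics layered on
top of such tables:

- **Cumulative log2fc** per gene cluster over genes with |log2fc| > 0.2.
  Genes are ordered by descending |log2fc| (ties by gene id) purely for
  plotting; the endpoint, the interpretable quantity, is order-invariant.
  Opposing systematic stiffness effects on the pre- and post-implantation
  clusters appear as series diverging to endpoints of opposite sign.
- **Direction fractions**: among significantly regulated genes of a
  cluster (padj < 0.05), the percentages up and down on soft; zero-fold
  genes are excluded from the denominator so the percentages always sum
  to 100 when defined.
- **ERK concordance**: direction fractions for ERK-activated and
  ERK-suppressed target clusters, plus mean |log2fc| of ERK targets
  against non-target genes.
- **Permutation test** for systematic regulation of a gene selection:
  the observed statistic is the set's mean log2fc; the null draws random
  gene sets of identical size without replacement from the table (the
  natural null for "a selection of genes" against the transcriptome
  background — sign-flipping would instead test symmetry of the fold
  changes); the two-sided p-value compares magnitudes with the add-one
  correction $p = (1 + \#\{|t^*| \ge |t|\})/(n_{perm}+1)$, so $p > 0$
  always and $p = 1$ in the degenerate whole-table case.

## What the generators emulate — and what they do not

The synthetic generators provide ground truth for every stage and define
the package's validation conditions.

**Indentation curves** follow the exact Hertz forward model (zero force
before contact; past contact each sample's piezo height is advanced by
indentation plus deflection) with additive Gaussian force noise. They do
not emulate drift, hydrodynamic drag, tilt or substrate-bottom effects.

**Retraction curves** model a tether as a linear effective spring loaded
from zero separation, rupturing at the planted (force, length); the
analysis only consumes the rupture coordinates, so the simplest monotone
loading suffices and keeps round-trip oracles analytic. Thermal ringing
and multiple simultaneous tethers are not simulated.

**Tether studies** draw (force, length) pairs directly from lognormal
populations: a specific population (StemBond-like gels: median 300 pN,
80 nm; soft conventional-crosslinker gels: median 120 pN, same length)
and a non-specific population (median 30 pN, 15 nm, log-scale
correlation 0.9) shared with the anti-IgG controls; the stiff
conventional-crosslinker scenario plants no specific population and
control-like very short lengths (median 8 nm), so the expected outcome is
"no significant binding". The acquisition scale mirrors force-mapping
practice — hundreds of curves per sample (600 for samples, 690 for
controls, within the tens-to-hundreds per sample typical of grid
acquisitions), four independent replicate samples, 500 pN setpoint. The
narrow specific distributions (log-sd 0.10 in force, 0.08 in length)
describe a single well-defined antibody-antigen bond rupturing at a fixed
loading rate; the dense, correlated control population keeps the control
density map well resolved, which the ratio classifier needs to reach its
operating point (≥90% recovery of planted specific events at zero
null-study leakage across the seeds examined during design). All
magnitudes are generator conventions, not measurements; passing tests
demonstrates the pipeline's internal consistency and statistical
calibration on these conditions, not agreement with any particular
instrument's data.

**Expression tables** plant per-cluster mean shifts with Gaussian noise
(sd 0.3) at the log2fc level — no negative-binomial count simulation —
and assign adjusted p-values to hit a requested significant fraction
(default 0.8). Default shifts are calibrated through the Gaussian
quantile so the expected direction fractions match the signature the
statistics are meant to detect: pre-implantation genes 80% up on soft,
post-implantation 85% down, ERK-activated ~90% down, ERK-suppressed
~85% up, with ERK targets carrying larger |log2fc| than non-targets.

All generators are pure functions of their scenario: identical seeds give
byte-identical output, and the seeded-run bundles written by the study
drivers (TSV with `#`-prefixed provenance headers recording every
parameter and seed, no timestamps) are byte-reproducible.

## Problem sizes used in the packaged validation

The shipped tests and the acceptance script validate at desk scale:
Hertz-oracle equivalence on 50 curves of 120-500 samples; modulus
recovery at E ∈ {300, 750, 3000, 16000} Pa with 50 seeded replicates
each (observed bias well under 1%); classifier null calibration on 20
seeded 500-vs-500-event studies; the default tether study (three
substrates × 4 samples plus two control arms); permutation calibration
over 1000 runs of 999 permutations on a 5000-gene table. These sizes
were chosen to give stable Monte-Carlo estimates while keeping a full
validation run in the order of a minute.

## Known limitations

- The contact-point search is grid-resolution limited; curves sampled
  very coarsely near contact will inherit that quantisation in E.
- The density-ratio classifier is calibrated for the event counts it was
  designed around (hundreds of retained events); very sparse studies
  (tens of events) leave the control map under-resolved, and the
  pseudo-event floor then makes the classifier conservative.
- Rupture extraction reports one event per curve (the global minimum);
  curves bearing several comparable ruptures are summarised by the
  strongest one.
- Expression statistics treat genes as exchangeable and independent;
  correlated co-expression inflates the permutation test's effective
  sample size in ways the random-gene-set null does not model.
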