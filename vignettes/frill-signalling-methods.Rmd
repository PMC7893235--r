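---
title: "Methods: whole-skull shape analysis for socio-sexual signalling tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-skull shape analysis for socio-sexual signalling tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(protomorph)
```

`protomorph` tests four predictions of socio-sexual signalling on
high-density 3D landmark data from a growth series of skulls: the putative
signal trait (the ceratopsian parietal-squamosal frill is the motivating
case) should (1) form its own phenotypic module, (2) show strong positive
allometry in size and shape, (3) carry the most size-independent variance,
and (4) possibly show shape dimorphism. This vignette explains the models
and procedures behind each stage, the tunable parameters, the numerical
choices, and what the synthetic generator does and does not emulate.

## Data model and superimposition

A *landmark scheme* fixes identity, type (fixed, curve semilandmark,
surface semilandmark), module label, midline flag and bilateral pairing for
every landmark; configurations are `k x 3` matrices in scheme order, with
`NA` rows for absent landmarks (partial specimens). A module counts as
present only when all its landmarks are.

Alignment is generalized Procrustes analysis: configurations are centred,
scaled to unit centroid size, and iteratively rotated to the evolving
consensus until the summed squared residual changes by less than `tol`
(default `1e-10`, at most 100 sweeps; non-convergence is an error carrying
the last change). The consensus is initialised from the first specimen and
the finished solution is rotated into a canonical orientation (principal
axes of the consensus with a deterministic sign rule), which makes the
output invariant to input order and to arbitrary rigid motions or
rescalings of individual specimens — properties the test suite checks to
`1e-8`. Reflections are never admitted inside alignment (anatomy is
chiral); mirroring happens only through the explicit reflection operations.
Tangent-space projection is not applied at storage time; the regression and
PCA stages operate on the aligned coordinates directly, which is adequate
because shape variation in a single-species growth series is small.

Skulls are bilaterally symmetric, and specimens of different widths can
pull a plain alignment off the midline. `symmetricGPA()` therefore doubles
each configuration with its mirror image across its own estimated sagittal
plane (a total-least-squares fit through the midline landmarks; at least
three non-collinear ones are required), aligns the doubled set, and drops
the mirrored half; the kept halves are re-centred and rescaled to unit
centroid size so the usual invariants hold, while centroid sizes are always
reported for the original configurations. Specimens preserved only on the
left side are reflected into canonical right-side form with
`mirrorIncompleteSide()` (an exact involution).

Retrodeformation is implemented at the landmark level: each landmark is
averaged with the reflection of its bilateral partner across the estimated
sagittal plane (midline landmarks are projected onto the plane), yielding
an exactly mirror-symmetric, idempotent result. Obliquity — the angle
between the fitted sagittal plane normal and the dominant direction of the
pair differences — gates the operation at 10° by default, mirroring the
practice of only retrodeforming mildly distorted material. This is a
deliberate surrogate for mesh-based retrodeformation protocols, which need
surface models that are out of scope here.

## Semilandmark sliding

Curve and surface semilandmarks have arbitrary positions along their
structure, so their spacing is treated as a nuisance. Sliding displaces
each semilandmark in its local tangent space — a 1D tangent from central
differences along the stated curve order, or the two leading principal
directions of its 8-nearest-neighbour cloud for surface points (neighbour
sets fixed from the consensus for determinism) — so that the thin-plate
spline bending energy of the deformation from the consensus to the specimen
is minimised. With the 3D kernel `U(r) = -r` (the sign that makes the
bending quadratic form positive semidefinite: distance matrices are
conditionally negative definite), the constrained minimiser is a linear
solve; fixed landmarks never move. The cycle slide / re-align / update
consensus runs `iterations = 3` times by default — the energy drop is
dominated by the first pass, and within each pass the energy cannot
increase by construction, which the tests verify together with a
grid-descent oracle on a toy curve. Sliding is tangent-only: there are no
meshes to re-project onto.

## Allometry

Shape is regressed on centred natural-log centroid size (natural log is a
base choice only; log-log slopes and p-values are base-invariant).
R² is the explained fraction of total squared coordinate variation; its p
comes from 999 seeded permutations of the size labels. The normalised
coefficient vector is the common allometric component (CAC); residual shape
components are the principal directions after partialling the CAC-score
direction out of the data, so their scores are exactly uncorrelated with
the CAC scores. `allometryCorrect()` returns consensus-plus-residuals and
feeds every downstream stage.

Module growth is summarised two ways, as in comparative practice: the
log-log slope of module centroid size on whole-skull centroid size
(isometry = 1), using sizes recorded from the original, unscaled
configurations; and the slope of the module's own CAC score on log
whole-skull size (no shape change = 0), with the CAC sign fixed so scores
correlate positively with size. Slopes are compared pairwise by ANCOVA
interaction F-tests; fits always retain intercepts (forcing them to zero
would bias slopes and is treated as a display convention only). Partial
specimens contribute to every module they preserve completely.

## Modularity

The congruence matrix correlates the stacked 3D deviation vectors of every
landmark pair across specimens. The maximum-likelihood scan assigns the
absolute off-diagonal coefficients to correlation classes per hypothesis —
one class per within-module set, and both a pooled and a separate
between-module variant — estimates each class mean, and scores a Gaussian
likelihood on the Fisher-z scale with sampling variance `1/(n - 3)`
(|r| clamped at 0.999999 to avoid infinities; n ≤ 3 is an error). AICc uses
parameter count = classes + 1 and sample size = number of landmark pairs; a
single-correlation null model is always included, and Akaike weights are
normalised over every model evaluated. Because high-density data
over-split, modules whose between-module class mean comes within 0.1 of the
lowest within-module mean are merged transitively (connected components),
once, on the AICc-best hypothesis; the between means are recomputed
directly from the congruence matrix so the rule is indifferent to whether
the winning variant pooled its between classes. The default hypothesis set
is a nested scan from two modules to eight (splitting the largest modules
in half); the set is ordinary user configuration via a YAML file, since any
concrete anatomical hypothesis list is study-specific.

The covariance ratio compares summed squared between-block covariances to
the geometric mean of the within-block ones (diagonal cells excluded),
averaged over module pairs; values below 1 indicate modularity.
Significance comes from permuting whole landmarks (x, y, z kept together)
across modules, preserving module sizes, with the smoothed p-value
`(b + 1)/(m + 1)` counting permuted values at or below the observed one
(ties count as extreme). All permutation and Monte-Carlo procedures take
seeds and default to 999 draws.

## Disparity and dimorphism

Per-landmark Procrustes variance is the mean squared 3D deviation from the
mean configuration with divisor `n - 1`; module variances are sums over
their landmarks, additionally divided by landmark count so modules of
different density are comparable. For the raw variant deviations are taken
from the mean of the aligned coordinates, for the corrected variant from
the allometry-corrected ones. Disparity-covariate relations (against
growth rate or within-module correlation) are ordinary least squares with
two-sided slope t-tests.

Hartigans' dip statistic is the smallest sup-norm distance between the
empirical CDF and any unimodal CDF. It is computed exactly: for a candidate
mode position, a unimodal CDF within distance `d` exists precisely when the
forced minimal values of a convex chain through the data "gates" stay
inside them on the left, the mirrored condition holds on the right, and the
two branches are compatible at the mode (an atom is allowed there);
bisection on `d` over all candidate modes gives the dip to ~1e-14. The
implementation was validated against a linear program transcribed directly
from the definition on hundreds of random samples including ties; that LP
remains in the test suite as the small-`n` oracle. The dip test simulates
the uniform null — the asymptotically least favourable unimodal law —
with 10,000 seeded Monte-Carlo samples by default; precomputed null tables
can be passed in and are cached per sample size inside the scan.

The dimorphism scan removes allometry from each supplied dataset variant
(whole skull, modules in the global alignment, modules aligned separately
with partial specimens included), takes the first eight residual shape
components, and dip-tests each. No multiple-testing correction is applied —
per-component p-values are reported raw, together with the number of flags
expected by chance — and the whole scan repeats with the smallest
("juvenile") specimens removed. Juveniles are flagged by a deterministic
rule replacing the visual cluster identification of practice: everything
below the largest gap in sorted log centroid size, provided that gap
exceeds twice the median adjacent gap. This default follows the module's
design decision but is conservative toward flagging — random uniform size
samples frequently exceed a ratio of two — so the juveniles-removed variant
is often populated even without true juveniles; the factor is configurable.

## The synthetic generator

`simulateDataset()` draws from the linear structure the analysis assumes:
shape = consensus + (centred log size) × allometric fields + module factors
+ a global factor + optional sex offset + iid coordinate noise, followed by
per-module rescaling by size^(β − 1) about the module centroid, optional
dorsoventral compression, exact scaling to the target centroid size, and a
random rigid motion. Factor scores are orthonormalised in-sample against
the size axis, so planted variance fractions hold exactly in the noiseless
limit, and the defaults are the study conditions throughout the tests:
five modules of 20 landmarks (60 on the analysis side), 30 complete + 14
partial specimens, β = (1.4, 1.1, 1.0, 1.0, 0.9) with the frill on top,
allometric fraction 0.5, within/between congruence targets 0.6/0.25,
relative deviation scales (2.2, 1.2, 1.6, 1.2, 1.0) so the frill carries
the most size-independent variance, log sizes uniform over a four-fold
range, coordinate noise σ = 0.01 (about 7% of a module's radius — large
enough that the non-allometric variance leaves headroom for the allometric
fraction, small enough that the nonlinear interaction of the calibrated
allometric fields with module centroid sizes stays within the ±0.05
slope-recovery band), and no dimorphism by default.

Several design choices exist purely to make planted truth survive the
pipeline, and are worth knowing when interpreting recovery results:

* All effect fields are projected orthogonal to the similarity tangent
  space at the consensus (translations, rotations, scaling), because GPA
  silently removes those components from any deviation; allometric fields
  are additionally made neutral to every module's own centroid-size
  direction so they cannot bias the planted β exponents.
* Factor fields are mirror-symmetric constant directions per module, chosen
  among candidates by how coherent the module's rows remain *after* the
  projections — the projection can otherwise turn a common direction into
  landmark-dependent ones and destroy the planted congruence. Module arc
  positions are assigned centre-out for the same reason: peripheral modules
  have long rotation levers and suffer most under alignment.
* The allometric shape magnitude is calibrated empirically (root-finding on
  the realised in-sample R²) because the β rescaling itself contributes
  size-correlated shape variance that an analytic calibration misses.
* The dimorphic offset displaces each landmark of the target module by (in
  root mean square) `dimorphismDelta` times the module's total within-sex
  per-coordinate deviation (factors plus noise), along a direction
  orthogonalised against the factor fields. A separation of four within-sex
  standard deviations along a single direction is near the dip test's power
  floor at realistic sample sizes, so the offset is defined per landmark —
  a frill-wide 4σ shift — which the scan detects reliably at n = 44.

What the generator does *not* emulate: digitisation error correlated along
surfaces, mesh geometry (sliding has nothing to re-project onto),
non-affine taphonomic bending or torsion, missing landmarks within a module
(modules are present or absent as wholes), allometric curvature (growth is
log-linear), and phylogenetic or temporal structure. Passing recovery tests
therefore demonstrates the pipeline's correctness on data satisfying its
own assumptions, not robustness to every way real fossils violate them.
Between-module congruence is also heterogeneous around its target, because
the similarity projection residue of each module's field couples
neighbouring modules — an alignment artefact real data share.

## Problem sizes and reproducibility

The packaged study sizes are desk-scale by design: the default scheme has
100 landmarks (60 on the analysis side), and the recovery studies in the
test suite use 100 replicates at n = 30 (slope ranking, disparity, R²),
100 replicates of k = 60 / n = 50 correlation simulations (module
hypothesis recovery), 500-replicate calibrations of the covariance-ratio
and dip tests at reduced n, and 60 replicates at n = 44 for the dimorphism
scan. Every stochastic step takes an explicit seed; the pipeline derives
its stage seeds from the root seed by fixed offsets, so a configuration
reproduces its report byte for byte. The full analysis on the default
preset runs in seconds.

## Known limitations

* The dip scan tests principal components, which mix near-degenerate
  variance directions; a dimorphic contrast hiding below the leading
  directions of a high-dimensional shape space can escape an
  eight-component scan even when it is detectable along the exact contrast.
* The merge rule is applied once to the AICc-best hypothesis, not
  iteratively re-fitted; strongly chained between-module correlations merge
  transitively.
* Obliquity, and hence retrodeformability, is estimated from bilateral pair
  differences; configurations without usable pairs fall back to midline
  projection only.
* Procrustes alignment spreads strictly local variation across all
  landmarks; congruence- and covariance-based modularity statistics inherit
  this, which is why the covariance ratio is compared against its own
  landmark-permutation null rather than against an absolute threshold.
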