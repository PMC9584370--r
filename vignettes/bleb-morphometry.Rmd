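---
title: "Morphometry of glaucoma drainage implant blebs: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of glaucoma drainage implant blebs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blebquant)
```

## The measurement problem

A Baerveldt glaucoma implant drains aqueous humour through a tube onto a
silicone plate placed under the rectus muscles. The plate becomes encapsulated
by fibrotic tissue, forming one or two fluid reservoirs — an *inner bleb*
between globe and plate and an *outer bleb* on top of the plate. The space the
whole complex (inner bleb + plate + outer bleb) occupies in the orbit is the
clinically interesting quantity: a sufficiently large complex can mechanically
restrict eye movement and cause double vision (diplopia).

`blebquant` quantifies this complex from labelled 3D segmentations (typically
derived from high-field MR images): per-compartment volumes, the complex
height perpendicular to the plate, a merged-bleb flag, and a large-bleb
classification, plus the clinical classifiers and nonparametric group
statistics used to compare patients with and without diplopia.

The pipeline deliberately starts from label maps or meshes. Image-intensity
segmentation is out of scope; in the originating workflow it was a
semi-automated, operator-checked step that no algorithmic re-implementation
could reproduce faithfully.

## Geometry pathway

### Surface extraction

`extract_surface()` runs marching tetrahedra over a Kuhn (six-tetrahedron)
decomposition of the voxel lattice at the 0.5 iso-level. We chose marching
tetrahedra over classical marching cubes because tetrahedral cases are
unambiguous: the result is guaranteed to be a closed, consistently oriented
2-manifold (every edge shared by exactly two faces) for *any* binary mask,
which downstream inside/outside tests require. Masks touching the grid
boundary are implicitly padded with one voxel of background so surfaces always
close.

### Smoothing

The original analysis fitted subdivision surfaces with a proprietary tool; the
control-mesh layout and convergence criteria of that step are not public, so
no faithful re-implementation is possible. `smooth_fit()` instead applies
Taubin lambda/mu smoothing (alternating shrink/inflate Laplacian passes,
defaults `iterations = 10`, `lambda = 0.5`, `mu = -0.531`) with an explicit,
testable contract: the enclosed volume changes by less than 1% at default
settings, and connectivity — hence watertightness — is untouched. The tests
assert the contract, not similarity to the proprietary output, which cannot be
verified.

### Voxelization

`voxelize_mesh()` rasterizes a watertight mesh onto an isotropic grid by z-ray
crossing parity: a voxel is inside iff its center is inside the surface. The
stated analysis resolution of the source workflow, an "isotropic resolution of
0.1 mm", is read as a 0.1 mm voxel *edge* (voxel volume $10^{-3}$ mm³), since
"isotropic" qualifies a length; the resolution is a plain argument, so any
value can be used. Voxel centers snap to integer multiples of the resolution,
which makes voxelizing a surface extracted from a commensurate grid lossless
(Dice 1 in the round-trip test). Two deterministic epsilons resolve measure-zero
degeneracies: ray columns are offset by ~$10^{-3}$ voxel (irrational multiples,
so lattice-aligned mesh edges are never hit exactly), and crossing depths are
nudged by $10^{-7}$ voxel so surfaces passing exactly through voxel centers
resolve consistently (an axis-aligned unit cube at 0.1 mm yields exactly
1000 voxels).

Center-inside counting is an unbiased volume estimator for closed surfaces;
the tests require a 5 mm sphere at 0.1 mm to be within 0.5% of
$\tfrac{4}{3}\pi 5^3 = 523.599$ mm³.

## Measurement pathway

### Gap closure

Because components are segmented independently, hairline background slivers
can remain between plate and blebs. `close_gaps()` formalizes the "cascade of
morphological operations" as a nearest-component fill with two guards: a
background voxel is filled iff

1. its nearest component and the nearest *different* component are both within
   `max_gap` (default 0.3 mm — about three voxels at 0.1 mm; the source
   workflow named no radius), and
2. it lies *between* them: the displacement vectors to the two components
   subtend an obtuse angle.

Guard 2 distinguishes a genuine inter-surface gap from background at corners
where components already touch and from genuine holes (the plate
fenestrations), making the operation idempotent on gap-free segmentations.
Filled voxels take the nearer component's label, distance ties going to the
lower label id, with a deterministic lexicographic tie-break on equidistant
displacement directions so results are exactly reproducible and equal to a
brute-force oracle on small grids.

### Plate plane and complex height

"Perpendicular to the plate" needs a single direction even though the plate is
curved. We use the minor principal axis of the plate voxel cloud (direction of
least variance), oriented away from the globe center — reproducible, and for a
symmetric spherical patch it coincides with the patch axis.

Height is computed column-wise: complex voxels are projected onto the plate
plane, binned into columns one voxel wide, and within each column containing
both bleb types the span is (highest outer-bleb projection − lowest inner-bleb
projection + one voxel). The one-voxel term compensates voxel centers sitting
half a voxel inside each outer surface. The maximum span over columns is the
height. Column-wise spans keep this a through-thickness measurement: a global
max-minus-min would happily pair laterally distant surface points. When a
merged complex has a single bleb label, that label plays both roles; how the
original analysis measured its six merged cases is unstated, so this fallback
is a recorded convention, as is the one-voxel surface term (whether the
capsule wall is included in the published heights is equally unstated).

### Merged blebs and the large-bleb flag

Blebs are *merged* when inner and outer masks have face-adjacent voxels away
from every fenestration axis (within one fenestration radius + two voxels of
an axis, contact is attributed to the fibrotic strands that grow through the
plate holes by design and does not count). Without fenestration geometry the
rule degrades to any-contact and flags itself in the result provenance.

`classify_large_bleb()` applies the strict threshold: total complex volume
> 1100 mm³.

## The synthetic phantom

`make_phantom()` builds label maps with analytically known ground truth: a
spherical globe (default radius 11.5 mm); a plate modelled as a spherical-shell
patch concentric with the globe (the implant conforms to the sclera; default
arc extent 32 × 14 mm, 1 mm thick — a 350 mm²-class device), with four
fenestration channels whose contents carry bleb labels (emulating strands
connecting the blebs); and inner/outer bleb shells of configurable thickness
(default 2 mm each). With `merged = TRUE` the bleb footprint extends past the
plate rim and the shells meet around the edge, reproducing the
plate-floating-in-one-bleb configuration seen in 6/30 study patients. The
default grid spacing, 0.4 mm, is the reconstruction resolution of the source
images. No MR signal, noise or artefact is simulated — phantoms are label
maps, not images — so passing recovery tests demonstrate the correctness of
the geometry and measurement code, not robustness to segmentation error.

Ground-truth volumes are exact voxel counts of the generated map (additivity
is exact by construction). Ground-truth *height* deserves a note: for a curved
shell, the maximum column-wise span is attained at the bleb footprint edge and
exceeds the apex thickness sum — analytically
$\sqrt{R_4^2 - R_1^2\sin^2\theta_b} - R_1\cos\theta_b$, where $R_1$ is the
globe radius, $R_4$ the outer bleb outer radius and $\theta_b$ the largest
bleb half-angle. `truth$height` is this value, consistent with what the
measurement defines; `truth$height_apex` is the plain inner + plate + outer
sum (they coincide as the footprint narrows). The globe is not stated in the
source study (nor is plate curvature); 11.5 mm and the footprint defaults are
conventions of this package, not study values.

## The cohort simulator

`simulate_cohort()` draws per-patient records matching the study conditions:
12 diplopia vs 18 control patients; total complex volume log-normal with
population median equal to the group median (1023.3 vs 804.6 mm³) and
`sdlog = log(q3/q1)/(2 z_{0.75})` so the quartile *ratio* matches the reported
IQR (a two-parameter distribution cannot also match both quartiles
individually; the published summaries give only median and IQR, not a
distribution — log-normal is the standard right-skewed positive model).
Height follows a cube-root link, `h = h_med (V/V_med)^{1/3} e^{\epsilon}`
with 6% log-normal noise — dimensional consistency, since no height-volume
relation is published. The plate contributes a near-constant ~280 mm³
(350 mm² footprint × ~0.8 mm), and the remainder is split between inner and
outer bleb by a Beta draw with mean matching the reported compartment medians.
Visual-field MD, IOP at four timepoints, demographics and restriction
frequencies (83% vs 33%) use the published group summaries. All draws funnel
through the single spec seed; the same seed reproduces the table byte for
byte.

## Statistics

Quartiles use inclusive linear interpolation (type 7); the rule is fixed and
recorded so summaries are reconcilable against alternative quartile
conventions. The test mapping follows the study: unpaired *t* (pooled by
default; Welch by flag) for age, IOP and follow-up time; Fisher's exact test
for counts; Mann-Whitney for visual field, volumes and height; Spearman for
correlations, with the diplopia indicator coded 1/0 and ranked like any other
variable. No multiplicity adjustment is applied, matching the original
analysis (each variable tested separately, α = 0.05).

Implementation rides on R's `stats` machinery (`wilcox.test`, `fisher.test`,
`t.test`), with conventions pinned down: Mann-Whitney is exact for pooled
n ≤ 20 without ties and tie-corrected normal with continuity correction
otherwise (so 12-vs-18 comparisons use the approximation, as common practice);
U is reported as min(U₁, U₂); Spearman p is an exact full-permutation value
for n ≤ 9 (valid under ties) and a t-approximation otherwise. Every p-value
path is checked against independent brute-force enumeration oracles in the
test suite, and the type-I error of both group tests at n = 12 vs 18 is
required to sit at 5% ± 1.5 points over 2000 null simulations.

## Validation sizes and numerical choices

The test suite and the acceptance script validate recovery on a fleet of 50
randomized phantoms at 0.25 mm grid spacing (globe 11–12 mm, shells 1–3 mm,
random plate orientation, ~20% merged) plus compact-geometry phantoms at the
full 0.1 mm analysis resolution; these sizes keep a complete validation run in
a few minutes of one CPU while exercising every code path at the analysis
resolution. Tolerances are 1% for compartment volumes against construction
ground truth, two voxel spacings for height, and exact agreement for the
merged flag. Rotating the phantom geometry must change volumes by < 1% and
height by < 2 voxels (rotation equivariance up to discretization).

Degenerate inputs fail loudly and specifically: empty components, plates with
fewer than 10 voxels or no unique minor axis (relative eigengap < 10⁻⁶),
non-watertight meshes, anisotropic grids where isotropy is assumed, negative
volumes in cohort tables (row-level rejection), constant inputs to
correlation. Boundary conventions are explicit: MD of exactly −6 or −12 dB
falls in the worse visual-field band (the published strict inequalities leave
the boundaries undefined); a duction loss of exactly 10° counts as restricted
("at least 10°"); a total volume of exactly 1100 mm³ is *not* large (strict
inequality). The "total amount of motility restriction" used in correlation is
implemented as the summed degrees lost over flagged directions — the study
does not define it numerically, so this is a recorded convention. Normative
duction ranges ship as an editable CSV because the study cites an external
normative source without printing values.

## Known limitations

* Phantoms are geometric idealizations; no segmentation noise, partial-volume
  effects or capsule-wall ambiguity is modelled. Recovery results validate the
  measurement code, not the upstream segmentation.
* The smoothing stand-in shares only a contract (volume preservation), not an
  algorithm, with the original subdivision fitting.
* The simulator matches published group summaries, not joint distributions;
  correlations among simulated covariates are only as real as the links coded
  here.
* Height for merged complexes follows the single-label fallback convention;
  the original choice is unknown.
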