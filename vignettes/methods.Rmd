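---
title: "Quantifying and grading breast tumors in 3-D ultrasound: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and grading breast tumors in 3-D ultrasound: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echograde)
```

`echograde` turns a volumetric breast ultrasound image and a binary lesion
segmentation into 44 quantitative features and a cross-validated low- versus
high-grade classifier. This vignette records the models, the conventions, and
the design choices that were genuinely open — the things a maintainer would
otherwise have to reverse-engineer from the code.

## Coordinate and intensity conventions

Every array is indexed `[depth, lateral, lateral]`: axis 1 is the beam
direction, with larger indices farther from the transducer ("deeper"). A
C-view section is a constant-axis-1 slice; an A-view plane contains axis 1.
"Beneath the lesion" always means larger axis-1 index. Gray levels are 8-bit
(0–255); values outside that range on input are an error unless clipping is
requested, because the fixed global scale is what makes texture and
posterior features comparable across cases. Voxel spacing is carried in mm
and used by every metric feature (volume, area, radius); texture
displacements are lattice vectors and deliberately ignore spacing. An
optional nearest-neighbour isotropic resampler (`resample_isotropic()`) is
provided for strongly anisotropic acquisitions but is off by default: the
target acquisitions are near-isotropic (≈0.2 mm), and resampling changes
the lattice the co-occurrence displacements live on, so it must be an
explicit user decision.

## Texture: directed 3-D co-occurrence

The volume is re-quantized to 16 levels by `g -> floor(16 g / 256)` on the
fixed scale — *not* per-lesion min–max stretching, which would erase
cross-case contrast differences that the posterior features also rely on.
For each displacement d ∈ {(1,1,1), (1,0,0), (0,1,0), (0,0,1)} the matrix
counts pairs (v, v+d) with *both* endpoints inside the mask. Two open
choices were fixed and tested rather than left implicit:

* the matrix is **directed** (unsymmetrized); `glcm(-d)` is the transpose of
  `glcm(d)`, and a property test asserts exactly that;
* pairs crossing the mask boundary are excluded, so the statistics describe
  the lesion interior only.

Six Haralick statistics summarise each matrix (angular second moment,
contrast, inverse difference moment, entropy with natural log, dissimilarity,
correlation). A constant region has zero marginal variance; its correlation
is *defined* as 1 (a constant region is perfectly predictable), and a mask
too thin to form any pair along some displacement yields `NA` for that
displacement's six statistics — the classifier refuses missing values
rather than imputing them.

## Morphology

Volume is voxel count × voxel volume. Surface area is the area of a
0.5-level isosurface mesh: marching tetrahedra (six tetrahedra per lattice
cell) on the one-voxel-padded mask, followed by Taubin's λ/μ mesh smoothing
(λ = 0.5, μ = −0.505, 100 iterations). The smoothing step is load-bearing:
the raw mesh of a digitized ball overestimates 4πr² by ≈9% because of
staircase facets, while Taubin relaxation is shrink-compensated, so it
removes the staircase without deflating the surface. With the defaults a
radius-15 ball's area is reproduced within ≈1% and a 10-voxel cube's within
≈8% (sharp edges are genuinely chamfered by any smoothing; the residual is
documented and tested). Classical compactness is normalized as 36πV²/A³ so
a continuum sphere scores exactly 1. Discrete compactness uses Bribiesca's
contact-surface form: A_c = (6n − F)/2 shared faces, normalized by
A_c,max = 3(n − n^(2/3)), clipped to [0, 1]; solid cubes score 1, a voxel
chain 7/12. Radius statistics use the 6-adjacency surface voxels and the
**population** standard deviation (declared for reproducibility; the sample
SD would differ at small n). Degenerate single-voxel masks return radius 0
and compactness 1 by convention, with a message.

## Ellipsoid fitting

The "optimally fitted ellipsoid" is moment-matched: center of mass,
orientation from the eigenvectors of the voxel-coordinate covariance, and
semi-axes aᵢ = √(5 λᵢ) — the exact second-moment relation for a solid
ellipsoid, so a rasterized ellipsoid refits itself (tested within 5%). A
least-squares surface fit was rejected because it needs an iterative solver,
has no closed-form determinism guarantee, and the moment fit is
volume-consistent for true ellipsoids.

Residual regions are 26-connected components of lesion∖ellipsoid (outside)
and ellipsoid∖lesion (inside). Any rasterized ellipsoid differs from its
refit by one-voxel shells, so components smaller than **27 voxels** (one
3×3×3 cell) are discarded before counting; without the filter E_R is pure
resolution noise. The threshold is a config knob (`sliver_min_size`).

"Angularity" of a residual region needed a concrete criterion. A region is
counted as angular when its sharpness s = (maximum radial distance of any
region voxel from the ellipsoid surface) / (equivalent radius of the
region's radial footprint on the surface) exceeds 1.0. Distances are
measured along the ray to the ellipsoid center (a cheap, monotone surrogate
for the exact point-to-ellipsoid distance), and the footprint radius is
√2 × the RMS spread of the region's surface projections, which equals the
radius for a filled disk. The threshold 1.0 is the hemispherical bump: a
bump as deep as it is wide sits at the boundary, spikes exceed it, shallow
caps do not. Both the criterion and its threshold are explicit config
(`angularity_threshold`) — the counts are meaningful only relative to a
declared rule.

## Posterior acoustic region

The footprint is the lesion's maximum-area C-view section shrunk to ⅔ of
its area by thresholding the 2-D Euclidean distance transform at the
smallest level whose superlevel set does not exceed the target — met from
below, never overshot, because the ⅔ rule exists to keep the rim (edge
shadowing) out of the region. Shrinking on the maximum-area slice (rather
than the depth-projected footprint) follows from that section being the
named reference area. Sections that are a single pixel row/column fall back
to a 1-D distance transform, since every pixel of a 1-wide section touches
transverse background. The region is a straight-walled prism extruded from
one voxel below the lesion's globally deepest voxel, for min(lesion height,
100) slices, clipped to the volume and excluding lesion voxels; per-column
draping was rejected as an undocumented alternative. The five features
compare posterior and lesion gray statistics (population SDs); ratios with
zero denominators are `NA` with a warning.

## Group statistics

Per feature, normality of each grade group is tested with the
Lilliefors-corrected Kolmogorov–Smirnov test at α = 0.05 (parameters are
estimated from the data, so the Lilliefors correction is the defensible
form); if both groups pass, a two-sided Welch t-test is used (equal
variances were not assumed — the unequal-variance form is the safer
default and is flagged in the report), otherwise a two-sided Mann–Whitney
U test. Groups smaller than 5 or constant are treated as non-normal.
Missing values exclude a case from that feature's test only. Raw p-values
are reported without multiplicity correction, matching the descriptive
purpose of the table.

## Classifier and search

The SVM is libsvm's C-classification with an RBF kernel via `e1071`,
class-weighted so weight(high)/weight(low) = n_low/n_high (the reciprocal
of the class-count ratio), with z-scoring fitted on the training portion
(`scale = TRUE`). The GA chromosome is 44 selection bits plus real genes
log₂C ∈ [−5, 15] and log₂γ ∈ [−15, 3] (the conventional search box).
Fitness is 0.8·(sens × spec) + 0.2/k, where sensitivity and specificity come
from stratified inner cross-validation on the training data only — outer
test folds never leak into the search. Resubstitution fitness was rejected:
it saturates at 1 for large C and would make the parsimony term the only
signal. GA mechanics (population 50, 100 generations, tournament-of-2
selection, one-point crossover at 0.8, bit-flip mutation at 0.02, Gaussian
perturbation of the real genes, elitism 1, empty subsets repaired to one
random feature, inner 5-fold) are declared defaults; only the fitness
weights are fixed by the design. Everything is reproducible from one seed.

Evaluation is stratified tenfold cross-validation. The headline indices are
computed from the confusion matrix **pooled** over test folds (whole-cohort
fractions such as 126/148, rather than averages of per-fold rates), and A_Z
is the Mann–Whitney statistic (ties ½) of the pooled decision values.
Pooled CV decision scores are known to be noisier than the plain
Mann–Whitney null because the ten classifiers share training data; the
phantom-based null checks therefore average A_Z over several independent
cohorts instead of trusting a single draw.

## The phantom generator

`generate_phantom()` emulates only what the features measure: a hypoechoic
ellipsoidal lesion (mean gray 60 on a 120 background — carcinomas are
typically darker than surrounding tissue), speckle approximated by
Gaussian-filtered white noise rescaled to SD 20 with a ≈1.5-voxel
correlation length, optional spherical surface protrusions, and an additive
gray shift in the posterior prism (positive = enhancement). It is *not* a
physics simulation: no beamforming, attenuation, or angular scattering —
so passing tests demonstrate that the pipeline measures what it claims on
images with the right second-order statistics, not that it handles every
artifact of clinical ultrasound. Cohorts mirror the target setting: grades
are imbalanced at will (e.g. 119 low / 29 high), and the high-grade effect
profile moves features in the clinically reported directions — stronger
posterior enhancement, lower gray-level correlation, more protrusions. The
"strong" profile separates the affected features by about two within-group
SDs; "null" makes the groups identically distributed.

## Problem sizes and numerical choices

The test suite and acceptance checks run on phantoms of 48³–64³ voxels and
cohorts of 60–200 cases, sizes at which every analytic oracle (ball areas,
compactness closed forms, self-fit ellipsoids) is already tight; feature
values are resolution-stable well below clinical grid sizes, and the same
code paths run unchanged on larger volumes. Null-cohort behaviour is
assessed as the mean A_Z over six independent 200-case cohorts because the
single-cohort CV A_Z has a sampling SD of ≈0.07 on 200 null cases —
a property of cross-validated AUC, not of this implementation. Ties in the
maximum-section scan break toward the shallower slice; ties in ROC ranks
count ½; the GA repairs all-zero chromosomes instead of erroring mid-search.

## Known limitations

* Segmentation quality is assumed; the largest-component rule only guards
  against stray islands.
* The angularity criterion is a declared stand-in for an unpublished rule;
  absolute E_ROa/E_RIa counts should not be compared across tools, only
  across cases processed with the same threshold.
* Surface area (and everything downstream: M_Cc, E_S) carries the
  smoothing bias discussed above — sharp-edged objects read a few percent
  low.
* NIfTI is the supported volume format; NRRD headers are not parsed.
* The phantom generator's speckle is Gaussian, not Rayleigh/Rician; tests
  on phantoms validate the measurement chain, not clinical performance.
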