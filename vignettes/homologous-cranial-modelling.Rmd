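---
title: "Homologous cranial modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homologous cranial modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how cranioform's pipeline works, which conventions
it fixes where several were defensible, and what its synthetic validation
does and does not demonstrate. It is the package's design record; the
README shows usage.

## The modelling problem

A homologous model is a triangle mesh with a fixed vertex count and
topology whose vertices are in anatomical correspondence across
specimens. Given a surface scan and 56 digitised craniometric landmarks
per specimen, the pipeline deforms one template mesh onto every scan, so
that downstream statistics operate on an N × 3V matrix of vertex
coordinates rather than on a handful of inter-landmark distances.
Specimens are *not* Procrustes-superimposed: each model is expressed in
an anatomically defined head frame, and size is carried by the
coordinates themselves (the non-normalised analysis) or removed by
dividing each specimen's row by its centroid size (the normalised
analysis). Centroid size is computed over **all** model vertices, not the
56 landmarks; that choice matches the unit of analysis (the whole
homologous surface) and is recorded in the run log.

## Head-oriented frame

The frame is built from four landmarks. X runs from left to right porion;
the Frankfurt horizontal (X–Z) plane passes through both porions and the
left orbitale; Z is the in-plane direction orthogonal to X with the
nasion forward; Y = Z × X (right-handed, up); the origin is the porion
midpoint. The textbook definition is over-determined: the nasion does not
in general lie exactly on the median plane through the porion midpoint.
We use the nasion only to disambiguate the signs of Z and Y and report
its residual X offset as a QC number; forcing it to zero would require a
non-orthonormal basis or an extra rotation that the landmark set does not
determine. Degenerate inputs (coincident porions, orbitale collinear with
the porion axis, missing required landmarks) are errors, not warnings.

## Template fitting

Fitting minimises, per pass,

E(X) = γ·E_stiffness + α·E_data + β·E_landmark,

over one 3×4 affine transform per template vertex (Amberg-style
optimal-step non-rigid ICP). E_stiffness is the summed squared Frobenius
difference of transforms across mesh edges (a graph-Laplacian
regulariser: it preserves local shape by making nearby vertices move
near-affinely together); E_data sums squared distances from deformed
vertices to their closest *compatible* scan surface points; E_landmark
pins the 56 landmark-bound vertices to the target landmarks. Each outer
iteration recomputes exact closest points on the scan (point-to-triangle
projection under a bounding-volume hierarchy; ties between equidistant
faces go to the lowest face index, which keeps runs deterministic) and
solves one sparse linear least-squares system; with correspondences and
weights fixed, the solve cannot increase E, and re-finding closest points
cannot increase E_data, so the energy is non-increasing whenever the
rejection set is stable. The pass ends when mean vertex motion falls
below `tol` (mm) or at `max_iter`.

Correspondences are rejected when the distance exceeds
`max(reject_dist_mult × median distance, reject_dist_floor)` or the
angle between the deformed vertex normal and the matched face normal
exceeds `reject_angle_deg`. The multiplicative rule alone destabilises
late iterations — once the median residual is essentially zero the
threshold collapses and the kept set churns — hence the absolute floor
(default 0.5 mm, well below any anatomical mismatch but above converged
residuals). Rejected vertices keep no data term and are carried by
stiffness alone, which also prevents the template's basal boundary from
snapping into the scan's basal opening.

The default schedule is three coarse passes with stiffness decreasing
(γ = 100, 10, 1) while surface attraction increases (α = 1, 5, 10) and
the landmark weight stays high (β = 50, 20, 20), then one Loop
subdivision, then a fine pass (γ = 0.5, α = 10, β = 200). Weights are
relative units — only ratios matter. The values are justified solely by
the pipeline QC bounds (per-specimen mean landmark residual below
0.01 mm; mean vertex-to-surface residual far below 0.322 mm on synthetic
batches, as asserted by the test suite); they reconstruct no external
tool's internals, and the whole schedule is exposed in configuration.
Rigid initialisation is Kabsch over shared landmark names, proper
rotation only; uniform scaling is available (`allow_scale`) but off by
default because the analysis deliberately retains size. Landmarks absent
from a scan are simply dropped from E_landmark (at least three are needed
for the rigid start). Loop subdivision uses the standard masks (interior
3/8–1/8 edge rule, valence-dependent β for even vertices, midpoint and
1/8–3/4–1/8 crease rules on the boundary); original vertices keep their
indices, so landmark bindings survive subdivision.

Two spec-level idealisations proved unattainable in floating point and
are asserted in weakened, documented forms. First, exact rigid-motion
equivariance of a full fit: borderline closest-face assignments flip
when the input is rotated, and the alternating scheme amplifies those
flips, so two runs agree to ~0.05–0.1 mm mean vertex discrepancy (with
identical QC), not to 1e-6; the test asserts the statistical version.
Second, the infinite-stiffness limit of the deformation is a *common
affine* transform, not the rigid initialisation; a global affine
legitimately absorbs a small least-squares share of any local target
deformation, so the test asserts an order-of-magnitude suppression
contrast rather than exact identity.

## Shape space conventions

PCA is computed on the sample covariance (N − 1) of mean-centred rows via
the N × N Gram matrix, since 3V (≈ 53k at full resolution) vastly exceeds
N; eigenvalues equal those of the direct 3V × 3V decomposition and the
score SD of component k is √λ_k, which defines the "SD" used for ±3 SD
virtual shapes. Coordinates are never standardised: they share mm units,
and standardising would erase the size structure the non-normalised
analysis is designed to retain. "Loading" means the Pearson correlation
between a coordinate column and a component's scores; the conventional
colour-map thresholds (0.45, 0.40, 0.30) only make sense on a
correlation scale, since raw unit eigenvector entries over ~53k
coordinates are O(10⁻²). Raw entries remain available via
`type = "eigenvector"`. Zero-variance coordinates load 0 by convention.
Component signs are arbitrary in principle; we fix each component so its
largest-|loading| coordinate loads positively, making orientations
reproducible across runs. Normalised rows are each specimen's row
divided by its own centroid size (unitless); no rescaling to a grand
mean size is applied. Colour classes map the set of axes whose |loading|
exceeds the threshold: {X} red, {Y} green, {Z} dark blue, {Y,Z} light
blue, {X,Z} pink, {X,Y} yellow, {X,Y,Z} white, {} uncoloured.

## Discrimination and allometry conventions

AUC is the normalised Mann–Whitney U with ties counted ½, computed with
the named group as positive on the raw score order; values below 0.5 are
reported as-is with a direction flag rather than silently flipped, and
ranking within a group uses discriminability max(A, 1 − A) so a
direction-flipped but strongly separating component ranks first.
Significance uses the Hanley–McNeil standard error
(Q1 = A/(2−A), Q2 = 2A²/(1+A)) and refers ((A − 0.5)/SE)² to χ²(1); this
is an approximation choice, documented as such, and its type-I error at
α = 0.05 is verified by simulation to sit near nominal (the test suite
uses 2,000 permuted-null replicates at 50 per class). The default
significance level is 0.001, configurable; no multiple-testing correction
is applied by default (a Bonferroni flag exists, off). Groups smaller
than `min_n` (default 5) are skipped with a log entry.

Allometry fits log Y = b log X + log a by OLS, with X the centroid size
of the *non-normalised* model — also when Y comes from the normalised
space, since a normalised score has no size of its own. Scores are made
positive by adding round(|min|) + 1 when the minimum is negative (plain
+1 otherwise). The rounding is half-up by default; the convention is
genuinely ambiguous (ceiling also guarantees positivity), so it is
exposed as `offset_rounding` and recorded in the output. In the
non-normalised scan PC1 is flagged as the size component but never
dropped — flags, not filters. Slope inference is the standard OLS
t-test with n − 2 df on the log scale.

## What the synthetic generator emulates — and what it does not

Every specimen is an image of one analytic base surface: an ellipsoid
(semi-axes 70 × 65 × 85 mm, i.e. ~140 mm cranial breadth and ~170 mm
length) with smooth radial bumps for the facial block and zygomatic
arches, the base removed below a polar cutoff. Four modes deform it:
isotropic scale (drawn as size/170 with size mean 170 mm, SD 6 mm —
a realistic few-percent adult variation), a vault length/breadth
exchange (±x vs ∓z scaling), and facial projection and height
(±10 mm · mask displacement per unit coefficient, within-group SD 0.3,
i.e. ~3 mm facial SD). Default group offsets put each group ~1.3–2 SD
out along "its" mode. Per-specimen surface noise is a sum of ten smooth
random bumps (amplitude SD 0.3 mm, angular widths 0.25–0.6 rad); it
emulates idiosyncratic surface detail at the scale of scan-cleaning
residuals, *not* high-frequency scanner noise. Landmarks are exact
analytic surface points by default (an optional isotropic mm jitter
emulates digitisation error). Scans get individual grid triangulations
(distinct ring counts, random azimuthal phase, ~20k vertices by default
versus hundreds of thousands in real scans) and a random rigid pose.

Because modes and landmarks are analytic, ground truth is exact, and the
recovery tests are sharp: non-normalised PC1 must correlate with the true
size coefficient, each group's most discriminative component must be the
one aligned with its injected mode, and an injected power-law size–shape
link must surface as a significant allometric coefficient of the correct
sign. One subtlety deserves emphasis: the "injected direction" of a mode
in homologous-vertex space is estimated by regressing the fitted shape
rows on the known coefficients. The naive analytic displacement fields
are *not* the right oracle — closest-point data terms constrain only
motion normal to the surface, so the tangential part of an analytic
field is replaced by stiffness-driven sliding, and the analytic fields
sit tens of degrees off the principal subspace while the realised
directions sit well inside it. Passing these tests therefore shows that
the pipeline recovers the generator's population structure under smooth,
clean, landmark-rich conditions; it does not certify performance on real
scans with holes, spikes, missing landmarks at scale, or digitisation
error, none of which the generator produces by default.

## Numerical choices and degenerate inputs

* Mesh I/O writes double-precision PLY (binary little-endian canonical;
  ASCII at 9 decimals), so round trips hold far below 1e-6 mm.
  Non-triangular faces are rejected naming the face; non-manifold edges
  are rejected by subdivision and fitting rather than repaired.
* The sparse normal equations carry a tiny *absolute* ridge (1e-8) purely
  as a numerical safeguard; a ridge scaled to the matrix diagonal would
  grow with γ and visibly shrink the solution toward zero.
* Convergence tolerances are in mm: coarse passes stop at 0.01–0.005 mm
  mean motion, the fine pass at 0.002 mm.
* PCA drops eigenvalues below 1e-10 of the leading one; `fit_shape_pca`
  refuses N < 3 and zero-variance tables; `fit_allometry` refuses
  non-positive inputs and zero variance in log X; `roc_auc` refuses an
  empty class; single-member classes are flagged `degenerate` in the
  χ² report.
* Determinism: a study is a pure function of its seed (the generator
  consumes it; fitting contains no randomness; correspondence ties break
  by face index). Re-running a study reproduces score CSVs bitwise.

## Problem sizes used by the shipped validation

The test suite exercises the full-resolution path (default 4,473-vertex
template, subdivided to 17,785; ~20k-vertex scans) for the ten-specimen
QC batch, and reduced sizes elsewhere: a 700-vertex template and
3,000–3,500-vertex scans for the 60-specimen four-group recovery study
and the 30-specimen allometry study, and a 1,200-vertex template for the
fitting unit tests. These sizes were chosen so the whole validation runs
comfortably on a single desktop core; resolution is an ordinary parameter
of `population_spec()`/`make_template()`, and nothing in the method
depends on it beyond the usual discretisation error.

## Known limitations

* No scan repair: holes, spikes and non-manifold geometry must be fixed
  upstream; the generator produces clean surfaces only.
* The anatomical frame depends on four landmarks; digitisation error in
  porion/orbitale/nasion propagates into every coordinate (this is a
  property of the head-frame design, shared with any non-Procrustes
  convention).
* Tangential vertex identity between landmarks is regularisation-driven;
  homologous correspondence is exact at landmarks and approximate
  elsewhere.
* Hanley–McNeil is an approximation to the AUC sampling distribution;
  for very small or very unbalanced groups, use the `degenerate` flag
  and permutation approaches outside the package.
* GPA/Procrustes superimposition, TPS semi-landmarks and phylogenetic
  comparative methods are deliberately out of scope.
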