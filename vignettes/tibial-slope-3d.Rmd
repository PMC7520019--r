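---
title: "Measuring the 3D tibial slope: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the 3D tibial slope: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tibslope)
```

## The measurement model

The posterior tibial slope is defined here as the signed sagittal-plane
angle between the anatomical tibial axis and the normal of a least-squares
plane fitted to an articular region. Four regions are measured separately
— medial plateau, medial rim, lateral plateau, lateral rim — because the
weight-bearing plateau and the elevated peripheral rim can carry different
inclinations, and radiographs cannot tell them apart. The intercondylar
area is never part of a region.

The pipeline consumes a segmented tibial surface mesh (millimetres, no
fibula, at least 150 mm of shaft) plus the four brushed regions, and has
three geometric stages.

### Anatomical axis from serial cross-sections

A provisional long axis is taken as the first principal component of the
mesh vertices — for a long bone this is nearly orientation-free — and
oriented so that the end with the larger mean cross-sectional area over
its terminal 20 mm (the flaring metaphysis) is proximal. The articular
reference point is the most proximal vertex along that direction: the
datum is reader-independent and reproducible, which is the property we
need from "the articular surface" without defining a joint line.

Cross-sections are then cut perpendicular to the axis at stations 150 mm
distal to the datum, stepping 5 mm proximally. Each section is built by
intersecting every triangle with the plane and chaining the segments into
closed loops through shared mesh edges (an exact, combinatorial chaining —
no coordinate snapping). The loop of largest absolute area is the shaft
contour; inner loops (intramedullary voids of a non-watertight
segmentation) are ignored. Area comes from the planar shoelace formula and
the centroid from the area-weighted polygon centroid mapped back to 3D.

Iteration stops at the first section whose area **strictly exceeds**
1.6 × the area of the first (most distal) section; that section is
metaphyseal by definition and is **excluded** from the fit. Exclusive
reading of "until the area exceeded the threshold" is a fixed, documented
choice — on synthetic shafts including it moves the axis by far less than
the method's noise floor, but tie behaviour must be deterministic, and
equality with the threshold continues. The axis is the 3D
total-least-squares line through the retained centroids (first principal
component of the centroid set, anchored at their mean). One refinement
pass (`refine_iterations = 1` by default) repeats datum, sectioning and
fit with planes perpendicular to the fitted axis, removing the residual
dependence on the provisional direction; on a straight shaft the pass
changes the direction by under 0.01 degrees, and whether the original
procedure refined is unknowable from its description, so the count is
exposed as a parameter.

### Region planes

Each brushed region is reduced to its total-least-squares plane: the plane
through the centroid whose normal is the eigenvector of the smallest
eigenvalue of the 3×3 scatter of centred points. Points are used exactly
as given — no area weighting, no resampling — because the measurement is
defined on the brushed points themselves. Two degenerate cases fail
loudly rather than guess: a rank-deficient (collinear) patch, and a patch
whose two smallest scatter eigenvalues tie (a rod-like set has no unique
least-squares plane, and a slope from an arbitrary one would be
meaningless). The reported `rms_residual` is the root-mean-square
orthogonal distance; eigenvalues below `1e-12` of the leading one are
treated as exact zeros so that interpolating fits report a zero residual
instead of solver noise.

### Sagittal frame and the signed angle

The slope needs a sagittal plane. The source procedure defers this to an
external method it does not describe, so the package defines its own,
recorded in every output's provenance field: the mediolateral direction is
the vector from the lateral to the medial plateau centroid,
orthogonalised against the axis (Gram–Schmidt) and normalised; a
user-supplied override is accepted for comparability with other
conventions. The anteroposterior direction completes a right-handed triad
as `longitudinal × mediolateral`. (The opposite product order can never be
right-handed: det[ml, ml × long, long] = −1 for any orthonormal pair.)
Anterior is disambiguated by the offset of the most proximal shaft-section
centroid from the midpoint of the plateau centroids — the shaft and tibial
tubercle lie anterior to the plateau centre — and if that indicator points
the other way both `ap` and `ml` are flipped together, preserving
handedness. An indicator below 1e-9 (an exactly symmetric phantom) keeps
the default orientation rather than flipping on floating-point noise.

The plane normal is re-oriented into the proximal hemisphere
(`⟨n, axis⟩ > 0`), then both normal and axis are projected into the
sagittal plane by removing their mediolateral components, and

\[
\theta \;=\; \operatorname{atan2}\!\big({-\langle \hat n_s, \mathbf{ap}\rangle},\;
\langle \hat n_s, \mathbf{long}\rangle\big)\cdot 180/\pi .
\]

**Sign convention.** Positive is the clinical posterior slope: the plateau
tilted posterior-inferior. A surface normal tilts towards its *downhill*
side, so a posteriorly sloped plateau has a posterior-leaning normal —
hence the minus sign on the anteroposterior component. The same convention
is wired into the synthetic generator and the 2D radiographic measurement
(positive when the plateau line drops posteriorly), so the 2D and 3D
measurements of one knee agree in sign as well as magnitude.

A normal within 1e-6 of parallel to the mediolateral direction cannot be
projected and is an error; with the normal proximally oriented the result
always lies in (−90°, 90°).

### Radiographic measurement

`measure_2d_slope()` takes two digitized lines in a fixed image convention
(x grows anterior→posterior, y grows distal→proximal; files must carry the
tag explicitly, because an untagged flipped axis silently negates every
slope). The cortex line is oriented proximally, its perpendicular
posteriorly; the result is the signed angle of the plateau line from that
perpendicular — equivalently 90° minus the acute inter-line angle. Endpoint
order never matters. Parallel lines (±90°) are a physically impossible
digitisation and are refused.

## Reliability statistics

`icc_a1()` is the two-way random-effects, absolute-agreement,
single-measures intraclass correlation — ICC(A,1) in the McGraw–Wong
taxonomy — from the two-way ANOVA decomposition of a complete
subjects × readers table. Only this form is provided: reliability analyses
are routinely invalidated by picking a convenient ICC variant, and the
inter-reader design measured here is exactly this one. The confidence
interval is the standard F-based construction with Satterthwaite degrees
of freedom; `alpha` defaults to 0.05. Sample SDs use the n−1 denominator.

Numerical corner cases: a zero-total-variance table is an error (not a
silent ICC of 1); identical reader columns give exactly 1 with a
degenerate interval; negative estimates are reported as computed with a
warning — truncation at zero is a presentation choice, not an estimator
property. Note that the raw estimator is not bounded below by −1 when the
between-subject mean square vanishes (e.g. `cbind(1:6, 6:1)` gives −1.5);
the package follows standard implementations and does not clamp.

## The synthetic tibia generator

`generate_tibia()` builds a phantom with exactly known ground truth: a
surface-of-revolution shaft (default radius 15 mm, length 200 mm) with a
linear metaphyseal flare (to 35 mm over the proximal 40 mm) and optional
circular-arc sagittal bow, capped by four articular regions. Each region
is a concentric-ring sampling of a disc (plateau, with a shallow
rotationally symmetric concavity, 0.8 mm deep) or an annulus (rim,
elevated 1.5 mm, "the outermost, elevated portion"), rotated by its own
sagittal slope and coronal tilt about a centre offset ±25 mm
mediolaterally and 5 mm posteriorly (so the shaft is anterior to the
plateau centres, as in vivo, which is what the frame's anterior
disambiguation keys on). Default slopes are the observed population means
(7.4, 7.6, 7.5, 8.1 degrees). The rotationally symmetric sampling makes the
constructed tilted plane the *exact* least-squares plane of each region —
including the concave plateau — so recovery error measures the pipeline,
never the phantom. The coronal tilt is applied before the sagittal slope,
so the sagittal projection of the region normal makes exactly the
specified angle with the true axis regardless of coronal tilt.

Optional Gaussian vertex noise (default SD 0; 0.3 mm in the validation
suite, the scale of CT segmentation surface error) can be isotropic or
along vertex normals; generation is bit-deterministic for a fixed spec and
seed, with the caller's RNG state restored.

What the phantom does **not** emulate: condylar curvature, the
intercondylar eminence, osteophytes, cortical thickness, or any
statistical shape variation of real tibiae. Passing recovery tests
demonstrates correctness of the geometry and statistics on meshes whose
truth is known — it does not certify accuracy on pathological anatomy.

`generate_reader_study()` simulates an inter-reader study: per-subject
true slopes drawn from a normal population (default mean 7.65°, SD 4°,
with fixed per-region offsets reproducing the regional means), each
subject measured once through the full mesh pipeline (axis and frame are
automatic, hence reader-independent), then per-reader values produced
either by additive Gaussian reader noise or by reader-specific patch
perturbation (boundary erosion plus random subsampling before re-fitting
the planes). Under the additive model the expected ICC is the
variance ratio σ²ₛ/(σ²ₛ + σ²ₑ) — e.g. 16/17 ≈ 0.941 for SDs of 4° and 1° —
which the validation suite checks at n = 500.

## Tunable parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `start_offset` | 150 | mm | first station distal to the articular datum |
| `step` | 5 | mm | station spacing |
| `area_factor` | 1.6 | — | stop threshold as a multiple of the first section area |
| `refine_iterations` | 1 | — | re-slicing passes perpendicular to the fitted axis |
| `override_mediolateral` | none | — | replaces the inter-plateau-centroid direction |
| `anterior_hint` | none | — | forces the anterior hemisphere for pathological shapes |
| `alpha` | 0.05 | — | ICC confidence level (95% CI) |

The first three are the published measurement constants and should only be
changed to study their effect; the rest cover anatomies the automatic
conventions cannot decide.

## Numerical choices

* **On-plane vertices.** A vertex exactly on a slicing plane would make
  triangle sign tests ambiguous; signed distances with magnitude below
  1e-12 mm are nudged to +1e-12. The bias is twelve orders of magnitude
  below reported tolerances and keeps shared-edge chaining exact.
* **Duplicate vertices** are merged within 1e-6 mm at load (STL is a
  triangle soup); zero-area faces are dropped with a count.
* **Open section chains** (a mesh hole crossing the plane) are an error
  naming the gap size in strict mode; the orientation probe near the
  articular end runs in lenient mode, where detached patch islands cut by
  the probe plane are discarded as open chains.
* **Symmetric shafts** have no intrinsic proximal end; when terminal areas
  tie to within 1e-9 relative, the provisional direction's sign is
  canonicalised (largest-magnitude component positive) so results stay
  deterministic.
* **Validation problem sizes.** The test and acceptance suites use shaft
  tessellations of 64 segments × 2.5 mm rings (≈6 400 vertices), a
  720-segment cylinder for the analytic area bound, 20 noise seeds, 100
  random instances for the plane and ICC oracles, n = 2000 for the
  variance-components check and n = 500 subjects for the reader study —
  sizes at which every quoted tolerance is comfortably resolved on a
  single CPU in about a minute.

## Known limitations

* Meshes containing the fibula are not handled; segmentation must isolate
  the tibia.
* Binary PLY is not read (binary and ASCII STL are); export ASCII PLY or
  STL from the segmentation tool.
* The sagittal-plane convention is this package's own documented stand-in
  for an external definition the source procedure references but does not
  describe; the frame provenance field and the `override_mediolateral`
  parameter exist precisely so results under other conventions remain
  comparable.
* With a perpendicular plateau defined as 0°, reported slopes near 7° are
  consistent with the axis-vs-normal angle definition; packages using the
  90°-complement convention will differ by construction.
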