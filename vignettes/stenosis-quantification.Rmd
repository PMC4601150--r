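---
title: "Measuring renal artery stenosis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring renal artery stenosis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenometry)
```

`stenometry` quantifies renal artery stenosis (RAS) on 3-D angiographic
volumes and evaluates how well different morphological measures predict a
hemodynamically significant stenosis. This vignette is the package's account
of the science behind each stage: what is modelled, which parameters matter,
what the synthetic data do and do not emulate, and where the design was
genuinely open.

## The measurement model

A renal artery is measured on planes perpendicular to its centerline. On each
cross-section the lumen is segmented and two quantities recorded: the area
(mm²) and the *shortest* diameter (mm) — the minimum caliper (Feret) width of
the lumen region, which is robust to non-circular, crescentic lumina. Along a
vessel segment this yields a profile from which four extremes are taken:

* `MinD`, `MinA` — the minima over all positions, located independently;
* `MaxD`, `MaxA` — the maxima over *eligible* positions only.

The relative reductions are `Dred = (1 − MinD/MaxD)·100 %` and
`Ared = (1 − MinA/MaxA)·100 %`. Using the same segment's maximum as the
reference caliber (rather than a distal "normal" segment) keeps the procedure
standardized and reproducible; its known cost is that a post-stenotic
dilatation can inflate the reference and hence the reduction.

Two segments are measured per artery: segment 1 from the aorta to the most
proximal bifurcation, segment 2 along the largest branch from the first to
the second bifurcation. Because the reference maxima are corrupted near
junction geometry, a position is eligible for the maximum search only if it
lies at least 10 mm from the aorta and at least 5 mm from a bounding
bifurcation. When these rules leave no position at all (very short branch
spacing), the maxima fall back to the unrestricted search and the summary is
flagged (`fallback_used`) — the automated counterpart of reading the value
visually from the profile graph.

## Threshold selection

Segmentation needs a lower grey-level threshold LT separating contrast-filled
lumen from tissue. It is derived per patient from ROI statistics:

* the **contrast value** is the mean of three per-slice aorta-ROI maxima — at
  the axial slice whose aorta-ROI mean is greatest, and 10 mm proximal and
  distal to it (offsets rounded to whole slices; clamped at the stack ends
  with a warning);
* the **background value** is the mean of per-ROI means in non-contrast
  tissue: four psoas-muscle ROIs for CTA, three vertebral-body ROIs for MRA;
* `LT = (aorta + 2·background)/3`, one third of the way up from background —
  a fixed formula, deliberately not re-fitted per site.

For CTA an **upper threshold** UT (the same three-slice maximum recipe) caps
the band, because calcified plaque exceeds the attenuation of contrast-mixed
blood and must not be counted as lumen. MRA has no UT. ROIs are circular
discs in the axial plane; their geometry was an open choice and discs are the
simplest shape a reader would place.

## Competing fuzzy-connectedness segmentation

Voxels are assigned to competing seeds (aorta, renal artery, possibly an
adjacent vein) by fuzzy connectedness: the affinity of a voxel pair is a
trapezoidal membership of the dimmer voxel — 0 at or below LT (and above UT
on CTA), rising linearly to 1 at the contrast value — and the strength of a
path is the minimum affinity along it. Each voxel takes the label of the seed
with the greatest max–min path strength, computed exactly by a priority-queue
Dijkstra on the 6-connected voxel grid (compiled code).

Ties are real: in a noise-free, uniformly bright tree *every* in-band voxel
has strength 1 to every seed. The declared deterministic tie rule is
(1) higher path strength, (2) smaller spacing-aware geodesic distance from
the seed in mm, (3) earlier queue insertion. The mm term makes uniform
competition a mm-Voronoi split between seeds, which is the physically
sensible boundary and is independent of voxel anisotropy; a pure
insertion-order rule would move the aorta/artery boundary when the slice
thickness changes. Practical seeding matters too: the aorta, being large, is
seeded generously (a line of seeds along its axis in `run_pipeline()`), which
prevents the artery seed from capturing thin slivers of aortic wall that are
hop-equidistant from a single central seed.

## Centerline extraction and segments

The centerline is traced on the labelled artery: the exact anisotropic
Euclidean distance transform (Felzenszwalb's separable algorithm) provides a
medialness weight, and branches are traced iteratively as minimum-cost
geodesic paths (cost = mm step × inverse squared medialness) from the
farthest unexplained voxel back to the growing tree. Tips are anchored
medially by maximizing geodesic distance *plus* local radius; tracing stops
when every remaining voxel lies within the local radius plus a 2 mm spur
allowance of the tree. Node positions are de-jittered by a short moving
average (ends pinned), tangents come from central differences, and the local
radius estimate is the distance-transform value at the node.

"Largest branch" at a bifurcation is defined as the branch with the largest
mean radius estimate over its first 5 mm — the field uses "largest" loosely
and this is the declared formalization. A side branch whose entire subtree is
shorter than 3 mm is treated as a centerline spur (residual competition bleed
at the aorta wall), not an anatomical bifurcation: no renal artery branch is
that short, and without this guard a 1 mm stub would terminate segment 1 at
the aorta. Obviously wrong centerlines have a manual fallback:
`import_manual_centerline()` reads hand-drawn branch polylines (JSON, mm) and
re-derives tangents, yielding the same tree contract.

## Cross-section segmentation and morphometry

Planes are resampled by trilinear interpolation orthogonally to the local
tangent (in-plane axes chosen deterministically from the tangent and the most
orthogonal world axis), at a pixel pitch of a quarter of the finest voxel
spacing — fine enough that caliper widths are not pixel-limited. The lumen
mask is the in-band connected component containing the plane centre,
regularized by morphological closing/opening with a disc whose radius scales
with `curvature_scale` (10 → one pixel), which closes single-pixel noise
holes and smooths the contour as a curvature term in a level-set evolution
would; pixels above UT (plaque) are excluded afterwards. Area is pixel count
× pixel area (the declared convention; whether a contour-polygon area would
differ is below measurement noise at this pitch). The shortest diameter is
the minimum Feret width over 1° caliper steps, computed on the convex hull
with the projected pixel footprint added — exact for the pixel union.

Two practical rules protect the extremes: positions within 3 mm of a *free*
(non-bifurcation) centerline end are marked invalid, because planes there cut
the partial end of the segmentation rather than a full lumen; and the
arc-length step defaults to 0.5 mm, about the finest CTA voxel pitch.

## Cohort summarization

Readers are merged by averaging the four absolute measures and *recomputing*
the reductions from the averaged minima and maxima — this keeps
`MinD/MaxD/Dred` internally consistent, whereas averaging the two readers'
percentages (available via `mode = "average_pct"` for sensitivity analysis)
does not. A segment measured by only one reader passes through unchanged.

Per kidney, one result is selected per approach: *First* (all first
segments), *Tightest* (all segments), *Main* (both segments of the artery
with the largest merged maximum diameter; ties to the artery with more
measurable segments). The selected segment is the candidate with the largest
`Dred`; exact ties go to the larger `Ared`, then segment 1 — tie-breaking had
to be declared somewhere, and this ordering prefers the more severe and the
more reproducible reading. By construction `Dred(Tightest)` dominates both
other approaches (maximum over a superset).

The functional reference resolves as: renography positive/negative stands;
intermediate renography defers to the captopril test. Cohort filtering drops,
in order and with an explicit accounting table: kidneys of patients lacking
any investigation, kidneys non-measurable on either modality, and kidneys
contralateral to a positive — including positives that were themselves
dropped as non-measurable, since renography cannot lateralize disease in
such patients; solitary kidneys are never dropped by the contralateral rule.

## Evaluation statistics

* **Limits of agreement**: mean difference ± exactly 2 sample SDs (the 2-SD
  convention, not 1.96), bracketing ≈ 95.4 % of Gaussian differences.
* **ICC**: two-way random effects (cases and raters both random), absolute
  agreement, single measures — ICC(2,1) from the ANOVA mean squares, with the
  standard F-based 95 % limits; the average-measures form ICC(2,k) is
  available behind a flag. Cases missing a rater are dropped, matching the
  convention of computing agreement on units measurable by both readers.
* **ROC/AUROC**: the empirical trapezoidal curve; the area equals the
  Mann-Whitney statistic with ties counting one half. Confidence intervals
  use the DeLong placement variance by default (Hanley–McNeil behind a flag).
  Orientation is declared per measure: reductions score higher-is-diseased,
  absolute minima invert, so true signal always gives AUC > 0.5.
* **Paired AUROC comparison**: DeLong's paired test from the placement
  covariances, two-sided normal p-value; rank-identical scores give p = 1.
* No multiple-testing correction is applied anywhere, by design; tables carry
  every comparison.

## The synthetic data

**Phantoms** emulate a contrast-filled aorta (axis-aligned cylinder) with
renal arteries swept along smooth paths, focal stenoses as cosine-taper dips
in the radius profile, optional hyperintense plaque spheres (CTA only), and
additive Gaussian noise from a seeded stream. CTA-like voxels are
0.5 × 0.5 × 0.75 mm, MRA-like 0.7 × 0.7 × 2.0 mm. Ground truth (`MinD`,
`MaxD`, `Dred`, `Ared`, bifurcation positions) is computed analytically from
the radius profile before voxelization, so it is exact at any grid
resolution, and circular cross-sections guarantee
`Ared = 100·(1 − (1 − Dred/100)²)` as an internal consistency check.

Voxelization is **partial-volume** by default: each voxel takes the mean of
the scene over a supersampled subgrid (≤ 0.35 mm), as a scanner integrating
signal over its voxel would. A binary centre-inside rule is available
(`voxelization = "binary"`) but is *not* physical at MRA slice thickness: a
70 % stenosis leaves a lumen of 1.5 mm, thinner than one 2 mm slice, and a
binary grid breaks it into disconnected voxels that no segmentation could
traverse — a voxelizer artifact, not a scanner behaviour. The demonstration
phantom places the artery in an axial-slice plane (as renal arteries lie in a
coronally planned MRA stack) with a sub-voxel in-plane offset and gentle
in-plane tilt, so no tube surface aligns degenerately with the voxel grid.

Phantom recovery, verified by the test suite on one CPU in seconds per case:
measured `Dred` within ±5 percentage points (CTA) / ±8 (MRA) and `Ared`
within ±7 / ±8 of the analytic truth for true reductions of 30, 50 and 70 %.
What this does *not* show: performance under scanner physics (beam hardening,
coil inhomogeneity, motion), eccentric or non-circular stenoses, and manual
ROI/seed variability — phantom results bound the geometric fidelity of the
pipeline, not its clinical accuracy.

**Cohorts** simulate the study design the statistics serve: ~47 patients
(94 kidneys, two per patient), about one kidney in six with an accessory
artery, segment-level true reductions spread broadly (`100·Beta(1.5, 1.5)`,
mean 50, SD 26), healthy calibers ≈ 5.5 ± 0.7 mm (accessories smaller), and a
latent hemodynamic significance drawn per kidney with probability
`plogis((worst Dred − 60)/8)` — a saturating link centred near the 50–60 %
range where clinical significance is conventionally placed. Renography
reports the latent state except in an intermediate fraction (7 %) resolved by
the captopril test. Reader noise defaults to 0.35 mm on diameters and
2 mm² on areas (segment-1-like agreement); an alternative parametrization
(`dred_noise_sd`) applies Gaussian noise directly on the `Dred` scale with
known variance components, which is what the ICC-recovery check uses: case SD
20 and reader SD 5 imply ICC = 400/425 ≈ 0.941, and the simulated estimate
lands within ±0.05 at n = 1000. Simulated cohorts do not model reader-segment
confusion (two readers measuring different branches), missing-at-random
structure beyond per-segment flags, or correlated bilateral disease.

## Numerical choices and degenerate inputs

* All distances are mm and spacing-aware; voxel indices are 1-based in R,
  converted once at the compiled boundary.
* The Feret caliper steps 1°; the angular discretization error at renal
  calibers is ≪ 0.01 mm.
* `Dred`/`Ared` clamp to [0, 100] with a warning when noise makes a minimum
  exceed its maximum; a zero maximum is an error.
* A profile with no valid cross-section yields a non-measurable summary, not
  an exception; kidneys with empty candidate sets are reported non-measurable
  for that approach.
* Zero total variance makes the ICC undefined (reported `NA`); identical
  scores give AUC 0.5; a single-class reference is an error.
* Reproducibility: every stochastic step derives from an explicit seed;
  rerunning a pipeline config byte-identically reproduces its CSV artifacts.

## Problem sizes used in the checks

The bundled checks run phantom recovery at full demonstration-phantom
resolution (≈ 0.5 M voxels CTA, 0.1 M MRA) for six conditions, the
fuzzy-connectedness oracle on fifty ≤ 6³ volumes against exhaustive max–min
labeling, AUC against brute-force pair counting on two hundred instances,
ICC recovery at 1000 kidneys, limits-of-agreement coverage at 10⁵ draws, and
the paired DeLong null at 500 replicates of n = 300 — sizes at which each
statistic's sampling error is comfortably inside the asserted tolerance.

## Known limitations

* The affinity and the 2-D regularization are declared, contract-level
  realizations of "fuzzy connectedness" and "threshold-based level set with
  curvature scale 10"; other monotone in-band affinities or evolution schemes
  would satisfy the same contracts with slightly different boundaries.
* Stenosis *length* is deliberately not measured.
* The maximum-as-reference convention can overestimate reductions in the
  presence of post-stenotic dilatation.
* MRA-like slice thickness fundamentally limits severe-stenosis fidelity:
  sub-slice lumina survive only through partial volume, and recovery
  tolerances are correspondingly wider.
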