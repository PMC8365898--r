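---
title: "Para-sagittal endplate morphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Para-sagittal endplate morphometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertamorph)
```

## The measurement model

`vertamorph` measures endplate geometry of a single sub-axial cervical
vertebra (C3–C7) on three sagittal section curves. Everything is driven by
five manually labelled anatomical points: the posterior endplate valley
(PEV, a midline point on the superior endplate), the intersection of the
bilateral laminae, the midpoint of the posterior rim of the inferior
endplate, and the lateral tips of the two uncinate processes. All
coordinates are millimetres.

**Reference planes.** The mid-sagittal plane (MSP) is the unique plane
through the three midline landmarks; if a user supplies additional
(near-)midline points, the total-least-squares plane (orthogonal
regression, eigen-decomposition of the centered scatter matrix) is used
instead. Each lateral plane is defined as the plane *parallel to the MSP*
through an uncinate tip: only a single point per side is available, and the
parallel family makes the subsequent averaging unambiguous. Each quarter
para-sagittal plane (QPSP) is the average of the MSP and one lateral plane —
for parallel planes the unique mid-plane. For completeness the average of
non-parallel planes is defined as the normal-sum bisector anchored at the
midpoint of the projections of a shared anchor point (the midpoint of the
two planes' closest-to-origin points) onto each plane; this reduces to the
mid-plane in the parallel case the pipeline actually uses, and to the
bisector through the intersection line when both planes pass through the
anchor. The MSP normal is signed toward the *left* uncinate tip, which
makes the left/right labelling of the quarter planes deterministic.

**Anatomical frame.** Sections are re-aligned into a frame with origin at
the posterior rim midpoint: `lr` is the signed MSP normal; `ap` is the unit
vector from the laminae intersection toward the posterior rim midpoint
projected into the MSP (the posterior elements lie behind the body, so this
points anteriorly); `si = lr × ap`, sign-checked so the PEV (on the
superior endplate) is superior to the posterior rim midpoint. For
anatomically consistent landmarks `(ap, si, lr)` is right-handed; a
mirrored landmark set flips `lr` only, honestly describing mirrored
anatomy.

**Sectioning.** Mesh–plane intersection visits every triangle crossing the
plane; the two edge intersection points per triangle form a segment, and
segments are chained through shared mesh edges into closed loops. Vertices
lying exactly on the plane are handled by symbolic perturbation (treated as
an epsilon on the positive side), so watertight meshes always produce
closed loops; open chains from defective meshes are excluded with a
warning. A section of a whole vertebra contains the body loop and loops
through the posterior elements; the body loop is selected by proximity of
the loop centroid to the centroid of the four body-associated landmarks
(ties broken by larger enclosed area, then input order).

**Dimensions.** In the 2D `(ap, si)` curve (orientation normalized
counter-clockwise), the four rim corners are the vertices maximizing the
four diagonal support directions (±ap ± si). The observers of the original
measurement protocol pick rims visually; the 45° support rule is a
deterministic, brute-force-checkable surrogate. The superior arc runs from
the anterosuperior to the posterosuperior corner along the superior side,
the inferior arc analogously. Then per curve:

* `SED` — chord length between the superior arc's endpoints,
* `IED` — chord length between the inferior arc's endpoints (the anterior
  and posterior rims of the inferior endplate concave),
* `IECD` — maximum perpendicular distance from that chord to the inferior
  arc, measured on the side carrying the dominant deviation (zero for a
  straight arc).

The measurement protocol names both "depth of the inferior endplate" and
"distance between the rims of the inferior endplate concave" while
announcing three linear dimensions; we identify the two phrases with the
same quantity (IED). Similarly, figure legends that call `LIED/MIED/RIED` a
*superior* endplate depth are treated as a typo; the aliases follow the
symbols, not the legend prose.

## Reliability statistics

Repeated measurements are compared per vertebral level and dimension.
Normality of the *paired differences* is tested with Shapiro–Wilk (the
routed test acts on differences, so the gate does too; threshold 0.05):
normal-looking differences get the paired *t* test, otherwise the Wilcoxon
matched-pairs signed-rank test. The Wilcoxon drops zero differences,
mid-ranks ties, and computes the exact two-sided p by full enumeration of
the 2^m sign assignments for m ≤ 12 (the study scale of interest — 12
subjects per group — sits exactly at this bound), falling back to a normal
approximation with continuity and tie corrections above it.

Agreement is quantified with the intraclass correlation coefficient from
the two-way ANOVA mean squares. The default form is ICC(2,1) — two-way
random effects, absolute agreement, single measures:

ICC(2,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE)).

The source protocol does not state its ICC model; absolute agreement
matches the notion of between-observer reproducibility (a constant
between-rater offset lowers it, unlike the consistency form ICC(3,1), which
is available as an option along with one-way ICC(1,1)). Which of observer
one's sessions anchors the inter-observer comparison is likewise unstated;
the default compares the first session (O1a) with observer two (O2), and
both pairings are configurable. ICC values strictly above 0.75 are classed
"excellent".

## The synthetic vertebra and what it does (not) show

`generate_vertebra()` builds a watertight mesh of a parametric vertebral
body: an elliptical footprint of width `W` (left–right) and mid-sagittal
depth `D0` (anterior–posterior, default shorter than wide, 16 vs 24 mm), a
flat superior endplate with lateral uncinate ridges of height `u` whose
tips sit exactly at `x = ±W/2`, an inferior endplate with parabolic
concavity `c(x)·(1 − (2y/D(x))²)` vanishing at the rims, and simplified
posterior elements (a thin wedge whose laminae meet at a midline point
about one body-depth behind the posterior wall — the spinal canal plus
lamina span, which also conditions the MSP fit realistically). Midline
landmarks sit exactly at `x = 0`, so the true MSP is `x = 0` and the
quarter planes are `x = ±W/4`, giving closed-form truth
`SED(x) = IED(x) = D0·√(1−(2x/W)²)` and `IECD(x) = c0·(1−(2x/W)²)`.

Default parameters (`W = 24`, `D0 = 16`, `H = 12`, `c0 = 2.4`, `u = 2` mm,
resolution 0.8 mm) approximate a mid-cervical body. Per-level scales 0.90
(C3) … 1.10 (C7) reproduce the growth of dimensions down the spine. The
study simulator draws subject anatomy around these defaults with an ~8 %
male–female size gap, ~8 % individual size variation, and
dimension-specific scatter chosen from published cervical morphometry
(endplate AP-depth SD ≈ 1.7 mm, width SD ≈ 2.4 mm, concavity depth SD ≈
0.5 mm). Observer sessions re-place landmarks with isotropic Gaussian
jitter (default 0.3 mm) and, for observer two, a small per-landmark bias
(0.3 mm lateral on the uncinate tips, 0.2 mm off-midline on the laminae
point). A *common* translation of all landmarks is a rigid motion and
cannot bias the measurements, which is why the bias is per-landmark.

Two simulation modes decouple geometry from statistics: `"geometric"`
exercises the entire mesh pipeline (one mesh per subject and level,
re-landmarked per session); `"variance_components"` generates values
directly from `value = μ + subject + rater + error`, cheap enough for
estimator studies at n = 200 with closed-form target
σ²subject/(σ²subject+σ²rater+σ²error).

What passing tests on these fixtures show: exact plane algebra, correct
loop topology and planarity of the slicer, convergence of measured values
to closed-form truth with mesh resolution, rigid-motion invariance, and
correct estimator behaviour of the statistics. What they do not show:
robustness to segmentation artefacts, osteophytes, or degenerated
endplates (real CT meshes are noisier and the landmarks are harder to
identify — the method is intended for vertebrae with at most mild
degeneration), nor anything about anatomical fidelity beyond the stylized
shape: landmark/measurement truth, not realism, is the generator's goal.

## Numerical choices

* Exact geometric identities are asserted to 1e-9 mm; slicing output is
  planar to 1e-6 mm; curve–frame parallelism is required within 1e-3 rad.
* Seeding is hierarchical: one root seed hashed with (subject, session,
  landmark) via a 31-bit polynomial string hash, so any subset of a study
  reproduces in isolation and all derived seeds stay below 2^31.
* Section loops are chained by shared mesh-edge identity (not coordinate
  matching), so chaining is exact; ties in body-loop selection are broken
  by area then stable input order.
* Corner degeneracy (coincident corners, out-of-order corners on
  pathological curves) raises typed errors rather than guessing.
* CSV output uses fixed 6-significant-digit formatting to keep files
  diffable and byte-reproducible; full precision is kept in memory (the
  writer/reader round trip is exact to ~1e-6 relative, the formatting
  limit).
* Measurement rows are always emitted in label order L, M, R; the
  right-first display order used in the source figures is cosmetic since
  every value is labelled.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run: ground-truth recovery on a
~2,000-vertex default mesh (< 1 s); 200 estimator-recovery replicates at
n = 200 subjects × 2 sessions (~10 s); and a full geometric study of 12
subjects × 5 levels × 3 sessions (~2 s). These sizes were chosen to make
the checks quick while keeping the estimator-recovery test at the scale
where the ±0.05 coverage band corresponds to ±2 standard errors.

## Known limitations

* With 0.3 mm landmark jitter the lateral-plane inferior-endplate
  dimensions (L/R IED and IECD) are the most sensitive outputs: the
  inferior rim chord lies at the base of the midline landmark triangle and
  is extrapolated laterally, so posterior-rim-midpoint jitter is amplified
  (~0.4 mm propagated SD for IED). Their population ICC under the default
  study conditions is ~0.92–0.94, so individual 12-subject cells can
  occasionally fall below the 0.75 "excellent" threshold at some random
  seeds — mirroring the original study, where a minority of cells also fell
  below 0.75. Mid-sagittal dimensions are an order of magnitude more
  stable.
* The exact Wilcoxon enumeration is limited to m ≤ 12 non-zero differences
  (4096 sign patterns); beyond that the corrected normal approximation is
  used.
* Mesh input is trusted to be in millimetres; only a bounding-box sanity
  warning (< 5 mm or > 500 mm extent) guards against unit errors.
* Landmark *detection* is out of scope: landmarks are observer-supplied, as
  in the manual protocol the package models.
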