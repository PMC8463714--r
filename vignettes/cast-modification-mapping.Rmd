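---
title: "Mapping plaster cast modifications: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping plaster cast modifications: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castmap)
```

## The problem

Custom ankle–foot orthoses (AFOs) are traditionally thermoformed over a
plaster cast of the lower leg that an orthotist first *rectifies*: plaster is
added over bony prominences, the toe box and anterior borders, and removed to
flatten the plantar surface and clean casting artefacts. That craft knowledge
is mostly undocumented. Given 3D scans of the cast **before** and **after**
rectification, castmap quantifies the rectification as a signed per-vertex
distance field — the *mesh-to-mesh difference* (MMD) — and relates its
summaries to participant characteristics across a cohort.

The pipeline is: rigid registration of the pre-modification mesh to the
post-modification mesh (landmark initialisation + trimmed iterative closest
point), a signed nearest-surface distance field on the pre cast, per-cast
summaries (pMMD/nMMD/mMMD), a colour-coded modification map, and two
statistical layers — intra-rater reliability (two-way intraclass correlation,
symmetric percentage error) and cohort association (Spearman with Portney
categories, Kruskal–Wallis).

## The signed distance model

For a query point $v$ on the pre cast and the post surface $S$, the MMD is

$$\mathrm{MMD}(v) = \pm \min_{q \in S} \lVert v - q \rVert,$$

positive when $v$ lies **inside** the post solid (plaster was added over it)
and negative when it lies outside (plaster was removed). The sign is the sign
of $-(v - q^\*) \cdot n(q^\*)$, where $n(q^\*)$ is the angle-weighted
pseudonormal at the closest point $q^\*$ — the face normal when $q^\*$ is
interior to a triangle, the mean of the two adjacent face normals on an edge,
and the angle-weighted vertex normal at a vertex. This classification is
exact for watertight meshes. When the dot product is numerically zero
(|dot| < 1e-9) the decision falls back to ray-casting parity on watertight
targets; on open scans such points are excluded from summaries and counted.

Per pair we report, over the sampled values $d_i$:

* **pMMD** — mean of the positive $d_i$ (mean addition depth where added),
* **nMMD** — mean magnitude of the negative $d_i$,
* **mMMD** — mean of $|d_i|$ over *all* samples (zeros included),
* the positive/negative maxima and counts.

mMMD is a mean **magnitude**, not a signed mean: a signed mean would be
dragged towards zero by cancellation and could not sit between the one-signed
means, which is how these three summaries are ordinarily reported. Zeros
(|d| < 1e-9 mm) count in mMMD but in neither pMMD nor nMMD, so when a cast
has large untouched regions mMMD legitimately falls below both one-signed
means. In `mode = "bidirectional"` the post-to-pre map is pooled after
negating its signs, keeping "addition" expressed relative to the pre cast;
one-way per-vertex sampling is the default because it is exactly
reproducible.

The nearest-point kernel is exact point-to-triangle minimisation under an
axis-aligned bounding-box hierarchy (C++); the test suite checks it against a
brute-force all-triangle scan at 1e-9 mm on seeded random meshes.

## Registration

Pre and post casts are the same physical object up to rectification, so the
alignment model is strictly rigid (rotation + translation, no scaling).

* **Initialisation**: least-squares superposition of labelled landmark pairs
  (Kabsch/SVD, reflections excluded), requiring at least 3 non-collinear
  matches. Without landmarks, centroid + principal axes with the proper
  axis-sign hypothesis chosen by lowest median nearest-surface distance.
* **Refinement**: trimmed point-to-point ICP. An area-uniform seeded sample
  of the source surface (default 5,000 points) is matched to nearest points
  on the target, the worst `trim_fraction` (default 0.2) of pairs by distance
  are discarded, and the pose is re-estimated by Kabsch on the survivors.
  Trimming is what makes ICP appropriate here: the casts *genuinely differ*
  where plaster was modified, and without it those regions bias the rigid
  fit. The trimmed RMS is provably non-increasing, and iteration stops when
  it changes by less than `convergence_tol_mm` (default 1e-4 mm, well below
  any plausible modification magnitude) or at 200 iterations.

On synthetic casts displaced by 10° and a few millimetres, landmark-seeded
trimmed ICP recovers the pose to well under 0.1° / 0.05 mm even with 3 mm
modifications planted on ~15 % of the surface (see the acceptance tests).

## Reliability statistics

Scan-rescan and re-registration reproducibility use the single-measure
intraclass correlation from a two-way subjects × sessions ANOVA:

* absolute agreement: $(MS_R - MS_E) / (MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E))$
* consistency (3,1): $(MS_R - MS_E) / (MS_R + (k-1)MS_E)$

Both are always reported because the two labels are frequently conflated in
applied work; absolute agreement is the headline since it additionally
penalises systematic session offsets. Two estimator facts worth knowing: the
usual claim "agreement ≤ consistency" holds only when the observed session
mean square is at least the error mean square (the estimated session variance
component can be negative, flipping the inequality), and the two forms
coincide only when $MS_C = MS_E$, not merely when the session means are
equal. The implementation does not truncate negative variance components.
Percentage error between replicates is symmetric,
$100\,|a-b| / \tfrac{a+b}{2}$, so neither replicate is privileged.

## Cohort statistics

Spearman's $r_s$ is the Pearson correlation of mid-ranks; p-values come from
the $t$ approximation on $n-2$ df or a seeded permutation (preferable for the
tiny subgroups such cohorts contain). Strength categories on $|r_s|$ follow
Portney (left-closed: [0, 0.25) little/none, [0.25, 0.50) fair,
[0.50, 0.75) moderate, [0.75, 1] excellent) and effect categories use
(0.10, 0.30) small, [0.30, 0.50] medium, (0.50, 1] large, with boundaries
fixed and documented because the verbal conventions do not specify them.
Kruskal–Wallis uses the tie-corrected $H$ with a $\chi^2$ or permutation
p-value. The cohort report is the full 12-cell grid — {age, height} ×
{pMMD, nMMD, mMMD} correlations and {AFO type, pathology} × the same
outcomes — with pairwise-complete deletion per analysis (each row carries its
own $n$), singleton groups excluded and noted, and **no** multiple-testing
correction; the number of tests performed is reported alongside instead.

## The synthetic-data generator

No scan data accompany the method, so validation rests on synthetic casts
with exactly known ground truth.

* `make_cast()` sweeps a capsule along a planar bent centreline (vertical
  shank, smoothstepped ankle bend, horizontal foot) by smoothly deforming a
  subdivided icosphere, so the mesh is watertight by construction.
  Child-scale defaults: shank 250 mm tapering 42→30 mm, foot 170 × 26 mm,
  plantigrade 90°, 6 mm target edge length (~10k vertices). The shape is
  deliberately schematic — the pipeline assumes cast-like topology and scale,
  not anatomy — and the radius profile narrows to the foot radius at the
  ankle so the sole is a proper flat-bottomed strip.
* `plant_modifications()` displaces vertices along their pseudonormals with
  cosine-falloff patches (amplitude reached at the centre), an optional thin
  uniform "smoothing" layer, and a plantar flattening that projects sole
  vertices onto a horizontal plane; the exact per-vertex displacement is the
  stored ground truth. A cheap guard (|amplitude| < patch radius, ±10 mm
  envelope) stands in for a full self-intersection test.
* `perturb_mesh()` applies a known rigid pose plus isotropic Gaussian vertex
  jitter, emulating a re-scan.
* `simulate_cohort()` draws ages uniform on 1–18 y, heights from a quadratic
  paediatric growth curve (±6 cm residual), AFO type and pathology from
  realistic clinic proportions (fixed 30 : hinged 16 : PLS 2 : SMO 1 :
  unknown 1 and CP 25 : CTEV 6 : SB 5 : NF1 2 : Other 12 per 50, so
  singleton-group pathologies are exercised), masks 16 % of heights, and
  plants a linear height effect on the addition amplitude,
  $A = a + b\,h + \varepsilon$, truncated at 0.3 mm.
  `calibrate_height_slope()` root-finds the slope that yields a chosen
  population Spearman correlation (default target 0.35).

**What passing tests do and do not show.** The generator produces clean,
watertight, hole-free, topologically simple surfaces with modifications that
are exactly normal displacements. Real scans have holes, fusion artefacts,
non-uniform triangulation and modifications that slide tangentially; passing
here demonstrates the correctness of the algorithms and the honesty of the
statistics, not robustness to every scanning pathology. Two known geometric
effects are documented deliberately: on strongly convex regions (the toe
cap) the recovered maximum underestimates the planted amplitude by up to
~10 % at the default resolution, because the nearest point on an outward
displaced convex surface is nearer than the displacement itself; and mMMD
dilutes towards zero when most of the surface is untouched, which is a
property of the measure, not a defect.

## Numerical choices

* Millimetres everywhere; these mesh formats carry no unit metadata.
* Vertex merge tolerance 1e-6 mm (exact duplicates only, far below scanner
  resolution); faces below 1e-9 mm² dropped; watertight meshes auto-flipped
  to outward orientation (positive signed volume) on load.
* Values with |d| < 1e-9 mm are zeros — neither addition nor subtraction.
* Volume is reported only for watertight meshes, never fabricated for open
  scans; distance mapping accepts open targets (with sign fallback counts).
* All stochastic stages (surface sampling, permutations, simulations)
  consume explicit seeds; identical configuration gives byte-identical
  outputs.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` use: subdivision-4 icospheres
(5,120 faces) for the analytic concentric-sphere limit; a default-resolution
cast (~20k faces) for registration and loop-closure checks; 20 seeded
320-face meshes × 1,000 query points for the brute-force distance oracle;
100 seeded 10×2 matrices for the ICC oracle; exhaustive 720-permutation
enumeration for the Spearman p oracle and 1e5 label permutations for
Kruskal–Wallis; 1,000 summary-level null cohorts and 200 calibrated cohorts
of n = 50 for size and power. Summary-level cohorts compute each
participant's MMD summary directly from the planted ground-truth field on a
shared template cast — the same field the full register+map pipeline is shown
to recover to < 0.1 mm RMSE — which is what makes thousand-cohort
simulations practical while staying faithful to the measured quantity.

## Known limitations

* Rigid registration only; casts re-scanned in a deformed state are out of
  scope, as are scale changes.
* No region-of-interest segmentation: summaries pool the whole surface.
* The synthetic cast is anatomically crude by design; deformity-specific
  geometries (e.g. equinovarus) are not modelled.
* ICC confidence intervals are not computed.
* Amplitude recovery degrades with surface curvature at coarse resolution
  (toe-cap effect above).
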