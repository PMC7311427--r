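---
title: "Methods: automated labeling and A1 variant classification of the Circle of Willis"
author: "cowpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated labeling and A1 variant classification of the Circle of Willis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The Circle of Willis (CoW) is the arterial ring that links the left and
right anterior circulations with the posterior circulation and is the
brain's main source of collateral flow. Its segments are absent or
diminished in a large fraction of the population; in particular the A1
segment of the anterior cerebral artery may be aplastic (absent) or
hypoplastic (markedly thinner than its contralateral partner). `cowpipe`
implements a fully automatic pipeline that takes a time-of-flight
MRA-like volume, segments the bright vasculature, reduces it to a
one-voxel-thick skeleton, converts the skeleton to a graph of nodes
(branching and end points) and edges (vessel segments), labels the
end-basilar and left/right M1/A1 branching points against an atlas of
expected positions, and classifies A1 anatomy as normal or variant.
Aplasia is detected through *failure*: when one internal carotid terminus
has no bifurcation to find, the symmetric pair search either returns
nothing on that side or falls back on near-midline nodes, and the
symmetry score S collapses. Hypoplasia, which leaves the bifurcation
intact, is scored afterwards from bilateral radius/intensity features
(F and the reduced fitted form F*).

Throughout, world coordinates are in millimetres with x running posterior
to anterior, y left to right, and z inferior to superior; the median
sagittal plane is the plane `y = m`.

## Pipeline stages and their parameters

**Preprocessing.** Input volumes are assumed skull-free and already
rigidly aligned to atlas space (brain extraction, bias correction and
deformable registration are established external tools, not
re-implemented; the pipeline exposes the histogram-matching reference and
atlas landmarks as configuration instead). `histogram_match()` performs
linear histogram matching: an affine intensity map that carries the
input's robust range onto the reference's. The anchors are the 1st-99th
percentiles; for sparse angiographic volumes whose voxels are
overwhelmingly background, that band can degenerate, in which case the
full min-max range is used. The map is monotone, hence rank-preserving,
and idempotent against a fixed reference. `resample_to_atlas()`
trilinearly resamples onto an isotropic 0.5 mm grid, preserving world
coordinates; trilinear weights are convex, so no new intensity extrema
appear.

**Two-phase segmentation.** Both phases run the same chain — a light
Gaussian denoising filter (SD 0.4 mm, the stand-in for the nonlinear
noise filtering a clinical pipeline applies upstream), adaptive k-means
intensity clustering, then a Chan-Vese active contour — but with
different rigidity:

* *adaptive k-means*: voxel intensities are rescaled to 0-255 and
  clustered with K = 4 centres seeded deterministically at evenly spaced
  intensities (reproducibility over random restarts). Centres closer than
  10 units on that axis are merged size-weighted; the phrase "minimum
  distance between cluster centres" is read as an intensity-space
  distance, the reading that makes merging well defined for a global
  intensity clustering. The strict phase keeps the single brightest
  cluster; the relaxed phase keeps the top three, deliberately admitting
  dim, thin structure (over-segmentation by design).
* *Chan-Vese*: the two-phase piecewise-constant energy
  \(E = \lambda_1 \sum_{in}(I-c_1)^2 + \lambda_2 \sum_{out}(I-c_2)^2 +
  \mu\,\mathrm{Per}\) is minimized by iterated conditional modes on the
  binary label field, restricted to the boundary band, with the region
  means re-estimated each sweep. Every accepted flip strictly lowers the
  energy at the current means and each mean update lowers it further, so
  the per-iteration energy trace is non-increasing by construction (this
  is asserted in the tests). The perimeter is the face-area interface
  (6-connectivity, spacing-aware). Defaults: strict
  \(\mu = 0.05, \lambda_1 = 2, \lambda_2 = 1\) (inside homogeneity is
  enforced, keeping dim vessels out); relaxed
  \(\mu = 0.01, \lambda_1 = \lambda_2 = 1\) (a small perimeter weight
  removes isolated noise voxels without eating one-voxel-thick
  communicating arteries). Iteration cap 200, tolerance 1e-4 changed
  fraction; a mask that empties or fills is returned as the
  initialization with a warning. Intensities are unit-normalized
  internally so these weights transfer across inputs; with per-scanner
  YAML profiles the same machinery covers heterogeneous acquisitions.

The strict mask is forced into the relaxed mask (union), so
`mask_strict` ⊆ `mask_relaxed` always holds — the skeleton-preservation
step below requires it.

**Skeletonization and graph.** `skeletonize3d()` is a sequential
six-subiteration topology-preserving thinning (26-connected foreground,
6-connected background): border voxels are peeled direction by direction
and deleted only if they are simple points and not curve end points, so
the skeleton has exactly as many connected components as the mask. The
Phase-1 (strict) skeleton is passed as a preserve set when thinning the
Phase-2 (relaxed) mask: preserved voxels are never deleted, which is what
ties the two phases together — the stable central skeleton survives
inside the over-segmented periphery. Terminal whiskers shorter than 3
voxels are suppressed before graph conversion, because raw thinning emits
one- and two-voxel spurs wherever the tube surface is rough.

One caveat established while validating the thinning: perfectly
grid-symmetric even-width objects (a tube whose axis lies exactly on a
voxel-boundary plane) can erode away entirely. The canonical Lee-style
reference implementation shows the same degeneracy, and generic or noisy
masks are unaffected; the phantom places no tube in that configuration
with noise present.

`skeleton_to_graph()` turns voxels with a neighbor count other than two
into nodes (adjacent node voxels grouped, lexicographic tie-break so runs
are bit-reproducible), traces degree-2 chains into edges with arc length
in mm, and anchors closed loops at their smallest voxel as a self-edge.
`prune()` removes terminal edges shorter than 10 voxels (the configured
minimum skeleton segment length), re-merges the resulting degree-2
nodes, and also dissolves two skeletonization artifacts: small cycles
(self-edges or parallel edge pairs whose total cycle is at most twice the
pruning length — these arise precisely where the preserved Phase-1 path
and the Phase-2 thinning disagree by one voxel) keep only their shorter
branch, and degenerate junction clusters left with exactly two incident
edges are reduced to a connector path so the through-edge re-merges.
Pruning iterates to a fixed point and is idempotent.

`merge_big_nodes()` clusters branch nodes within 5 mm by single linkage
into *big nodes* — an anatomical branching point such as the basilar tip,
where both P1 segments, both superior cerebellar arteries and the basilar
artery meet, fragments into several skeleton junctions within a small
region. Single linkage matches the permissive "region where all visible
arteries meet" notion; clusters whose diameter exceeds twice the radius
are split post hoc.

**Labeling.** Candidates for each anatomical label are the big nodes
within 30 mm of the corresponding atlas landmark (closed ball, three
nearest kept). The basilar tip maximizes
\(B(n) = \pm d_y(n, m) - h(n)_x\), where \(d_y\) is the absolute midline
offset of the node centre and \(h(n)_x\) the x (posterior-anterior)
projection of the centre of mass of its branch voxels. As printed, the
first term rewards *distance* from the midline, which contradicts
basilar anatomy (the basilar tip is the midline-hugging, most posterior
candidate); both sign conventions are implemented behind
`negate_midline_term`, and the default (negated, i.e. midline proximity
rewarded) is the one that identifies the ground-truth basilar node on
phantoms. The literal reading remains one flag away.

The M1/A1 search is bilateral. Per side, candidates keep their branch
y-extent \(e_i = \min(15\,\mathrm{mm}, \max |y - y_{node}|)\), where a
branch is followed through pure continuation nodes (exactly two incident
edges — skeleton path splits, not anatomy) so that the extent reflects
the full M1 wingspan. Left-right pairs are scored with
\(g(i,j) = \beta d(i,j) - \max(d_y(i,m), d_y(j,m))\) (the max is read
over both nodes of the pair) and
\(M(i,j) = \alpha|e_i - e_j| - g(i,j)\); the pair with the highest M is
selected, ties broken by distance to the landmarks. Two design decisions
matter here:

* The node already labeled as the basilar tip is excluded from the
  carotid candidate pool. The pipeline is sequential (posterior
  circulation first), and the exclusion is also forced algebraically:
  the basilar tip ties any true M1/A1 node on \(|e_i - e_j|\) (both reach
  the 15 mm cap) while sitting closer to the contralateral candidate, so
  without the exclusion the (M1/A1, basilar) pair outranks the true pair
  for every \(\alpha, \beta\).
* \(\alpha, \beta\) have no canonical values; a pilot grid over the
  phantom cohorts froze \(\alpha = -2\), \(\beta = 0.3\) (negative
  \(\alpha\) penalizes extent-asymmetric pairs, small \(\beta\) keeps the
  distance term from dominating the midline-offset term in g). They are
  exposed in the configuration.

The winning pair is then scored for symmetry:
\(S(i,j) = g(i,j) - |y_i - y_j| / \min(y_i, y_j)^2\) with \(y_i\) the
absolute midline offsets. The penalty explodes for midline-hugging
pairs — exactly the fallback selection an aplastic side produces — and a
node on the midline itself yields a \(-\infty\) sentinel.
`classify_a1()` reports *variant* when a side is unlabeled or when
\(S < s_{threshold}\); the default threshold \(-8\) is the Youden point
of the phantom ROC: normal pairs concentrate near \(-6\) while failures
score below \(-50\) or fail outright, so the operating point is not
delicate. S is evaluated on the winning M-pair only.

**Features and hypoplasia.** For each labeled side, the A1 path is the
incident edge that heads medially — the edge minimizing the smallest
midline offset reached *along* its voxel path. (The far-endpoint offset
is not a usable criterion: in a complete CoW the A1 edge continues
through the degree-2 anterior-communicating junction to the contralateral
bifurcation, so its far endpoint is lateral.) The path is truncated at
the first node encountered moving medially or at the median sagittal
plane crossing, whichever comes first; a side with no medial edge is
flagged aplastic-by-feature. The artery volume is modeled as the union of
maximal spheres centred on the path inside the relaxed mask, with radii
from a spacing-aware Euclidean distance transform; \(r\) is the mean
sphere radius and \(p\) the mean intensity over the union (on the
histogram-matched scale — required for cross-subject comparability).
Tortuosity is arc length over end-point chord (the two quantities named
by the definition, combined as the field's standard ratio), so
\(T \ge 1\) with equality exactly for straight paths. \(H(i,j)\) is 1
iff only side i's path ends at a free skeleton end. These feed
\(F_i = a|r_i - r_j| + b|p_i - p_j| + H(i,j) - c|T_i + T_j|\) (weights
configurable; no canonical values exist) and the reduced fitted score
\(F^* = 0.19367\,|r_i - r_j| - 7.1199\,|p_i - p_j|\), whose coefficients
are fixed. `fit_fstar_coefficients()` reproduces the fitting route: OLS
of a normal/variant response on the four F terms, dropping terms with
coefficient p ≥ 0.05 and refitting. On a noiseless synthetic cohort whose
response is the linear score itself, the generating coefficients are
recovered exactly; a thresholded 0/1 response identifies the surviving
terms and their signs but not the absolute scale (OLS on a thresholded
response cannot).

## The synthetic phantom

The generator is the package's validation instrument: it emulates what
the labeling stages consume — bright tubular vessels on a dark
background in the textbook complete-CoW topology, with the A1
aplasia/hypoplasia variants — with known ground truth (node positions,
per-segment radius, tortuosity, mean intensity, midline position).

* Geometry: 16 vessels (ICA/M1/A1 pairs, ACo, BA, P1/P2/SCA/PCo pairs)
  hand-authored once as spline control points on an 80 × 80 × 40 mm world
  box, midline at y = 40; the right side is the exact mirror of the left,
  and the noise-free complete-variant rasterization is voxelwise
  mirror-symmetric (asserted in the tests). Radii 0.5-2.0 mm, A1 at
  1.6 mm so that a hypoplasia factor of 0.4 (0.64 mm) stays resolvable at
  the 0.5 mm grid.
* Intensities: arbitrary units, 0.20 at the carotid down to 0.11 for the
  anterior communicating artery, with a linear -0.4 %/mm decay along each
  vessel as the flow-saturation analogue. The posterior communicating
  arteries are set far dimmer (0.03), below any segmentation threshold:
  on clinical TOF they are frequently invisible for the same
  flow-saturation reason, and their invisibility is what makes an
  aplastic carotid terminus produce *no* lateral candidate.
* Rasterization: tubes are the union of spheres along a densely resampled
  spline centreline; partial volume is handled by rasterizing at 3× per
  axis and averaging down (this stabilizes radius recovery at coarse
  grids). Overlapping vessels combine by maximum.
* Noise: additive zero-mean Gaussian, SD 0.1 of the brightest baseline,
  clipped at zero. Gaussian rather than Rician is a deliberate
  simplification — adequate for exercising thresholding behaviour, wrong
  as MR physics in the low-signal tail.
* The complete-variant ground truth doubles as the default atlas (an
  artifact convention; clinical use would supply an atlas built from a
  registered healthy reference).

What the phantom does *not* emulate — skull and brain tissue background,
bias fields, registration error, motion, Rician noise, anatomical
variability of the geometry itself — bounds what green tests mean:
they validate the algorithmic chain under its stated assumptions, not
performance on clinical data.

## Problem sizes and numerical choices

The validation suite runs 20 complete-variant phantoms (0.5 mm grid,
noise 0.1, seeds 1-20) for node recovery within 5 mm, 20 aplastic
phantoms for variant detection, their 20 + 20 union for the S-threshold
ROC, and 1 mm phantoms for the structural invariants; these sizes keep
the full suite in single-digit minutes on one CPU while leaving the
binomial ceiling (20/20) meaningful. Degenerate inputs are handled
explicitly: constant volumes are rejected by histogram matching and
clustering; an empty candidate set yields an indeterminate basilar label
and feeds the variant rule for M1/A1; midline nodes yield the S
sentinel; loops are anchored deterministically; all tie-breaks
(candidate order, node grouping) are lexicographic so reruns are
bit-identical.

## Limitations

The phantom ROC is effectively saturated (normal and aplastic S
distributions do not overlap under the study conditions), so the
reported AUC exercises the machinery rather than estimating clinical
discrimination; the clinical figure of merit would have to come from
real cohorts. F* separates hypoplastic phantoms through the radius term
while matched intensities keep the p term small — with real
flow-dependent contrast the intensity term is a confound, and the F
weights would need refitting per population. Aneurysms do not alter
branching-point topology and are invisible to this approach by design.
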