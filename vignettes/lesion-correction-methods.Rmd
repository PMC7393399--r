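---
title: "Lesion-corrected cortical volumetrics: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-corrected cortical volumetrics: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

Surface-based volumetry represents the cortex as a triangulated mesh
with a per-vertex thickness field $t_v$ (mm), the distance to the paired
gray–white surface vertex. `lesionsurf` attributes to each vertex one
third of the area of its incident triangles,

$$a_v = \tfrac{1}{3}\sum_{f \ni v} A_f,$$

so that vertex areas conserve the total mesh area exactly. A region $R$
(here, a network of a 7-network functional parcellation) then has

$$A_R = \sum_{v \in R} a_v, \qquad
  \bar t_R = \frac{\sum_{v \in R} a_v\, t_v}{\sum_{v \in R} a_v}, \qquad
  V_R = \frac{A_R\, \bar t_R}{1000}\ \text{ml}.$$

The uniform one-third area split was chosen over Voronoi/mixed vertex
areas because every quantity the package reports is a *regional sum*:
any per-vertex split that conserves triangle area gives identical
regional areas up to the assignment of boundary vertices, and the
one-third rule is simple, always non-negative, and exactly conservative.
Mean thickness is area-weighted by default, consistent with the
area-based volume formula (an unweighted option exists; with
near-uniform meshes the two differ negligibly).

Lesion correction is an *exclusion*, not an edit: the labelled vertices
are dropped from $R$ and the three quantities are recomputed. This
yields the conservation identity tested throughout the package: for
every region, pre-correction area equals post-correction area plus the
lesion-overlap area. A region fully covered by the overlay is reported
with zero vertices and undefined thickness rather than silently
vanishing.

The underlying scientific assumption — that cortex under a lesion label
is non-functional and should not contribute to volumetrics — is a
modelling decision of the method, not something the package can verify;
the package's job is to apply it exactly and reproducibly.

## Labeling semantics

The interactive workflow being reproduced draws a chain of anchor
points, closes it, and flood-fills the enclosed patch:

* `close_path()` joins consecutive anchors (and last back to first) by
  shortest paths on the mesh *edge graph* with Euclidean edge lengths.
  Graph geodesics, not exact polyhedral geodesics, were chosen because
  they match how an interactive tool connects clicked vertices and admit
  a simple independent oracle (any Dijkstra implementation). Ties in
  path length are broken toward the lower-indexed predecessor, making
  paths reproducible across runs and platforms.
* `flood_fill()` performs breadth-first search from the seed, blocked at
  boundary vertices. The returned label **includes the boundary**: the
  drawn outline passes through inaccurate surface, so excluding it too
  is the conservative choice. Users wanting an interior-only label can
  subtract the path vertices. Fills from any seed inside the same
  enclosed component give identical labels (seed invariance), and the
  interior fill, exterior fill and boundary together partition the mesh.
* A fill that reaches more than `max_fill_fraction` (default 0.5) of the
  mesh vertices aborts with a "fill escaped outline" error. An unclosed
  outline otherwise floods the whole hemisphere silently — the failure
  mode an interactive user catches by eye; 0.5 is far above any
  plausible single-lesion extent and far below a whole-hemisphere flood,
  so the guard cannot misfire on legitimate lesions. It is configurable
  for unusual cases.

Labels follow the protocol naming `"<hemi>.lesion-NN.label"` with a
zero-padded ordinal in 1..99, and per-hemisphere overlays are plain
vertex-set unions (`<hemi>.all-lesions`), written both as a label file
and as a curv-format 0/1 indicator field so that either representation
can be consumed downstream.

## Network overlap reporting

* Percent surface area affected: $100\cdot a(\text{lesions} \cap
  \text{network}) / a(\text{network})$, with unassigned (region-0)
  vertices in no denominator.
* A network counts as lesioned when at least one lesion vertex falls in
  it; no minimum-area threshold is applied, and one lesion can count
  toward several networks (so network counts sum to more than the number
  of lesions).
* Percent volume change is $100 (V_\text{post} - V_\text{pre}) / V$,
  with the denominator selectable as the pre- or post-correction volume
  (default post). Both conventions appear in practice and the sign is
  reported as computed rather than forced: with genuinely thinned lesion
  tissue, post-correction volume can move in either direction depending
  on whether the area loss or the thickness correction dominates, so the
  package exposes the choice instead of hard-coding one reading.

## Quality-control statistics

* **SNR** $= \mu/\sigma$ within the white-matter mask (sample SD).
  Scale-invariant, deliberately not offset-invariant.
* **CNR** = mean of the WM–GM and GM–CSF contrasts with
  $\text{contrast}(a,b) = |\mu_a-\mu_b| / \sqrt{(\sigma_a^2+\sigma_b^2)/2}$.
  The pooled-SD form was adopted as the contrast normalization; it is
  offset- and scale-invariant and symmetric under relabeling of the
  outer tissue classes.
* **ABC/2**: $A\,B\,C/2000$ ml from mm diameters. From a mask, A is the
  maximum pairwise distance between lesion voxel centers on the axial
  slice with the largest cross-section (ties: lowest slice index), B the
  center-point extent perpendicular to A's direction, and C the number
  of lesion-bearing slices times slice thickness. Measuring over voxel
  centers slightly underestimates diameters (by up to one voxel); for
  the 40×30×20 mm reference ellipsoid at 1 mm the estimate lands at
  12.6 ml against the analytic 12.57 ml.
* **ICC**: two-way single-measurement coefficients from the
  subjects-by-raters mean squares. The default is absolute agreement,
  ICC(2,1) — the natural choice when raters should produce
  interchangeable volume measurements — with consistency ICC(3,1) via a
  flag. Intervals are the standard F-based constructions
  (Satterthwaite-approximated degrees of freedom for agreement). With
  degenerate perfect-agreement input (zero error mean square) the
  interval collapses to the point estimate.

## The synthetic generator

`make_subject()` emulates the inputs of a surface pipeline, not their
biology: spheres (optionally sinusoidally "wrinkled" so vertex areas are
not all equal) stand in for folded cortices, because every statistic
here is geometry-agnostic and spheres provide analytic area checks.
Defaults: subdivision 4 (2562 vertices/hemisphere), radius 70 mm
(hemisphere area ≈ 6.2·10⁴ mm², a realistic pial-surface magnitude),
base thickness 2.5 mm with a ±0.3 mm low-frequency perturbation
(typical cortical thickness and smooth regional variation), lesion
thinning factor 0.25 (severe focal thinning). The parcellation grows 7
contiguous patches by nearest-centroid assignment from seeded random
centers. Lesions grow breadth-first from a random in-network seed
vertex, adding vertices in deterministic index order until the
accumulated vertex-area fraction of the network first reaches the
target; the achieved fraction therefore overshoots by at most one
vertex area, and that quantization bound is recorded in the ground
truth next to the exact pre/post statistics (computed by a plain
per-vertex loop, independent of the vectorized statistics path). All
randomness flows from one seed through per-component subseeds, and
identical seeds give byte-identical subject directories.

What the generator does **not** emulate — folding geometry, surface
reconstruction failure modes, partial-volume effects, registration
error, raters — bounds what green tests mean: they validate the
statistics, formats and labeling semantics exactly, not the upstream
reconstruction or the human outlining step.

`make_phantom()` provides concentric WM/GM/CSF shells with Gaussian
intensities for SNR/CNR recovery and ellipsoidal lesion masks for
ABC/2; odd default dimensions (63³) center the grid on a voxel so
symmetric shapes digitize symmetrically. `make_rater_data()` generates
subjects-by-raters volume matrices with known theoretical ICC
$\sigma^2_\text{true}/(\sigma^2_\text{true} + \overline{\sigma^2_\text{rater}})$.

## Numerical and interface choices

* Vertex indices are 0-based in every user-facing structure, matching
  the on-disk label format; R's 1-based indexing is confined to
  internals.
* All binary formats are big-endian regardless of host, and writers are
  deterministic (fixed creator comments, no timestamps), so identical
  inputs give byte-identical files; cross-implementation fidelity is
  tested against nibabel on small fixtures.
* Hemisphere is a property of the file/mesh (the `lh.`/`rh.` prefix),
  never inferred geometrically; a filename prefix contradicting a
  caller-declared hemisphere is an error.
* Degenerate inputs: zero-area faces yield area 0 with a warning;
  empty labels are errors on read and write; constant-intensity masks
  are errors for SNR; disconnected anchor pairs name the component
  sizes.
* Conservation and oracle-equivalence checks use relative tolerances of
  1e-6 to 1e-9; format round trips are exact for indices and ids and
  float32-limited for coordinates and scalars.

## Problem sizes used in the test suite

Unit and property tests run on icospheres at subdivisions 2–3 (162–642
vertices) with cohorts of 20–50 synthetic subjects; recovery and
analytic checks use subdivision 4 (2562 vertices); phantom statistics
use up to 127³ grids (~10⁵ white-matter voxels) and ICC coverage uses
100 replicates at 500 subjects × 2 raters. These sizes put every
quantity's Monte-Carlo or quantization error well inside the asserted
tolerances while keeping the whole suite interactive.

## Known limitations

* Group frequency maps assume overlays already live on a common
  template mesh; cross-subject surface registration is upstream work.
* Graph geodesics overestimate true surface distance on coarse meshes;
  outlines hug the drawn chain, which is the intended semantics, but
  path *lengths* should not be interpreted metrically.
* ABC/2 from masks is a caliper heuristic, not an integral volume; use
  voxel counting where the mask itself is trusted.
* The percent-volume-change sign convention differs between published
  tables depending on the chosen denominator and on whether lesioned
  thickness is near zero or merely unreliable; both denominators are
  exposed, and reported values are signed as computed.
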