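---
title: "Methods: geometry, simulation and learning in crownforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, simulation and learning in crownforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

crownforge implements a three-phase digital workflow for partial dental
crowns (inlays and onlays): quantitative comparison of 3D surface scans,
prosthesis synthesis by two CAD principles, and a volumetric convolutional
classifier that predicts the prosthesis type from a voxelized tooth
preparation.  Because clinical scan data cannot be redistributed, every
input is produced by a procedural anatomy simulator whose defaults encode
the study conditions; this vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic data can and
cannot demonstrate.

## Geometric substrate

**Meshes and solids.** All geometry is exchanged as triangle meshes in mm
coordinates (both STL dialects are read and written; facets are merged into
shared vertices within 1e-6 mm on load because STL stores facets
independently and topology checks need shared edges).  A mesh is accepted
as a solid when it is watertight: every undirected edge shared by exactly
two faces, with consistent winding.  Surface area is the triangle-area sum;
volume is the signed-tetrahedron (divergence) sum, with an inverted global
orientation auto-corrected under a warning since scanners emit either
winding.

**Voxel grids.** Solids are rasterized on axis-aligned grids with isotropic
pitch; a voxel is occupied iff its *center* lies inside the closed surface,
decided by z-column ray parity.  Center-based occupancy makes the
brute-force inside-test oracle exact (the test suite checks agreement
voxel-for-voxel on small grids) and keeps the Dice coefficient symmetric.
Ray queries are shifted by distinct sub-nanometre offsets in x and y so
that column rays never pass exactly through triangle edges or the shared
diagonals of axis-aligned faces; the induced geometric error is far below
every tolerance used.  The default pitch is 0.1 mm: crowns span 8-12 mm and
the deviations of interest live at 0.02-0.10 mm, so 0.1 mm resolves them
while keeping grids near 100^3.

**Isosurfacing.** Grids and implicit fields are contoured by marching
tetrahedra on the Kuhn 6-tetrahedron cube decomposition.  Unlike classic
marching cubes, the tetrahedral case table has no ambiguous
configurations, and the Kuhn split is translation-invariant, so face
triangulations match across cells and the output is watertight by
construction.  Edge-interpolated vertices are deduplicated through global
edge keys.  The cost is more triangles per surface cell (about eight); the
scan simulator accounts for this when converting a triangle budget into a
sampling pitch.

**Signed distance CSG.** Boolean solid operations run on voxel grids that
carry a clamped narrow-band signed distance (positive inside, exact within
two cells of the surface, clamped to ±2.5 pitch elsewhere): union, is the
voxelwise max; subtraction is `min(a, -b)`.  Compared with raw 0/1
occupancy Booleans this recovers sub-voxel surface placement at
re-extraction while keeping identical set semantics, which is why the
conservation identity (preparation + prosthesis = template) holds to a
fraction of a percent rather than a voxel-count error.  Meshes produced by
the anatomy simulator additionally carry their analytic implicit field as
a closure; when present, CSG samples the closure directly and projects
extracted vertices onto the zero set by two damped Newton steps
(central-difference gradients, step capped at 0.2 mm), making remeshing
error quadratic in pitch.

## Procedural anatomy

The intact crown is a superellipsoid-like implicit solid: a rounded-square
lateral cross-section (exponent 3.5) whose half-widths follow a barrel
profile over height, closed below by the base plane and above by an
occlusal surface built from a central fossa plus four Gaussian cusps.
This is deliberately the *minimum* geometry exhibiting the features the
workflow manipulates — proximal surfaces, occlusal anatomy, cusp-reduction
semantics; it is not an anatomically realistic tooth library, and no root
is modelled (scans of preparations concern the crown).  Default dimensions
(9 x 8 x 7 mm before seed jitter) were fixed once so that generated crowns
span roughly 300-400 mm^3, centred near 345 mm^3 — the volume scale of
scanned molar crowns; each seed jitters dimensions and cusp layout by a
few percent.

**Preparations.** The MOD cavity is an implicit solid: an occlusal channel
with buccal and lingual walls parallel to each other and perpendicular to
the occlusal plane, plus proximal boxes extended gingivally whose axial
walls diverge pulpo-occlusally (default 6 degrees).  Internal line angles
are rounded with a polynomial smooth-min of radius 0.35 mm and cavosurface
margins with 0.15 mm — real burs cut rounded angles, and sharp implicit
creases would otherwise dominate the coarse-scan discretization error.
Defaults: isthmus width 2.2 mm, pulpal depth 2.0 mm, box extension 1.5 mm,
cusp reduction 1.5 mm (onlay).  Oversampling multiplies widths and depths
by +4% per variant (the magnitude of the incremental variations is a free
parameter of the study design; 4% spans a noticeable but clinically
plausible range over five variants).

**Scanner simulation.** A scan rendition resamples the solid at a pitch
derived from the profile's triangle budget, jitters vertices along their
normals, then applies Taubin (shrink-limited) smoothing.  The two default
profiles encode the devices' differing "magnification": intraoral 200k
triangles, 0.005 mm jitter; desktop 100k triangles, 0.008 mm jitter; both
2 smoothing iterations.  These defaults are the generator's calibration
contract: across the six base specimens, same-specimen pairs must satisfy
DSC >= 0.90 and |signed deviation| <= 0.10 mm, the envelope reported for
real scanner pairs.  Measured values sit near DSC 0.998 and 0.06 mm —
comfortably inside, without tuning to the boundary.  What passing these
checks shows is that the *pipeline* (metrics, CAD, learning) behaves
correctly on data with the study's statistical structure; it does not show
robustness to real-scanner artefacts such as coverage holes, registration
error, or reflective-coating noise, which the simulator deliberately omits
(meshes are born co-registered; an optional rigid pre-alignment flag is
out of scope for the same reason).

**Study design.** Six base specimens (alternating 3 inlay / 3 onlay — the
original split across six teeth is not recorded, so a balanced split is
the natural default), five variants each (30 preparations), crossed with
2 workflows x 2 operators into 120 design rows; all counts are exact
invariants of the default configuration.

## CAD synthesis

Two design principles are implemented.  *Boolean subtraction* computes
prosthesis = template AND NOT preparation on the shared grid (the crown
template for onlays is the intact synthetic crown), keeps the largest
connected component, re-extracts and smooths.  *Surface reconstruction*
(used for workflow-1 inlays) caps the cavity with the intact reference's
occlusal surface — or, when no reference exists, bridges the opening by
morphological closing (Euclidean-distance-transform dilation/erosion with
a 1.8 mm ball, enough to span the isthmus) — and subtracts the
preparation; a final closing of 0.25 mm emulates the wrap/autofix cleanup
steps of interactive CAD.  The manual sculpting steps of the original
workflows are emulated by Taubin smoothing of configurable strength.

Operator variability is simulated as personas: a sub-voxel margin offset
(± a quarter pitch on the preparation field) and differing smoothing
strength.  This reproduces an inter-operator variance component for the
factorial analysis without human operators; it is a stand-in for human
behaviour, not a model of it.

Fit is quantified on the shared grid: penetration volume (prosthesis
intersecting remaining tooth), restored Dice (prosthesis plus preparation
against the intact reference), and the maximum margin gap, defined as the
largest distance from any cavity-wall point of the preparation (surface
points lying inside the intact reference by more than two pitches) to the
prosthesis surface — zero for an exact Boolean design, and equal to the
displacement for a translated prosthesis.

## Similarity metrics

Surface comparison is point-to-surface: points are sampled area-uniformly
on the source mesh (plus its vertices, which bound the supremum from
below) and measured by exact point-to-triangle distance against the target
through a uniform spatial grid.  This makes the Hausdorff estimate
independent of tessellation density, which differs between scanner
profiles by design.  Sampling is *nested*: the random stream is consumed
point by point, so enlarging the sample only adds points and the directed
Hausdorff estimate is monotone non-decreasing in the sample count.  The
default 50,000 samples per direction keep the sampling error below
~0.01 mm on crown-sized surfaces.  The signed deviation range reports
nearest-distance negated inside the reference solid; its negative minimum
is the quantity that appears as a negative "Hausdorff" bound in scan
comparisons, and both it and the true (nonnegative) Hausdorff distance
are emitted side by side.  Dice is computed on voxel occupancy in one
shared frame (union bounds padded by two voxels) at 0.1 mm pitch.

## The classifier

The 17-layer network comprises a 13-layer feature-extraction block — the
input layer plus four stages of [3x3x3 convolution -> stride-2 max pool ->
ReLU with batch normalization] — and a 4-layer classification block:
flatten, dense(512), dropout(0.60), dense-softmax(2).  The filter schedule
is [64, 128, 256, 256]: the written description of the first stages
("64-128 and 256 filters") does not pin down the fourth stage, so it
repeats 256; the schedule is configurable.  The per-stage order
(pool before activation/normalization) follows the workflow description
as stated even though conv-BN-ReLU-pool is the more common idiom; with
ReLU and max-pool commuting, the practical difference is where BN
statistics are computed.  Positive class for sensitivity/precision is
*inlay* (the description does not name one; the worked confusion example
fixes the convention).  Precision with no positive predictions is
reported as undefined (NA with a flag), never silently zero.

All layers are implemented in the package (im2col + GEMM convolutions in
C++ through BLAS, double precision, single-threaded): training is
bit-reproducible per seed.  The optimizer is Adam at 1e-4 with batch size
4 — none of these are recorded in the workflow description; they were
chosen for stability at n = 20 training samples.  Early stopping halts
when the best validation accuracy has not improved for 15 consecutive
epochs (max 100).

**Transfer learning.** The feature block is pretrained on a synthetic
proxy task — classifying random blob volumes that do or do not contain an
ellipsoidal internal void — standing in for an external volumetric corpus
so the package builds and validates offline; an external corpus can be
substituted by passing its volumes to `pretrain_proxy()`.  Pretraining
runs at 16^3 with 192 volumes: convolution and normalization parameters
are resolution-independent, so they transfer unchanged to the 32^3 dental
volumes, at an eighth of the compute.  After transfer the block is frozen;
frozen-feature activations are then precomputed once (inference-mode
batch norm), which is exact and makes head training on 20 samples take
seconds.  The trainable-parameter count is exposed and tested against
closed-form arithmetic; for the default 32^3 configuration the
classification block holds 1,050,114 parameters.  The inlay/onlay task on
synthetic preparations is nearly linearly separable in cavity geometry,
so validation accuracy typically saturates near 1.0 — the printed floors
(accuracy >= 0.60, cross-entropy <= 0.8748) are treated as lower/upper
bounds, not as targets to reproduce exactly, since the original values
arose from scan data that was never deposited.

## Statistics

Phase 1 uses the pooled-variance two-sample t-test (df = n1 + n2 - 2; two
groups of six give the integer df 10 that a Welch test would not).
Phase 2 uses the fixed-effects 2x2x2 ANOVA with all interactions; in the
balanced default every effect has numerator df 1 and Type I/II/III
coincide, and the sums of squares are tested against a direct group-mean
oracle plus the exact decomposition identity.  With unbalanced data (as
after removing corrupted specimens) the implementation falls back to
Type-II sums of squares with a warning.  Cell summaries are formatted
"mean ± sd" in the factorial layout.  Sample-size planning inverts
noncentral-F power, `P(F'(df1, N-k, f^2 N) > F_crit)`, over N; the default
configuration is the omnibus 8-group test with df1 = 7, which yields a
minimum of 108 specimens at f = 0.40, alpha = 0.05, power = 0.85 — the
configuration is exposed because the planning tool's test family is
otherwise underdetermined.  One boundary case is worth noting: for
extreme effect sizes the minimum is groups + 2, not groups + 1, because a
single error degree of freedom inflates the critical value beyond any
attainable power at conventional alpha.

## Problem sizes and determinism

Default problem sizes are chosen for desk-scale runs: phase 1 compares
six scan pairs at 0.1 mm pitch with 50,000 samples per direction (under a
minute); phase 2 designs 120 prostheses at 0.2 mm CAD pitch (a few
minutes); phase 3 pretrains at 16^3 and trains at 32^3 (about two
minutes).  Every stochastic step draws from a named stream derived from
one top-level seed, so phases can be rerun independently and full runs
are reproducible bit-for-bit in single-threaded execution.

## Known limitations

Synthetic anatomy is smooth and co-registered; no registration, hole
filling, or scan-artefact repair is implemented or tested.  Voxel CSG
cannot represent features below the grid pitch (sub-0.1 mm margin
details).  The morphological-closing fallback for surface reconstruction
caps any opening narrower than twice the closing radius, which over-fills
cavities with strongly divergent walls.  The classifier is validated on
10 volumes; its saturated accuracy reflects the separability of the
synthetic classes, and no claim is made about real preparation scans.
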