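---
title: "Single-cell microglia morphometry: models, parameters and validation"
author: "MicrogliaMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell microglia morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

Microglia shift between morphological reactivity states — from the compact
"ameboid" form with few short processes (associated with phagocytic and
pro-inflammatory programs) through transitional shapes to the classically
ramified "surveillance" state and, under chronic stimulation, a bushy
hyper-ramified form. Those states separate quantitatively along a small set
of single-cell shape statistics computed from a traced skeleton of the cell:

* **total filament (process) length** (µm) — the sum of Euclidean edge
  lengths of the skeleton;
* **filament volume** (µm³) — conical frusta over the skeleton edges, with
  per-node radii fitted from image intensity, plus the soma body volume;
* **Sholl intersections** — for concentric shells of radius $k\,\delta$
  ($\delta$ = 1 µm by default) centered on the soma, the number of times the
  skeleton crosses each shell, and their sum;
* **convex hull volume and area** (µm³, µm²) — the smallest convex solid
  containing the cell, a measure of territorial extent;
* **sphericity** $\Psi = \pi^{1/3}(6V)^{2/3}/A$ — the surface area of the
  equal-volume sphere over the hull's surface area; 1 for a sphere, lower
  for elongated or spread-out shapes.

The pipeline reconstructs cells from two-channel 3D confocal stacks (a
membrane/cytoskeletal marker such as Iba1, and a nuclear stain such as
DAPI), applies the study's quality-control rules, and runs nonparametric
group statistics. A parametric scene generator with exact ground truth
validates every stage.

# The reconstruction chain

## Channel preparation

Tracing operates on min–max normalized intensities. A **colocalization
channel** — the voxelwise geometric mean of the normalized nuclear and
membrane channels — marks soma bodies: the nuclear stain fills the dim
center that membrane markers leave hollow, so only soma voxels are high in
both. (The geometric mean is this package's operator choice; it is zero
wherever either input is zero and 1 where both reach their maxima, which is
exactly the behavior the soma-detection step needs.) Optional **background
subtraction** is a per-slice morphological opening with a physical disc
radius — per-slice because the coarse axial pitch of optical sectioning
(0.8 µm here) makes a 3D structuring element ill-posed.

## Debris removal

Bright antibody deposits are detected as 26-connected components above a
creation threshold and scored by volume, mean intensity, isosurface-mesh
sphericity and moment ellipticities; selection criteria stack
conjunctively (small AND bright AND round). Saturating deposits are best
isolated at a high creation threshold (0.9 of the normalized range by
default) where even soma interiors drop out; the selected surfaces are then
dilated over their point-spread halo before masking, because a masked core
with a surviving bright annulus would seed false filaments. Masking holes
punched into genuine processes are bridged downstream by the gap rule (see
below), which is why the default maximum gap (4 µm) exceeds the worst
masking hole (~3 µm).

Surface area comes from a marching-tetrahedra isosurface on the intensity
field, which respects anisotropic voxels and the resolved (PSF) edge;
voxel-face counting would overestimate area by tens of percent and wreck
the sphericity criterion. For components only a voxel or two across, the
mesh area and the voxel-count volume become mutually inconsistent and
sphericity is unreliable (it can exceed 1); selection should therefore
always stack an intensity or volume criterion, as the defaults do.

## Soma and seed detection

Starting points (somas) are local maxima of the scale-normalized
Laplacian-of-Gaussian response at $\sigma = d_{\text{start}}/(2\sqrt{3})$
on the colocalization channel, greedily suppressed to one starting diameter
apart and refined to sub-voxel accuracy by an iterated intensity-weighted
centroid — the refinement matters because slices are 0.8 µm apart and both
the seed-exclusion and soma-collapse radii assume an accurate center. The
**starting diameter should be measured as the visible soma diameter**
(body plus PSF halo, here 2·(radius + 1 µm)): with a bare geometric
diameter, noise scatters rim seed points just beyond the exclusion radius
and hair-like arcs crawl the soma surface.

A starting point survives nucleus QC only if a supra-threshold nuclear
component overlaps its starting sphere and touches neither the first nor
last z slice.

Seed points use the same detector at the process scale with a
ridge-tolerant maximum rule (a voxel qualifies when within 5% of its
strongest 26-neighbor), so seeds follow the nearly flat response along tube
axes; they are snapped onto the axis by centroid refinement, deduplicated,
and removed within `removeSeedRadiusFactor` starting radii of any soma.

## Tracing

Autopathing is realized as intensity-weighted geodesics on the
26-connected voxel grid: edge weight = physical step length ×
$(0.01 + 1 - \hat I)^\gamma$ with $\gamma = 2$. Voxels below the intensity
floor stay traversable at a large constant penalty, so paths can bridge
faint gaps; the floor defaults to 0.12 of the normalized range, roughly
4 standard deviations above the simulated background, so that shot noise
rarely pokes above it. Each seed is assigned to the starting point of
minimal geodesic cost (not Euclidean distance — this is what prevents
cross-cell capture between adjacent cells).

The union of seed-to-soma geodesics is built farthest-seed-first with
redundant-path suppression: a later path attaches to the tree as soon as
it reaches an existing node or comes within an anisotropic merge radius
(seed radius laterally, one slice axially) of one. In flat-intensity tube
cores, geodesics from nearby seeds otherwise run in parallel voxel lanes
that never meet and double-count length. The soma interior is collapsed
into a single soma node with straight edges to each entry point (and any
path that dips back *into* the soma sphere after leaving it is discarded
as a shell-crawling artifact). Chains are smoothed by a short
moving-average window — which removes the voxel staircase that inflates
path length by several percent on anisotropic grids without cutting real
branch curvature — resampled to ≤ 0.5 µm node spacing, terminal spurs
below 1.5 µm are pruned, and tips are extended to the half-maximum edge of
the tube end (never into the soma).

`removeDisconnectedSegments()` then walks the tree from the soma,
accumulating contiguous sub-floor run length; a run only resets after
≥ 1 µm of contiguous supra-floor path (a single noise speck must not break
a gap in two), and when a run exceeds the maximum gap — or is still open
at a leaf, i.e. the bridge lands on nothing real — the whole run and
everything distal is deleted.

Node radii are fitted as the mean over eight rays, cast normal to the
local tangent, of the distance where interpolated intensity first falls
below half the on-axis value; rays that never fall below half-maximum run
along a neighboring structure and are excluded; results clamp to
[0.1 µm, starting radius]. Soma volumes are imported from the supra-
threshold colocalization component containing each soma node, with a
sphere fallback (flagged) when none exists.

# Morphometry choices

* **Sholl mode.** Spherical (3D) shells are the default — they match
  volumetric data and the exported "Sholl sphere" statistic; a
  `projected2d` mode (dropping z first) reproduces the classical
  flattened-circle description exactly and equals the 3D mode for planar
  cells.
* **Crossing rule.** Shell crossings are sign changes of
  $(d \ge r)$ along each soma-outward edge, resampled at ≤ 0.1 µm with the
  analytic closest-approach point inserted, so a tangential dip cannot
  slip between samples and a tip exactly on a shell counts once. The
  generator's independent oracle uses brute-force 0.01 µm sampling; the
  two agree exactly, shell by shell, on random trees.
* **Hull point set.** The hull is taken over all skeleton nodes *plus a
  64-point sample of the soma sphere*. The soma body is part of the cell;
  a bare point-skeleton hull reduces a compact ameboid cell to a
  near-simplex over a few tips and inverts the sphericity contrast between
  compact and ramified states that the statistic exists to capture. A
  `tips_only` mode (leaves + soma) and `includeSoma = FALSE` preserve the
  literal constructions.
* **Degeneracy.** A cell whose skeleton points are collinear/coplanar (in
  particular a lone soma) is flagged `degenerate_hull` and always fails
  QC, mirroring how zero-extent cells indicate reconstruction errors.
* **Filament volume** includes the imported soma volume: the statistic
  describes the whole cell, not the processes alone.

# Quality control and statistics

Only cells with a nucleus fully inside the stack enter the analysis. Cells
below the 10th percentile on *any* of length, Sholl sum, sphericity or
hull volume are excluded (union rule, strict inequality), guarding against
cells clipped at the stack border. Percentiles use linear interpolation of
order statistics (`quantile` type 7), computed over a cohort scope pooled
across treatment groups so groups share one cutoff and no group is
differentially censored; metric list, percentile and scope are all
configurable.

Two groups are compared with the Mann–Whitney U test (exact enumeration up
to a combined n of 12 without ties, otherwise the tie- and
continuity-corrected normal approximation); more groups with the
tie-corrected Kruskal–Wallis H and a Dunn post hoc whose Bonferroni
multiplier is the number of *planned* comparisons, not all pairs. Sholl
distributions are compared by expanding each cell's profile into a
multiset of radii (radius repeated by its intersection count), pooling
within groups, and applying the two-sample Kolmogorov–Smirnov test; this
pooled-radii reduction is one defensible operationalization of a
distribution test on Sholl curves, chosen for its simplicity and
scale-freeness. Data are summarized per animal (means and cell counts) as
well as per cell.

# The synthetic scene generator

Cells are sampled as rooted trees: primary processes leave the soma
surface in random directions (z-damped by 0.3 so arbors stay inside thin
optical sections, as cells in 50 µm slices do; directions keep ≥ 0.5 rad
separation because two primaries inside one tube radius would rasterize
as a single fused trunk, making the stored skeleton inconsistent with its
own image), grow in ~1 µm steps with angular jitter, and bifurcate with a
per-junction probability up to a maximum order, with radii tapering per
order. The four presets span the reactivity spectrum; their numeric values
are this package's calibration — only the ordinal relations (length and
Sholl sum increasing from ameboid to hyper-ramified; ameboid hull volume
smallest; ameboid sphericity highest) are contractual, and they hold with
wide margins over sampled cells.

Scenes are rasterized by exact point-to-segment distance in physical µm
(capsules along edges, soma and nucleus spheres, max over primitives, a
one-voxel partial-volume edge), blurred with a per-axis Gaussian PSF
(σ = 0.5, 0.15, 0.15 µm in z, y, x), degraded with Poisson shot noise
(200 photons at full scale) and Gaussian read noise (1% of full scale),
and quantized to 16 bits with background at 2% of full scale. Debris are
small spheres (0.5 µm) whose pre-blur intensity exceeds full scale, so
they saturate the detector as real antibody deposits do — sub-resolution,
sub-saturating smears would be unmaskable by any intensity criterion and
would not emulate the nuisance the debris module exists to remove. The
default acquisition geometry mirrors the targeted protocol (101.54 µm
field at 1440 px, 0.8 µm slicing, 16 bit); validation studies use coarser
lateral sampling (0.25–0.3 µm) and smaller fields so a study fits in
minutes of compute, a resolution at which every stage is still
well-sampled.

One seeded generator drives each scene with a documented stream order
(placement, per-cell trees, debris, noise), so identical specifications
give byte-identical stacks.

**What the generator does not emulate:** depth-dependent attenuation,
spherical aberration, channel bleed-through, tissue context (other cell
types, vessels), inhomogeneous background, and real antibody penetration
gradients. Passing the validation studies therefore demonstrates that the
algorithms are correct and unbiased under controlled conditions, not that
they are robust to every artifact of real tissue; on real data the
detection thresholds, floor and gap length are expected to need tuning,
which is why they are all exposed.

# Validation results the package checks for itself

The test suite and `scripts/acceptance.R` recompute, among others:

* exact shell-by-shell agreement between the production Sholl profile and
  the 0.01 µm brute-force oracle on 200 random trees;
* convex hull volume/area agreement with brute-force facet enumeration to
  1e-9, plus exact unit-cube and regular-tetrahedron values;
* sphericity 1 for the analytic sphere, the closed-form cube value, and
  ≥ 0.97 for a 2 µm sphere rasterized at 0.1 µm voxels;
* tracing recovery on 50 noise-free single-cell scenes (length within 5%
  and leaf count within ±1 for ≥ 90%) and on 25 noisy scenes with a
  30-deposit debris field and masking (length within 10% for ≥ 80%);
* the textbook small-sample values of the rank statistics (H = 7.2 on
  {1,2,3},{4,5,6},{7,8,9}; U = 0 with exact p = 0.1; Dunn z = 0 with
  adjusted p = 1 on identical groups; KS D ∈ {0, 1} on identical/disjoint
  supports);
* the 20-cell QC fixture retaining exactly 18 cells at q = 0.10;
* a seeded two-state study (ameboid vs surveillance, 3 animals per group,
  16 cells per animal) in which the pipeline reports lower length, lower
  Sholl sum, lower hull volume and higher sphericity in the ameboid group,
  each at p < 0.05.

# Known limitations

* Touching structures defeat intensity-guided tracing: where two branches
  (or two cells' processes) run within about one tube diameter, the
  geodesics can merge or hop between them. The seed-to-soma assignment by
  geodesic cost prevents most cross-cell capture, but fused skeletons in
  dense neuropil must be caught by the QC outlier rules.
* Deposits lying directly on a cell are only removable when they saturate
  relative to the cell (the high-threshold isolation); deposits at
  process-level intensity on a process are indistinguishable from the
  process.
* Sphericity of sub-voxel surface objects is numerically unreliable (mesh
  vs voxel volume inconsistency); stack an intensity or volume criterion.
* The Kolmogorov–Smirnov reduction treats every intersection as an
  independent draw, which overstates the effective sample size; its p
  values should be read qualitatively.
* Diameter fitting reports the PSF-broadened half-maximum radius; for
  processes thinner than about twice the lateral PSF sigma it
  overestimates the true radius.
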