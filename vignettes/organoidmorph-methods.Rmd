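---
title: "Models and methods behind organoidmorph"
author: "organoidmorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind organoidmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidmorph)
```

organoidmorph quantifies two aspects of liver organoid and assembloid imaging
data: how the outline of a structure changes shape over time (a topological
shape descriptor with a distance-ratio score), and how the bile-canaliculi
(BC) network inside a structure is organized (a 3D two-channel segmentation
and skeleton-graph feature pipeline). This vignette explains the models, the
tunable parameters, the numerical choices, and what the synthetic-data tests
do and do not establish about real data.

## 1. The shape descriptor

### The Euler characteristic transform

A closed outline of an organoid (traced clockwise in image coordinates and
stored in micrometres) bounds a planar region $P$. For a unit direction
$v(\theta) = (\cos\theta, \sin\theta)$ and a height $t$, the sublevel set
$P_{\theta,t} = \{x \in P : \langle x, v\rangle \le t\}$ is the part of the
shape "below" height $t$ in that direction. Its Euler characteristic
$\chi(P_{\theta,t})$ — components minus holes — traced over $t$ gives the
Euler characteristic curve of direction $\theta$; the family over all
directions is the Euler characteristic transform (ECT), a complete signature
of the shape that mixes geometry (where mass sits along each direction) with
topology (how pieces merge).

The smooth variant (SECT) centres each curve by its mean over the threshold
window and integrates it cumulatively, producing, per direction, a continuous
function that starts and ends at zero. The package stores this as a
$D \times T$ matrix (default $D = 72$ directions, $T = 128$ thresholds) with
an $L^2$ norm under the product measure $\Delta\theta\,\Delta t$.

Two discretizations are implemented:

* **vertex** (default): the polygon is triangulated (ear clipping) and cells
  enter the filtration at the height of their highest vertex. Because the
  sublevel complex of this filtration is homotopy-equivalent to the true
  sublevel set, $\chi(t)$ is exact and independent of the triangulation.
  The centred cumulative integral is then evaluated in closed form from the
  sorted cell heights,
  $s(t) = \sum_c \sigma_c \max(0, t - h_c) - (t + R)\,\bar\chi$, rather than
  by quadrature of a threshold-sampled curve. This matters: sampling the
  integer-valued curve on the threshold grid quantizes the descriptor at the
  grid pitch (about 1 µm at the defaults), which makes it blind to
  sub-pitch boundary changes and non-smooth under rotation. The closed form
  is exact, so the descriptor responds continuously to arbitrarily small
  boundary perturbations.
* **raster**: the outline is rasterized (pixel-centre, even–odd rule) and the
  cubical complex of the mask is filtered the same way, with the sampled
  curves integrated by the trapezoid rule. This route exists for mask inputs
  and as an independent cross-check; its accuracy is resolution-limited
  (norms move by under 3 % when $N$ doubles from the default 256).

The window half-width $R$ is fixed at 1.25 times the maximal
centroid-to-vertex distance — **per series, not per frame**. Shapes are
centred on their area centroid (hence translation invariance), but they are
deliberately *not* scale-normalized: compaction is a size change, and
normalizing sizes away would erase the signal the score exists to measure.
One consequence worth knowing: because each curve is mean-centred over the
fixed window, a shape that fills less of its window produces a *larger*
centred signal, so descriptor norms grow as a structure compacts. The
temporal score below is a ratio of distances and is unaffected by this
convention.

### Rotation-aligned distance

The distance between two descriptors on a common grid is the $L^2$ matrix
distance. With alignment enabled it is minimized over rotations of the
direction axis: the $D$ integer cyclic shifts — so rotating a shape by any
multiple of $2\pi/D$ is absorbed *exactly* (the vertex heights permute) —
refined by continuous fractional shifts evaluated through trigonometric
interpolation of the direction-axis cross-spectrum. Fractional shifts act
unitarily on the descriptor, so the aligned distance is an orbit metric:
symmetric, triangle inequality intact. Residual error for off-grid rotations
comes only from sampling the direction axis at $D = 72$ and measures below
1 % of the descriptor norm for the shape classes used here.

### The temporal score

For an outline series (default acquisition design: 2 h after seeding, then
every 24 h), `build_timecourse()` computes one descriptor per frame on the
shared window, estimates the orientation once on the first frame (rotation to
a canonical pose) and freezes that shift for the whole series — an organoid's
orientation in its well is common to all frames, and re-aligning every frame
would absorb genuine shape change into the alignment. `distance_ratio()`
then reports

$$ \mathrm{ratio} = d_1 / d_0, $$

where $d_0$ is the first frame's descriptor magnitude (its distance to the
empty shape) and $d_1$ the distance between final and first frame. A static
series gives a ratio near zero; progressive compaction gives ratios of order
one. Two variants (`cumulative`, summing consecutive inter-frame distances,
and `consecutive`, their maximum) are available behind an argument; the
default first-versus-last form is the most direct reading of a
"how far did it travel" score and is stable for static series.

Morphology classes (smooth "ball" versus lobed "bubbly/grape") are separated
by average-linkage hierarchical clustering on the aligned pairwise distance
matrix, cut at $k = 2$. The metric is size-sensitive by design, so class
clustering presumes cohorts of comparable size; with large size scatter the
first split can be by size, not class. That is a property of the unnormalized
metric, not a bug, and it is why the class-separation tests generate both
classes at a common base radius.

## 2. The bile-canaliculi pipeline

The 3D pipeline mirrors the published segmentation recipe for two-channel
stacks (apical marker such as CD13, plus cortical actin), at isotropic
0.3 µm voxels:

1. **median filter**, radius 1 voxel per channel (edge-reflected);
2. **threshold** each channel independently with the IsoData intermeans
   iteration on the integer histogram (the image software's default
   automatic method); the actin channel's method is configurable since
   protocols vary;
3. **overlap** — the voxelwise AND of the two masks marks apical patches;
4. **lumen completion** — `inflate` 6-connected dilations (default 3), fill
   of cavities not 6-reachable from the volume border, `deflate` erosions
   (default 3): hollow membrane shells become solid lumina;
5. **object filter** — 26-connected components below 500 voxels
   (≈13.5 µm³) removed, then components touching the volume border removed
   (all six faces by default; an xy-only policy exists for thin stacks), with
   a removal report;
6. **local thickness** — per voxel, the diameter of the largest inscribed
   sphere containing it (Hildebrand–Rüegsegger), computed by painting the
   maximal distance-transform balls over an exact Euclidean distance
   transform;
7. **skeletonization** — homotopy-preserving thinning: simple points
   (Bertrand–Malandain characterization) that are not curve endpoints are
   deleted in six directional subiterations per pass, ordered by increasing
   distance from the background. Directional candidacy (a voxel is a
   candidate only while its face-neighbour in the subiteration's direction
   is background at collection time) bounds the retraction of free tube ends
   to about one voxel layer per pass; free ends therefore lose roughly one
   tube radius of length, the usual behaviour of curve thinning;
8. **network features** — skeleton voxels are classified by 26-neighbour
   count (endpoint 1, slab 2, junction candidate ≥ 3); adjacent candidates
   merge into junction nodes, branches are traced between nodes, and branch
   length sums the Euclidean inter-voxel steps ($1, \sqrt2, \sqrt3$ × voxel
   size). A *network* is one connected component; per structure, the network
   with the largest total length (ties: more junctions) is summarized by
   total length, triple/quadruple/total junction counts, and per-branch mean
   diameters read off the local-thickness map. Diameters are distributed in
   half-open 0.25 µm bins as percentages of branch count.

Two discreteness corrections are applied before feature counting, both
reflecting that one anatomical junction occupies a finite voxel
neighbourhood:

* junction nodes connected by a branch shorter than `merge_junction_um`
  (default 1 µm) merge into one node — this is what makes a 4-way crossing
  one quadruple junction rather than two adjacent triples;
* terminal spurs shorter than `prune_spurs_um` (default 3 µm, just above the
  canaliculus diameter scale of $2r + h \approx 2.6$ µm) are removed, and
  junctions thereby reduced to pass-throughs dissolve. Rounded tube ends
  occasionally thin into short forks; stubs below the tube diameter cannot
  be resolvable side branches. Both thresholds are configurable and logged.

## 3. SHG collagen quantification

Fibrillar collagen is quantified from a maximum projection of the SHG
channel, a band threshold with both ends inclusive (defaults 60 and 110, the
image software's min/max convention), optional restriction to a hand-drawn
assembloid ROI polygon (pixel-centre, even–odd rule), and the integrated
density of the selection: `RawIntDen` (sum of pixel values) and `IntDen`
(area × mean), which coincide when area is counted in pixels.

## 4. Statistics

Group comparisons use the two-tailed Mann–Whitney test reporting
$U = \min(U_x, U_y)$: exact (full rank distribution, two-tailed as twice the
smaller tail capped at 1) whenever there are no ties and both samples are
below 50 values — which covers the $n = 16$ per arm design used for ratio
comparisons — a seeded permutation of the observed values for tied small
samples ($n_1 + n_2 \le 20$), and the tie-corrected continuity-corrected
normal approximation otherwise; the method used is recorded in the result.
Diameter distributions are summarized with a Gaussian kernel density
(Scott's-rule bandwidth) evaluated as an explicit sum of Gaussians so the
curve matches the closed form to machine precision. Cell-type composition
per structure is reported in percentages.

## 5. What the synthetic data emulate — and what they do not

No image data accompany the study the pipelines target, so the package ships
seeded generators with known ground truth:

* **Outlines**: $r(\theta) = R\,(1 + a\cos k\theta + \varepsilon\,\eta(\theta))$
  with smooth unit-amplitude noise $\eta$ (random-phase Fourier series,
  harmonics 2–6). $a = 0$ is the ball class; $a = 0.35, k = 5$ the default
  grape. The default base radius is 50 µm, a typical organoid scale.
* **Time courses**: static mode re-draws only $\varepsilon$-noise per frame;
  compacting mode scales radius and lobe amplitude by $1 - s$ per frame
  (default $s = 0.15$), i.e. compaction = smaller and smoother. The default
  $\varepsilon = 0.001$ models the smooth, low-order component of manual
  outline tracing error — the only component the descriptor metric responds
  to; independent per-vertex jitter integrates out of the Euler curves. Under
  these conditions static ratios stay well below 0.02 while 15 %-per-frame
  compaction produces ratios near one, two orders of magnitude apart.
* **Tube phantoms**: a fixed 10-edge centreline graph (one quadruple
  junction, two triples, two pass-through bends, jittered node positions)
  voxelized as hollow membrane shells — apical intensity where the distance
  to the centreline falls within $[r - h/2,\, r + h/2]$, minus any tube
  lumen so lumina stay connected at junctions — plus planar cell-border
  sheets in the cortical channel, additive Gaussian noise with
  $\sigma = (\mathrm{fg} - \mathrm{bg})/\mathrm{SNR}$, and intensities
  rounded to non-negative integers. Membrane thickness defaults to 0.6 µm
  (two voxels) so the inflate/fill/deflate logic is genuinely exercised.
  Because the pipeline measures the completed object (lumen plus membrane),
  the ground-truth branch diameter is $2r + h$. At SNR 5 the pipeline
  recovers junction counts exactly and total length within a few per cent
  (free-end retraction and staircase jaggedness largely cancel).

These generators exercise every stage with controllable truth, but they do
not model optical blur (no PSF), depth-dependent attenuation,
photobleaching, drift, anisotropic sampling, touching parallel tubes, or
segmentation-confounding autofluorescence. Passing the phantom tests
therefore shows the *algorithmics* are correct at realistic noise levels,
not that segmentation parameters transfer to any particular microscope
setup; the thresholding method, completion depth and size cutoffs remain the
user's responsibility on real data.

## 6. Numerical choices and degenerate inputs

* Outlines are normalized to clockwise orientation (positive shoelace area
  under the image convention, y down); counter-clockwise files load with a
  warning, duplicate closing vertices are dropped, and fewer than three
  distinct vertices or zero signed area is an error. Self-intersecting
  polygons are rejected before any geometry is computed.
* Problem sizes in the tests and in the acceptance measurements were chosen
  as the smallest that still exercise every code path meaningfully:
  32 × 32 masks for the Euler-characteristic oracle, $D = 36, T = 64$
  descriptors for cohort-level checks ($D = 72, T = 128$ defaults where the
  rotation tolerance itself is under test), a ~100³-voxel phantom for the 3D
  pipeline.
* Cell-height ties in the filtration are harmless by construction: curves
  are only ever evaluated at thresholds, where all cells at or below the
  threshold are counted regardless of within-threshold order.
* The IsoData iteration stops when the threshold moves by less than half an
  integer level; constant volumes raise a degenerate-histogram error, and
  the full pipeline converts that into a stage-named abort, as it does for
  any stage that empties the mask.
* `kde_curve()` refuses constant data rather than guessing a bandwidth.
* Empty selections in the SHG integrated density return zeros with a
  warning rather than an error, matching how batch quantification treats
  background-only images.

## 7. Known limitations

* The shape metric is size-sensitive by construction; cohorts mixing very
  different sizes will cluster by size first.
* The skeleton-length estimate carries the two usual discretization biases
  (free-end retraction of about one tube radius; diagonal staircase
  inflation of a few per cent). They partially cancel but are not modelled
  out.
* Junctions closer than about one tube diameter are reported as one node —
  intended behaviour for canaliculi, wrong if applied to networks with
  genuinely denser junction spacing.
* The permutation fallback of the Mann–Whitney test is seeded and
  reproducible but is only used for tied samples with $n_1 + n_2 \le 20$;
  larger tied designs get the corrected normal approximation.
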