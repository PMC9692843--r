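---
title: "Clustering seed-coat surface patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering seed-coat surface patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

The seed coat (testa) carries a sculptured surface whose features are
taxonomically informative: the *anticlinal* walls — boundaries between
neighbouring testa cells — undulate in characteristic ways (straight, S-,
U-shaped, U-to-Ω, strongly re-entrant Ω, and two irregular forms), while the
*periclinal* (outward-facing) walls carry granules or wart-like verrucae of
varying size and placement. `testaclust` implements a complete unsupervised
analysis of such surface patterns:

1. **generate** labeled synthetic testa patches (or ingest external PNGs),
2. **preprocess** each patch into three representations — grayscale, binary
   threshold, and colored connected components,
3. **select** the number of clusters per representation by the elbow (SSE)
   and silhouette criteria over k = 2..10,
4. **cluster** with five methods (k-means, k-means++, minibatch k-means,
   spectral, Birch), producing method runs M1..M5 and six proposed runs
   EG, SG, ET, ST, EC, SC (criterion x representation),
5. **compare** runs pairwise: overlap contingency tables, relation
   categories (identical / related / none), threads across three or more
   runs, and a six-level per-image agreement grouping
   (SI, SS, SM, NS, PS, PD).

The consensus stage is the scientific core: instead of trusting any single
clustering, it asks how consistently each image is grouped across all six
criterion-representation combinations, and grades that consistency.

## The synthetic generator

Real testa SEM corpora are assembled from heterogeneous literature figures
and are rarely redistributable, so the package ships a generator that
emulates the two annotation axes with known ground truth.

**Cell mesh.** Each 250 x 250 patch is tessellated by a Poisson-disk-seeded
Voronoi diagram (`cell_count` seeds; dart throwing with a minimum separation
of 0.75 x the mean spacing; border cells closed by mirroring seeds across
the frame). The Delaunay triangulation behind the Voronoi edges is computed
by direct circumcircle testing, which is exact and fast at these point
counts.

**Anticlinal walls.** Each Voronoi edge becomes a polyline displaced
sinusoidally: normal displacement `A sin(2 pi f t + phase)` windowed by
`sin(pi t)` so endpoints stay fixed, plus a tangential component scaled by
`lobe_reentrance` that folds the wave into re-entrant lobes as it
approaches 1. The per-class defaults form a ladder —

| class | amplitude (px) | freq (cycles/edge) | re-entrance |
|---|---|---|---|
| straight | 0 | 0 | 0 |
| irregular_to_straight | 3 | 1 | 0 (jittered) |
| S | 6 | 1 | 0 |
| irregular_curved | 6 | 1.5 | 0 (jittered) |
| U | 10 | 2 | 0 |
| U_to_omega | 12 | 2 | 0.6 |
| omega | 14 | 2 | 0.9 |

— chosen so that mean wall tortuosity (arc length / chord length, computed
on the generator's own vector boundaries) increases strictly along
straight < S < U < U_to_omega < omega; the test suite asserts this over ten
seeds. Amplitudes are capped at 0.35 x edge length and validated against
half the cell spacing so neighbouring walls cannot cross.

**Periclinal sculpture.** Bright Gaussian bumps (`verruca_count`,
`verruca_radius`, placement uniform / marginal-to-walls / dense) are placed
with a minimum separation so the rendered bump count matches the requested
count; the pre-noise bump layer is kept as an attribute so tests can count
rendered blobs independently.

**SEM look.** Cell interiors get a per-cell albedo in [0.74, 0.78], walls
are drawn dark (0.08, ~3 px wide), then the patch is Gaussian-blurred
(sigma 1 px) and perturbed with additive Gaussian noise (sd 0.03), clipped
to [0, 1]. This is deliberately minimal: it stresses thresholding and adds
realistic blur, but does **not** model SEM charging artifacts, directional
illumination, 3-D relief shading, magnification variation, or the
within-class biological continuum of real seeds. Passing the planted-truth
tests therefore demonstrates that the pipeline machinery is correct and
coherent, not that it would recover taxonomic classes from an arbitrary
literature corpus.

Generation is bit-deterministic given `(wall_class, params, seed)`; dataset
seeds are derived per image from one master seed.

## Preprocessing and feature spaces

The threshold rule is `pixel >= threshold -> foreground` with a global
default of 0.6 (the comparison is at-or-above; a local-mean adaptive switch
exists but is off by default). Connected components are labeled under
selectable 4- or 8-connectivity (8 is the default) via the pixel-adjacency
graph; per-component area, bounding box, centroid, perimeter (exposed
4-neighbour edges) and moment-based eccentricity are tabulated.

Clustering needs fixed-length vectors:

* **grayscale / threshold** — the raster is *block-mean pooled* to
  `downsample_side^2` values and flattened. Area averaging (not
  interpolation) is essential: testa classes differ in wall and sculpture
  *density*, which block means capture, whereas point-sampling preserves
  the random placement of individual walls — noise that swamps the class
  signal. The config default is 64; the planted-truth studies in this
  package use 4 (62-px blocks), the coarsest grid that still retains some
  spatial layout, because blocks smaller than a cell mostly encode where
  walls happen to fall.
* **colored** — the component labels get arbitrary colors, so the colored
  representation is summarized by a 10-element region-statistics vector:
  log(1 + component count); mean/sd area and mean/sd perimeter as fractions
  of the image; mean/sd eccentricity; foreground fraction;
  largest-component fraction; components per pixel. Units are
  dimensionless so no single raw scale dominates the Euclidean geometry;
  the count is log-scaled because component counts span two orders of
  magnitude across classes while their within-class spread grows with the
  mean.

Augmentation draws a rotation uniform in +/-5 degrees and shifts up to 1%
of the side (2.5 px at 250), applied as one bilinear affine warp; augmented
copies only ever enlarge training sets — the consensus analysis always runs
on original images, because agreement is defined per original image.
The shuffle/split stage is recorded in the report for completeness.

## Cluster-count selection

For each representation the SSE curve over k = 2..10 is computed with
best-of-10 k-means++ restarts per k, each k additionally warm-started from
the previous k's solution with its widest cluster split — this makes the
best SSE provably non-increasing in k, which plain restarts cannot
guarantee. The elbow is the interior k maximizing perpendicular distance to
the chord joining the curve's endpoints (deterministic; ties toward smaller
k). The silhouette choice is the argmax of the per-k mean silhouette
(Euclidean; singleton clusters contribute 0; ties toward smaller k).

## Clustering engines

* **M1 k-means**: Lloyd iterations from random-point initialization
  (best of 10 restarts); empty clusters are re-seeded with the farthest
  point whose donor cluster keeps at least one member.
* **M2 k-means++**: same Lloyd core with the D^2 sampling initialization.
* **M3 minibatch k-means**: per-iteration random batches with streaming
  per-centroid mean updates at learning rate 1/count, best of several
  restarts by final assignment SSE.
* **M4 spectral**: RBF affinity (`gamma` defaulting to
  1 / (dimension x mean feature variance)), symmetric normalized
  Laplacian, row-normalized k leading eigenvectors, k-means in the
  embedding.
* **M5 Birch**: one-pass CF-tree (entries absorb a point only if their
  radius stays within the threshold, default 0.5 in standardized units;
  leaves split at the branching limit, default 50, by farthest-pair
  seeding), then agglomerative centroid-linkage merging of leaf entries to
  k clusters.

Features are z-scored before spectral and Birch (their affinity radius and
absorption radius are scale-sensitive); the k-means family sees the raw
features. Convergence is unchanged assignments or 300 iterations. The six
proposed runs EG..SC use the k-means++ engine at each representation's
selected k. Every stochastic stage derives its seed from the master seed by
stable stage-name hashing, so the battery is a pure function of its inputs.

## Consensus analysis

For every unordered pair of runs a contingency table counts shared images
per cluster pair — `C(6, 2) = 15` tables for the proposed battery. Each
cell at or above the report floor becomes a relation with Jaccard
similarity `overlap / (size_a + size_b - overlap)`, categorized
*identical* at >= 0.9 and *related* at >= 0.5. The literature-scale floor
of 500 images is the config default; analyses on the 60-image synthetic
corpus scale it proportionally (floor 5), since a fixed 500 would simply
silence every table. A cluster with several reported partners ranks them by
descending overlap (ties by partner index) — the separation number in the
run-cluster-separation naming scheme.

**Threads** chain relations across runs: maximal simple paths in the
relation graph whose nodes come from pairwise distinct runs and span at
least three runs. Because possible extensions of a path depend only on its
node set and endpoints, the search memoizes on that state, and each thread
is reported once (canonical endpoint ordering). On the planted corpus the
three class-aligned clusters of all six runs chain into exactly three
six-run threads.

**Agreement grouping.** For image i and run r, `mates_r(i)` is the set of
images sharing i's cluster in r, excluding i. The agreement level of i is
the size of the largest set of runs whose mates sets for i are pairwise
identical; since set equality is transitive this is the largest
multiplicity among the six mates sets. Levels map to groups 6 = SI
(strongly identical) through 1 = PD (possibly different). A brute-force
subset oracle verifies the level computation exhaustively in the tests.
Relabeling a growing fraction of images can only break agreement, so the
SI count is non-increasing in perturbation — also property-tested.

## Study conditions

The planted-truth validation uses three wall classes chosen to be clearly
separated on both axes the feature spaces measure — wall density
(foreground fraction) and fragment count:

| class | cell_count | fg fraction | components |
|---|---|---|---|
| straight + granule | 15 | ~0.92 | ~8 |
| U_to_omega + small verrucae | 30 | ~0.77 | ~29 |
| omega + verrucate verrucae | 50 | ~0.61 | ~120 |

with 20 images per class (n = 60), preprocessing at `downsample_side = 4`,
and overlap floor 5. Under these conditions all five methods recover the
planted partition (adjusted Rand index 1.0), both criteria select k = 3 on
all three representations, and the agreement grouping places all 60 images
in SI. Problem sizes throughout (60-image corpus for recovery, 18-image
corpus for the determinism check, 200-point blob sets for k-selection
recovery, n <= 8 instances for the exhaustive k-means oracle) were chosen
as the smallest sets that exercise every code path with comfortable
statistical margins.

## Numerical choices and degenerate inputs

* Distances are Euclidean throughout; no metric is configurable.
* Grayscale conversion uses ITU-R 601 luminance weights.
* Rasters are row-major with origin top-left; bounding boxes are half-open
  and 0-based; run labels are 0-based cluster indices displayed as C1..Ck.
* `detect_elbow` restricts candidates to interior grid points, so an
  exactly linear curve yields the smallest interior k.
* All-identical inputs: k-means re-seeds empty clusters point by point and
  reports SSE 0; the silhouette of an all-singleton labeling is 0 by
  convention.
* Binarize is validated to `{0, 1}` and is idempotent on binary input at
  threshold 0.5.
* The Birch global step reduces k to the number of CF entries when the
  tree is coarser than the requested k.

## Limitations

* The generator's realism is deliberately limited (see above); conclusions
  about real SEM corpora require real images through the same interface
  (`read_images` + `extract_patch`).
* The feature spaces are simple density summaries; texture descriptors
  (e.g. local binary patterns, wavelet energies) would likely separate
  subtler classes but are out of scope.
* Agreement uses exact mate-set equality; a softer set-similarity variant
  would interpolate between the six levels but is intentionally excluded.
* With six runs of ~3 clusters the thread search is exact; for much larger
  batteries the memoized path enumeration would need a cap.

## Design decisions on open points

* The five-type periclinal vocabulary (granule, small/large/marginal/
  verrucate verrucae) is used as the canonical enum.
* The threshold comparison is at-or-above (the general definition), not
  strictly-above.
* The M1..M5 method runs default to the grayscale representation at its
  elbow-selected k; both the representation and criterion are exposed in
  `battery_config`, and the report labels every run explicitly.
* Agreement counts are counts of *images* (each image appears exactly once
  in the partition).
* The total number of comparison tables is interpreted as the sum over
  pairwise run comparisons, i.e. `combination_count(#runs, 2)`.
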