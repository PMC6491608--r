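---
title: "Segmenting poly-lobular subunits in cleared adipose fat pads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting poly-lobular subunits in cleared adipose fat pads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-mount clearing and confocal imaging of the murine inguinal
(subcutaneous) fat pad show that its core is organised into 15–21
*poly-lobular subunits*: 3D-connected clusters of adipocyte lobules
separated by thin, darker mesenchymal septa. In 2D sections these subunits
appear as many disconnected "lobules", so their true number, volume and
inter-connectivity can only be measured by a genuinely 3D segmentation. The
periphery of the pad shows no such organisation; a preliminary step must
therefore split the tissue into a *Segmentable Lobule Area* (SLA) and a
non-segmentable periphery before any subunit-level analysis.

`lobuseg` implements this workflow end to end: edge-preserving contrast
filtering, binarization and morphological cleanup, Euclidean-distance
seeding, priority-flood watershed, foreground masking, and
contact-surface-driven merging of over-segmented fragments, followed by
morphometric quantification and a subunit connectivity graph. A synthetic
phantom generator provides ground truth for every stage.

## The processing model

All stages operate on 3D arrays with an anisotropic physical voxel spacing
$(d_x, d_y, d_z)$ in micrometres (confocal stacks are coarser along $z$).
The stages, in order:

1. **Optional block-mean downscaling** (`downscale()`): each
   $f_x \times f_y \times f_z$ block is replaced by its mean. Averaging
   (rather than subsampling) preserves the intensity statistics of septa
   that are only a few voxels wide at reduced resolution.
2. **Kuwahara-type filtering** (`kuwahara_ratio_filter()`): around every
   voxel, eight octant boxes of per-axis half-extent $r$ (the 3D analogue
   of the four 2D Kuwahara quadrants, each box corner-anchored at the
   voxel) are evaluated. In `"ratio"` mode the output is
   $\frac{1}{8}\sum_b m_b / (v_b + \epsilon)$, with $m_b$ the box mean,
   $v_b$ the population variance and $\epsilon$ a regulariser: dense
   homogeneous tissue scores high, noisy or boundary-straddling
   neighbourhoods low. In `"classic"` mode each voxel takes the mean of its
   minimum-variance box — conventional edge-preserving Kuwahara smoothing,
   in input intensity units. Boxes clipped at the volume border use
   in-bounds voxels only, with per-box counts adjusted accordingly.
3. **Binarization** (`binarize()`): `value > threshold`, with `"otsu"`
   maximising the between-class variance over a 256-bin histogram. Inside
   `segment_lobules()` automatic thresholds are computed from the
   SLA-restricted histogram: the global histogram is dominated by
   background and bright periphery and would place the cut between
   compartments rather than between lobule and septum.
4. **Cleanup** (`cleanup()`): Euclidean-ball closing (radius in voxel
   units; anisotropy deliberately ignored, as the structuring element
   models gaps in the *image grid*, not in physical space) followed by
   removal of foreground components below `min_island_voxels`
   (26-connectivity). Closing and island removal are each idempotent.
5. **Distance map** (`distance_map()`): exact Euclidean distance, in
   micrometres and honouring the anisotropic spacing, from every
   foreground voxel to the nearest background voxel centre (separable
   lower-envelope transform). Thresholding it at `distance_threshold`
   and labelling connected components yields the watershed seeds
   (`extract_seeds()`).
6. **Watershed** (`watershed_flood()`): seeded priority flood on a relief
   (by default the 3D Sobel gradient magnitude of the cleaned binary
   support), restricted to a flood domain, with a fully deterministic
   order: ascending relief, ties broken by ascending linear voxel index,
   remaining ties by queue insertion order.
7. **Foreground masking** (`apply_foreground()`): pointwise product with
   the *unfiltered* binarized volume, trimming watershed labels back to
   bright tissue.
8. **Graph merging** (`merge_subunits()`): septa have genuine holes, so
   the gradient borders are incomplete and the watershed over-segments.
   For labels $i, j$ let $S_{ij}$ be the number of 6-neighbour voxel face
   pairs with labels $\{i, j\}$ and $S_k$ the total surface of $k$ (faces
   against any different label or background). While any contact ratio
   $S_{ij} / \tfrac{1}{2}(S_i + S_j) \ge$ `merge_threshold`, the
   highest-ratio pair is merged (ties resolved toward the smallest label
   pair; the higher label is relabelled into the lower) and affected
   ratios are updated incrementally — equivalent to recomputation, since
   face counts depend only on label equality.

### SLA separation

`separate_sla()` concretises the preliminary core/periphery split: a local
standard-deviation map over the filter box is thresholded (septa and their
surroundings score high, the homogeneous periphery low), intersected with
an eroded tissue mask (erosion by `box_radius + 1` voxels per axis removes
the tissue/background boundary shell, which would otherwise dominate the
contrast map), and cleaned. The largest connected component with its
cavities filled is the core; it is trimmed by one `box_radius` per axis to
compensate the outward reach of the box SD estimator, and a user-supplied
exclusion mask (e.g. a delineated lymph node) is subtracted. The tissue
mask itself is the *hole-filled* binarized volume, because a bimodal
threshold classifies dark septa as background. There is no automatic
lymph-node detection: the occluder is an explicit input.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `box_radius` | (2, 2, 1) | voxels | filter/contrast box half-extent; smaller along z to match coarser axial sampling |
| `variance_epsilon` | 1 | intensity² | regularises the ratio-mode variance; set it near the noise variance for noisy data |
| `kuwahara_mode` | `"classic"` | — | see below |
| `closing_radius` | 0 | voxels | ball closing of the support; see below |
| `min_island_voxels` | 64 | voxels | denoising of the binarized support |
| `distance_threshold` | 3.2 | µm | minimum interior depth of a seed; must exceed the depth of septum holes but stay below the lobule half-width |
| `seed_connectivity` | 26 | — | connectivity of seed components |
| `min_seed_voxels` | 20 | voxels | discards noise seeds |
| `merge_threshold` | 0.1 | — | contact ratio above which fragments merge; fragments of one subunit share large interfaces (ratio ≳ 0.15) while distinct subunits touch only through septum holes (ratio ≲ 0.03) |

Defaults were calibrated once on the default synthetic phantom (the only
input with known ground truth); they are starting points for real data,
where the septum scale and noise differ, and every one of them is exposed
through the YAML config.

Two defaults deserve their rationale spelled out:

* **`kuwahara_mode = "classic"`.** The ratio filter collapses brightness
  and homogeneity into one dimensionless score. When lobule interiors are
  only 6–10 voxels wide and septa 3–4 voxels (the phantom's scale, and a
  realistic one after downscaling), voxels within one box-reach of a
  boundary average clean and straddling boxes, and their ratio response
  overlaps that of the septum interior: no threshold separates them, and
  the binarized support fragments. The minimum-variance variant assigns
  every near-boundary voxel the statistics of its best fully-interior box
  and keeps boundaries sharp. The ratio variant remains available
  (`kuwahara_mode = "ratio"`) and is preferable when structures span many
  voxels relative to the box.
* **`closing_radius = 0`.** A voxel-ball closing of any radius ≥ 1 fills
  gaps one or two voxels wide — which is exactly the thickness of a septum
  along the coarse z axis. Closing therefore welds stacked subunits
  together and collapses the seed field; small-island removal alone does
  the cleaning at this scale. On data where septa are everywhere several
  voxels thick, a small closing radius is useful again.

## The synthetic phantom

`generate_phantom()` emulates, deterministically given `rng_seed`:

* a box-shaped tissue slab in a dark background, with an unstructured
  bright periphery;
* an interior core (default 20% of the x-extent, ~15–25% of the tissue
  volume) tiled by `n_subunits` (default 18) subunits, each the union of
  1–3 random ellipsoids elongated preferentially in x–y; every covered
  core voxel belongs to the subunit of its nearest lobe in normalised
  ellipsoidal distance, which produces inter-digitated poly-lobular
  shapes;
* septa of `septum_width` (default 4 µm) realised by eroding each subunit
  by half the septum width in *physical* distance, plus a capsule band at
  the core boundary; per adjacent pair, a septum "window" of
  `window_radius` (default 3 µm) may re-open (probability 0.7), so true
  contact surfaces exist — real mesenchymal septa are incomplete, which
  is the very reason the workflow ends with a merging step;
* an ovoid occluder (lymph node analogue) at the core's edge, reported as
  a mask so it can be excluded exactly as a user would exclude a
  delineated node;
* additive Gaussian noise (default SD 10 against a lobule/septum contrast
  of 200/60).

What the phantom does **not** model: the optics (point-spread function,
attenuation with depth, mosaic stitching seams), intensity inhomogeneity
across the field, vessel networks, and septa of spatially varying
thickness. Passing the phantom-recovery tests therefore demonstrates that
the chain of operations is implemented coherently and that the workflow's
assumptions suffice on data satisfying them — not that the default
parameters transfer to any particular microscope or clearing protocol.

## Numerical choices

* The distance transform is exact (no chamfer approximation); oracle tests
  compare it to brute-force nearest-background search on random grids up
  to $8^3$, including anisotropic spacing.
* The watershed order is a total order (relief, linear index, insertion
  counter), so results are bit-reproducible across runs and platforms;
  property tests compare it against an exhaustive priority-flood
  simulation on all-random reliefs, masks and seeds on grids up to $6^3$.
* Contact ratios are ratios of small integers; merge ties are resolved by
  exact float equality (identical divisions give identical doubles) toward
  the lexicographically smallest label pair.
* Degenerate inputs fail early with typed conditions: constant volumes
  under Otsu (`lobuseg_degenerate_histogram`, surfaced as an empty-SLA
  error by `separate_sla()`), empty seed sets (`lobuseg_no_seed`), seeds
  outside the flood mask (`lobuseg_consistency_error`), all-covering
  exclusion masks (`lobuseg_empty_sla`).
* Morphological operations are built on the same distance transform
  (dilation/erosion by Euclidean balls), so closing is exactly idempotent.
* Volumes with no background have infinite foreground distances; the
  value propagates honestly rather than being clamped.

## Problem sizes

The default phantom is $128 \times 128 \times 32$ voxels at
$(1, 1, 2)$ µm spacing with 18 subunits — small enough that the full
pipeline (generation, SLA separation, segmentation, quantification)
completes in seconds, yet large enough that each subunit spans hundreds of
voxels across several z-planes. Unit tests use a $64 \times 64 \times 24$,
6-subunit variant. Oracle-equivalence tests run on hundreds of randomized
micro-volumes ($\le 8^3$).

## Interpreting the outputs

`subunit_volumes()` reports voxel counts, physical volumes (mm³) and
barycenters (µm); `contact_surfaces()` reports per-pair face counts,
physical areas (mm², summing per-orientation face areas) and the
normalized weight $S_{ij}/\tfrac12(S_i+S_j)$ — the same quantity used for
merging, now between *final* subunits, and the edge weight of the
connectivity graph. `partition_clusters()` operationalises the visual
identification of macro-domains as connected components above a weight
threshold (default 0.05); greedy-modularity community detection is
available as an alternative. Neither claims to reproduce a by-eye
clustering: the threshold is the analyst's choice, and the monotonicity
property (raising it never decreases the cluster count) is the tool for
exploring it.

The adjusted Rand index quoted by the acceptance machinery is computed
over voxels with a positive ground-truth label; septum voxels (truth 0)
are excluded, and voxels the segmentation leaves unlabelled there count
against it as an extra cluster.

## Known limitations

* The workflow is deliberately faithful to its description, including its
  tendency to under-segment where septa are weak: merging cannot split,
  only join, so a missing septum stretch is unrecoverable downstream.
* Automatic thresholds assume a roughly bimodal histogram within the SLA;
  strong illumination gradients violate this and call for explicit
  thresholds in the config.
* TIFF output is restricted to integer data (8/16-bit); float volumes and
  voxel spacing round-trip through NIfTI-1 instead.
* Desk-scale volumes only: everything is in-memory, single-threaded R and
  C++; tiled out-of-core processing of full-size mosaics is out of scope.
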