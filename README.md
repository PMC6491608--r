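# lobuseg

Semi-automatic 3D segmentation and morphometry of whole cleared adipose
fat pads.

Cleared whole-mount confocal imaging shows that the core of the murine
subcutaneous (inguinal) fat pad is partitioned into 15–21 *poly-lobular
subunits* — 3D-connected clusters of adipocyte lobules separated by thin,
darker mesenchymal septa — while the periphery has no such organisation.
`lobuseg` segments these subunits from autofluorescence or vessel-label
volumes, quantifies them, and builds their connectivity graph:

1. **SLA separation** — a local-contrast heuristic splits the tissue into
   the *Segmentable Lobule Area* (SLA) and the unstructured periphery,
   minus an optional user-supplied exclusion mask (e.g. the lymph node).
2. **Contrast filtering** — a customised 3D Kuwahara filter over eight
   octant boxes per voxel (mean of per-box mean/variance ratios, or the
   classic minimum-variance-box mean), which homogenises dense tissue
   while preserving septum boundaries.
3. **Seeded watershed** — binarization and morphological cleanup give the
   segmentation support; its exact anisotropic Euclidean distance
   transform is thresholded (in µm) into seeds; a deterministic
   priority-flood watershed on the 3D Sobel gradient relief partitions the
   support; pointwise multiplication with the unfiltered binarized volume
   trims the labels back to bright tissue.
4. **Contact-graph merging** — septa have holes, so the watershed
   over-segments; fragment pairs whose shared interface
   `S_ij / ((S_i + S_j)/2)` (face counts; `S_k` = total surface of label
   `k`) reaches `merge_threshold` are merged greedily, highest ratio
   first.
5. **Quantification and graph** — per-subunit voxel counts, physical
   volumes (mm³), barycenters (µm); per-pair contact surfaces and
   normalized weights; SLA/fat-pad ratio; a subunit graph (nodes at
   barycenters, sized by volume, edges weighted by contact ratio) with
   threshold-based cluster partitioning, exported to GraphML/JSON.

A deterministic **synthetic phantom generator** reproduces the study
conditions — an inter-digitated poly-lobular core (default 18 subunits)
with incomplete septa, a bright periphery, an ovoid lymph-node occluder
and Gaussian noise — and supplies the ground truth that every stage is
tested against.

## Worked example

```r
library(lobuseg)

# synthetic fat pad with known ground truth (128 x 128 x 32 voxels,
# (1,1,2) µm spacing, 18 subunits, seed 42)
ph     <- generate_phantom(phantom_spec())
comp   <- separate_sla(ph$volume, preprocess_params(), ph$truth$node_mask)
labels <- segment_lobules(ph$volume, sla = comp$sla,
                          exclusion = ph$truth$node_mask)
labels
#> <vol3d> 128 x 128 x 32 integer, spacing (1, 1, 2) µm
#>   19 positive labels, 43946 labelled voxels

head(subunit_volumes(labels), 3)
#>   label voxel_count volume_mm3   bx    by    bz
#> 1     1        7289   1.46e-05 31.5  63.8  4.07
#> 2     2        3642   7.28e-06 34.3  75.6 15.93
#> 3     3        1432   2.86e-06 31.2 106.2 14.67

head(contact_surfaces(labels), 3)
#>   label_i label_j face_count area_mm2  weight
#> 1       2       3         15  3.0e-05 0.00737
#> 2       2       4         28  4.2e-05 0.01286
#> 3       2       8         31  4.7e-05 0.01539
```

Nineteen subunits are recovered against 18 ground-truth subunits, with an
adjusted Rand index of 0.866 over the ground-truth-labelled voxels. The
`volume_mm3` column is `voxel_count` times the physical voxel volume; the
`weight` column is the contact ratio that also drives merging and the
connectivity graph.

The published per-pad morphometric arithmetic is a one-liner:

```r
mapply(sla_ratio, c(7.58, 16.34, 34.57), c(38.58, 95.89, 145.54))
#> 19.6 17.0 23.8        (% SLA / fat pad, rounded to 1 d.p.)
summarize_values(c(38.58, 95.89, 145.54))
#>   n  mean  sem
#> 1 3 93.34 30.9
```

## Command line

A thin CLI wraps the same functions (installed under `exec/lobuseg`):

```sh
lobuseg phantom  --spec spec.yaml --out-volume vol.nii --out-truth truth.nii
lobuseg segment  input.nii --config params.yaml --out labels.nii
lobuseg quantify labels.nii --spacing 1,1,2 --out volumes.csv --edges edges.csv
lobuseg graph    volumes.csv edges.csv --threshold 0.05 --out graph.graphml
lobuseg sweep    input.nii --grid grid.csv --out sweep.csv
lobuseg run      --config config.yaml
```

`run` executes segment → quantify → graph and writes `labels.nii`,
`volumes.csv`, `edges.csv`, `graph.graphml`, `summary.json` and a
provenance echo of the configuration; repeated runs are byte-identical.

## Layout

- `R/`, `src/` — implementation (R plus Rcpp kernels for the distance
  transform, connected components and watershed)
- `tests/testthat/` — unit, property and acceptance tests with
  brute-force oracles
- `vignettes/lobule-segmentation.Rmd` — the methods vignette: model,
  parameters, phantom design, numerical choices, limitations
- `exec/lobuseg` — command-line interface
- `scripts/acceptance.R` — headline-number reproduction
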