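---
title: "Density-based single-cell segmentation and marker quantification for IMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based single-cell segmentation and marker quantification for IMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Imaging mass cytometry (IMC) reads out metal-isotope-tagged antibodies by
laser ablation and mass cytometry, producing one intensity image per marker
over a tissue region of interest (ROI), typically 750 × 750 µm at roughly
1 µm per pixel. To compare a marker between patient groups *per cell* — for
example LYN or THBS1 in lymph-node fibroblasts of leukemia patients versus
healthy controls — the marker images must first be segmented into single
cells. `imcseg` implements a marker-driven segmentation that clusters
bright pixels of lineage channels (Vimentin for fibroblasts, CD31 for
endothelium, CD68 for macrophage-lineage cells) directly, without a
nucleus-seeded watershed or a learned model, followed by overlap-based cell
typing, per-cell quantification, and two-group statistics.

## Pipeline stages and their parameters

All constants live in one `pipeline_config()` object; no stage hard-codes a
number. The defaults are the procedure's reference operating point.

1. **Hot-pixel removal** (all channels). A pixel whose count exceeds the
   maximum of its 8 neighbors by more than `hot_pixel_threshold` (default
   50 counts) is an isolated detector artifact and is replaced by that
   neighbor maximum. The rule runs in a single pass over the original image,
   so it is idempotent and never increases a value; at borders only existing
   neighbors are consulted.
2. **Background subtraction** (segmentation channels). Uneven staining and
   ablation intensity vary on a scale much larger than a cell, so the
   background is estimated as a Gaussian blur with `blur_sigma` = 40 px and
   subtracted; negative residuals are clamped to zero because the following
   stage needs nonnegative weights. The blur uses a separable kernel
   truncated at 4σ and symmetric-reflect boundaries (`d c b a | a b c d`),
   fixed so that results are bit-reproducible and testable against a dense
   convolution.
3. **Weight transform.** Background-corrected intensities become DBSCAN
   sample weights: values strictly below the 30th percentile of the pixel
   population are zeroed, values above the 99.5th percentile are clipped,
   and the map is divided by its new maximum so the largest weight is
   exactly 1. Percentiles use linear interpolation over *all* pixels (zeros
   included); computing them over nonzero pixels only is available via
   `percentile_population = "nonzero"` since the population is a
   convention, not a law. The strict "below" keeps a constant image mapping
   to all-ones rather than all-zeros.
4. **Weighted DBSCAN** (`dbscan_eps` = 2 px, manhattan metric,
   `dbscan_min_weight` = 4). Each positive-weight pixel is a point
   `(row, col)` carrying its weight as a *sample weight*: a point is a core
   point iff the weight sum over its ε-neighborhood (itself included)
   reaches the threshold. This is the standard weighted-DBSCAN contract;
   treating the weight as a third coordinate instead would make an integer
   `min_samples` of 4 incoherent with weights in (0, 1]. Cluster growth,
   border-point attachment (nearest core, ties to the lowest cluster id)
   and id assignment (row-major position of the first member pixel) are all
   fixed so the output is independent of any input ordering. The
   `dbscan_leaf_size` field (3) is recorded for completeness of the
   parameter set but is a tree-search performance knob with no effect on
   results. The grid implementation is checked in the test suite against an
   independent brute-force O(n²) DBSCAN on random weight maps.
5. **Local-maxima splitting.** Touching cells merge into one density
   cluster, so local maxima are detected on the background-corrected image
   and any cluster containing m ≥ 2 maxima is split into m clusters, each
   pixel joining its nearest contained maximum (Euclidean distance, ties to
   the lexicographically smaller maximum). A maximum is a positive pixel
   that is not smaller than any neighbor within `maxima_footprint_radius`
   (default 4 px); connected equal-valued plateaus count once, represented
   by their smallest (row, col). The footprint radius matters on count
   data: detector counts are shot-noise limited, and with a bare 3 × 3
   footprint nearly every pixel-level Poisson fluctuation inside a cell
   becomes a "maximum", shattering each cluster into fragments smaller than
   the erosion survives. Four pixels is about one cell radius at 1 µm/px:
   large enough to suppress intra-cell noise peaks, small enough to resolve
   adjacent touching cells. Radius 1 remains available for noise-free
   images.
6. **Cell typing.** CD31-positive regions are endothelial cells. A
   Vimentin-positive region overlapping the union of all CD31-positive
   pixels by strictly more than `overlap_discard_fraction` (30%) of its own
   area is discarded as a Vimentin⁺CD31⁺ vessel profile; remaining Vimentin
   regions are fibroblasts. The denominator is the Vimentin region's own
   area and the numerator uses the pooled CD31 mask, the most literal
   reading of "overlap by more than 30% of their area". CD68 regions are
   carried through untyped (`"unassigned"`) for completeness.
7. **Erosion and area filter.** Cell masks are shrunk by
   `erosion_iterations` = 3 passes of binary erosion with the 3 × 3 cross
   (the common default structuring element; a square is available) to avoid
   signal contamination from neighbors; pixels beyond the image border
   count as background. Cells with eroded area outside the inclusive band
   [`min_area`, `max_area`] = [10, 800] px² are discarded as likely false
   detections — this also silently removes regions emptied by erosion.
   Typing happens before erosion, matching the stated stage order.
8. **Quantification.** Per cell, the arithmetic mean of each quantification
   channel (LYN, THBS1 by default) over the eroded pixels is computed on
   the hot-pixel-cleaned **raw** channel — smoothing and the weight
   transform apply only to segmentation channels — and transformed as
   `asinh(x / cofactor)` with `arcsinh_cofactor` = 5, the standard
   variance-stabilizing convention for cytometry counts.

## Statistics

`compare_groups()` pools all cells of the requested type across ROIs and
samples within each group and applies an independent two-sided t-test to
the arcsinh values. The Welch (unequal-variance) variant with
Welch–Satterthwaite degrees of freedom is the default because per-group
cell counts and variances differ; Student's pooled variant sits behind
`var_equal = TRUE`. The degenerate case of two zero-variance samples with
equal means returns t = 0, p = 1 (df set to the pooled n₁ + n₂ − 2).
Summaries use the violin/box convention: median and quartiles by linear
interpolation, whiskers at the Tukey adjacent values (extreme observations
within 1.5 × IQR of the quartiles).

Pooling cells ignores patient-level clustering; per-cell n's (thousands)
therefore overstate the effective sample size relative to a mixed-effects
analysis. This is faithful to the per-cell figure convention the pipeline
reproduces and is flagged here as a limitation, not corrected.

`cross_layer_concordance()` compares log2 fold-change tables from two omics
layers: identifiers present in both tables and exceeding `threshold` = 0.8
in absolute log2-FC in **at least one** layer are selected and Spearman's
rank correlation (average ranks on ties) is returned. Whether the filter
should bind in one or both layers is ambiguous in the field's usual
phrasing; "both" is available via `mode = "both"`. Fewer than 3 selected
identifiers is an error rather than a meaningless coefficient.

## The synthetic-data generator

Patient imaging data of this kind are typically not deposited, so every
stage is validated against simulations with known ground truth
(`simulation_config()`, `generate_roi()`, `generate_cohort()`):

* **Geometry.** 750 × 750 px ROIs at 1 µm/px, 150 cells by default, placed
  by rejection sampling with a 15 px minimum center separation (a realistic
  packing for stromal/vascular cells and tight enough that touching blobs
  exercise the maxima-splitting stage). Cells are isotropic Gaussian blobs
  (σ = 4 px, truncated at 3σ) — the simplest shape that exercises maxima
  detection, splitting, erosion and the area filter with analyzable truth.
* **Panels.** Fibroblasts express Vimentin + LYN + THBS1, endothelial cells
  CD31 + a weak Vimentin signal (so the 30% overlap-discard rule is
  exercised, mirroring real Vimentin⁺CD31⁺ vessels) + LYN + THBS1, "other"
  cells CD68; all carry DNA. Peak amplitudes default to 25 counts for
  lineage markers (8 for the weak endothelial Vimentin), 15 for LYN/THBS1,
  with lognormal between-cell spread (sdlog 0.35).
* **Noise.** Constant background (0.3 counts) plus per-pixel Poisson noise
  — the correct first-order model for ion-count data; Gaussian and
  noise-free models are available. Hot pixels are injected at rate 5×10⁻⁵
  with +150 counts at recorded coordinates so the cleaning stage is
  testable.
* **Group effects.** Multiplicative amplitude factors per
  (group, type, channel); the default emulates the directions reported for
  leukemic versus healthy lymph nodes: CLL-LN fibroblast LYN × 1.5 and
  THBS1 × 0.6.
* **Truth.** Per-cell centers, types and amplitudes, per-lineage label
  masks (disks of radius 2σ), and the injected hot-pixel coordinates.
  `evaluate_segmentation()` greedily matches predicted centroids to truth
  centers by ascending distance (type must agree, distance ≤ 5 px by
  default) and reports precision/recall/F1 plus the Pearson correlation
  between measured raw means and true amplitudes.

What the simulator does **not** model: ablation physics, isotope spillover
between channels, autofluorescence-like structured background, non-convex
cell shapes, and spatially correlated staining. Passing tests therefore
demonstrate the correctness of the computational procedure under a
realistic noise model, not performance on real tissue.

## Numerical and design choices

* Coordinates are 0-based (row, col); areas are pixel counts.
* The blur boundary is symmetric reflection with edge repetition and the
  kernel is truncated at `ceil(4σ)`; both are stated because they change
  low-order digits and the package promises bit-reproducibility.
* DBSCAN border-point ties and cluster-id order are fixed (see above)
  because classical DBSCAN leaves them implementation-defined.
* A cluster containing zero maxima (possible, since weights and maxima come
  from different transforms) is retained unchanged.
* A point's own weight counts toward its core condition; with this
  convention the plus-shaped five-pixel figure at unit weights is exactly
  one cluster at the default ε = 2, min weight 4.
* Erosion of each region is computed on its own mask, so two touching cells
  erode independently rather than propping each other up.
* Per-ROI seeds in a cohort are `base_seed + index`: reproducible without
  inter-ROI correlation.
* Test and validation problem sizes: oracle equivalence on 16 × 16 maps
  (50 replicates), recovery on one full 750 × 750 ROI, group-effect
  recovery and type-I calibration on 2 × 6 ROIs of 256 × 256 px with ~40
  cells each (100 null replicates) — sizes at which the brute-force oracles
  and replicated cohorts are comfortably computable while leaving every
  pipeline stage active.

## Known limitations

* **Intensity recovery has a structural ceiling.** The segmented extent of
  a cell depends on its *lineage-marker* brightness, which is independent
  of the quantified marker; the per-cell mean is therefore diluted by a
  geometry factor whose spread (CV ≈ 0.13 under default conditions) caps
  the correlation between measured means and true amplitudes at roughly
  0.94–0.95 when the between-cell amplitude CV is ≈ 0.38. Larger true
  biological spread raises the apparent recovery; this is a property of
  segmentation-then-mean quantification generally, not of this
  implementation.
* Pooled per-cell tests, no multiple-testing correction across markers, and
  no spillover compensation — all faithful to the procedure the package
  reproduces.
* The TIFF dialect is deliberately minimal (multi-page grayscale + CSV
  channel manifest); OME-TIFF metadata parsing is an extension point, not a
  feature.
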