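# imcseg

Single-cell segmentation, cell typing, marker quantification and two-group
statistics for imaging mass cytometry (IMC) regions of interest, plus a
synthetic multiplexed-image generator with known ground truth.

IMC produces one intensity image per metal-tagged antibody over a laser
ablated tissue region (typically 750 × 750 µm at ~1 µm/px). To compare a
marker *per cell* between two patient groups — e.g. LYN or THBS1 in
lymph-node fibroblasts from chronic lymphocytic leukemia (CLL-LN) versus
healthy controls (HC-LN) — the package implements a marker-driven
segmentation pipeline:

1. hot-pixel removal (8-neighbor rule, threshold 50 counts);
2. background subtraction: image − Gaussian blur (σ = 40 px), clamped at 0;
3. weight transform: zero below the 30th percentile, clip at the 99.5th,
   normalize the maximum to 1;
4. **weighted DBSCAN** over positive pixels — a pixel is a core point iff
   the weight sum within manhattan distance ε = 2 (itself included) is
   ≥ 4 — followed by **local-maxima splitting** of clusters that contain
   several intensity peaks;
5. typing: CD31 regions → endothelial; Vimentin regions overlapping the
   CD31 mask by > 30% of their area are discarded, the rest → fibroblast;
6. 3 passes of binary erosion (3 × 3 cross), then an inclusive 10–800 px²
   area filter;
7. per-cell mean intensity of the quantification markers on the cleaned raw
   channels, transformed as asinh(x / 5);
8. group comparison of the arcsinh values with Welch's two-sided t-test and
   Tukey box/violin summaries (median, quartiles, adjacent values).

An auxiliary operation, `cross_layer_concordance()`, computes the Spearman
rank correlation of log2 fold changes shared between two omics layers after
an |log2FC| > 0.8 filter.

Because patient IMC images of this kind are generally not deposited, the
package ships a first-class simulator (`simulation_config()`,
`generate_roi()`, `generate_cohort()`) that renders blob-shaped cells of
three lineages with Poisson count noise, hot pixels, and per-group
amplitude effects, together with ground-truth centers, types, amplitudes
and label masks, so every stage is verifiable end to end
(`evaluate_segmentation()`).

## Worked example

Simulate a small two-group cohort (3 ROIs per group, 256 × 256 px, ~40
cells each; the default group effect scales CLL-LN fibroblast LYN
amplitudes × 1.5), run the full pipeline, and compare fibroblast LYN:

```r
library(imcseg)

sim <- simulation_config(image_size = 256, n_cells = 40)
coh <- generate_cohort(sim, c("HC-LN" = 3, "CLL-LN" = 3), base_seed = 42)
tab <- run_cohort(coh)

table(tab$group, tab$cell_type)
#>          endothelial fibroblast unassigned
#>   CLL-LN          34         59         24
#>   HC-LN           37         60         24

compare_groups(tab, "LYN", "fibroblast", groups = c("HC-LN", "CLL-LN"))
#>   n1 n2 median1 median2 t_statistic degrees_of_freedom   p_value
#> 1 60 59   1.464   1.848      -6.588              115.1 1.396e-09
```

The pipeline finds ~40 cells per ROI and types them; the negative t
statistic says the second group (CLL-LN) has the higher arcsinh LYN signal,
recovering the simulated ×1.5 amplitude effect at p ≈ 1.4e−9. Medians are
on the arcsinh(x/5) scale.

Segmentation accuracy against ground truth on a full-size ROI
(750 × 750 px, 150 cells):

```r
g  <- generate_roi(simulation_config(), "HC-LN", "demo", seed = 42)
pr <- run_pipeline(g$roi)
evaluate_segmentation(pr$cells, g$truth, match_radius = 5)
#> precision 0.992  recall 0.992  F1 0.992  intensity recovery r 0.937
```

A command-line front end (`inst/scripts/imcseg`) exposes `simulate`,
`segment` (multi-page TIFF + channel manifest → `cells.csv` + label masks +
run manifest), `compare`, and `concordance` subcommands.

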