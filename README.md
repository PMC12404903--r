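# puncta

Per-cell quantification of RNAscope single-molecule FISH signal in
multichannel confocal z-stacks.

RNAscope hybridization renders each mRNA molecule as a diffraction-limited
fluorescent "dot". Studies that use it typically need the same chain of
measurements: delineate cell nuclei in 3D from a Hoechst counterstain,
expand each nucleus a couple of pixels to capture perinuclear cytoplasm,
detect and count the dots of each probe channel inside every cell, decide
which cells count as *positive* for a probe, and compare positive-cell
numbers across experimental groups with nonparametric statistics. `puncta`
implements that pipeline for R, plus a calibrated synthetic-data generator
so every stage is testable against ground truth without any raw images.

It is aimed at imaging labs quantifying transcript expression per cell —
for example across hormonal states, where the number of expressing cells
(rather than expression per cell) is the readout of interest.

## The method in brief

* **Dot detection** uses the isotropic undecimated (*à trous*) wavelet
  transform with the separable B3-spline kernel (1,4,6,4,1)/16: detail
  planes `W_j = A_{j-1} − A_j` satisfy `Σ_j W_j + A_J = input` exactly.
  Dots are suprathreshold components of the scale-2 detail plane at a hard
  threshold `τ` (default 10 ADU), positioned at detail-weighted centroids
  and linked across adjacent z-planes so each dot is counted once.
* **Cell ROIs** are nuclei labels (built-in classical 3D watershed, or any
  external label TIFF) dilated 2 px in-plane by competitive nearest-label
  growth, so ROIs never overlap and each dot belongs to at most one cell.
* **Positive cells**: per probe, the pooled per-cell count distribution
  (zero-count ROIs excluded) sets the threshold `mean − 2·SD`, rounded to
  whole dots and floored at 1; a cell is positive when its count reaches
  the threshold.
* **Group statistics**: section counts are averaged per animal, then
  compared with the tie-corrected Kruskal–Wallis statistic
  `H = [12/(N(N+1)) Σ nᵢR̄ᵢ² − 3(N+1)] / [1 − Σ(t³−t)/(N³−N)]`
  and Dunn's pairwise z-tests with Bonferroni adjustment.

See the methods vignette (`vignettes/rnascope-quantification.Rmd`) for
assumptions, parameter rationale, and limitations.

## Worked example

```r
library(puncta)

# A synthetic 3-channel stack: 7 nuclei, two probes, realistic noise.
cfg <- sim_image_config(
  shape_zyx = c(4L, 96L, 96L), n_nuclei = 7L,
  nucleus_radius_um_range = c(2.8, 3.4),
  dots_per_cell_dist = list(
    probe1 = list(pi0 = 0.3, mean = 12, dispersion = 3),
    probe2 = list(pi0 = 0.5, mean = 10, dispersion = 3)),
  seed = 7L)
sim <- simulate_stack(cfg)

nuclei <- segment_nuclei(sim$stack)
rois   <- dilate_labels(nuclei, dilation_params(radius_px = 2))
spots  <- rbind(
  assign_spots(detect_spots_stack(sim$stack, "probe1"), rois),
  assign_spots(detect_spots_stack(sim$stack, "probe2"), rois))
counts <- tabulate_counts(spots, rois)
counts[, c("cell_id", "count_probe1", "count_probe2")]
#>   cell_id count_probe1 count_probe2
#> 1       1           11            7
#> 2       2            0            0
#> 3       3            0            0
#> 4       4            0            7
#> 5       5           10           13
#> 6       6            5            6
#> 7       7            0            0
```

All 7 planted nuclei are recovered and the per-cell counts match the
simulator's ground truth (`sim$truth$true_counts`): cells 2, 3 and 7 were
drawn as non-expressing for both probes.

Group-level inference on a simulated five-group study (four estrous
stages plus lactation, 4 animals per group, 3 sections each, arcuate
nucleus means calibrated to 12.3 positive cells/section in diestrus vs
178.2 in lactation):

```r
design <- simulate_group_counts(group_sim_config(regions = "ARN", seed = 3L))
am     <- aggregate_per_animal(design)
groups <- split(am$mean_cells_per_section, am$stage)
kruskal_wallis(groups)
#> Kruskal-Wallis 14.68 (df = 4), p = 0.005423
#>      group n      mean        sem mean_rank
#>   diestrus 4  11.33333  1.7690759     6.875
#>     estrus 4  10.91667  0.3154949     6.250
#>  lactation 4 215.16667 43.8022704    18.500
#>  metestrus 4  11.00000  1.6942167     6.375
#>  proestrus 4  26.33333  4.3226364    14.500

dunn_posthoc(groups, comparisons = list(c("lactation", "diestrus"),
                                        c("lactation", "metestrus")))
#>     group_i   group_j mean_rank_diff     z    p_raw p_adjusted n_comparisons
#> 1 lactation  diestrus          11.62 2.781 0.005419   0.010838             2
#> 2 lactation metestrus          12.12 2.901 0.003724   0.007449             2
```

The lactation group's ~19-fold elevation in expressing cells is detected
(KW p = 0.005; Dunn adjusted p ≈ 0.01 against both baseline stages).

`run_pipeline(run_config(manifest, out_dir))` composes all stages over a
manifest of stacks and writes per-stack spot tables, the pooled cell-count
table, thresholds, co-expression summaries and statistics under `out_dir`;
`inst/scripts/puncta-cli.R` wraps `simulate`, `detect` and `run` for shell
use.

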