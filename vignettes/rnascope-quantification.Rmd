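---
title: "Quantifying RNAscope dots per cell: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNAscope dots per cell: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

RNAscope fluorescent in situ hybridization renders individual mRNA
molecules as diffraction-limited "dots". Counting those dots per cell in
confocal z-stacks turns images into per-cell transcript counts, and from
there into the biology-level quantities a study reports: how many cells
in a brain region express a transcript, how expression differs between
physiological groups, and how often two transcripts co-occur in the same
cell. `puncta` implements that pipeline end to end, plus a synthetic-data
generator calibrated to the imaging geometry it targets, so every stage
can be validated against a known ground truth.

```{r setup, eval = FALSE}
library(puncta)
```

# The pipeline

Each multichannel stack (`probe1`, `probe2`, nuclear counterstain;
0.553 um/pixel laterally and 2 um z-steps by default) passes through five
stages:

1. **Nuclei delineation in 3D** (`segment_nuclei()` or `load_labels()`).
2. **Cytoplasmic dilation** of each nucleus by 2 px (`dilate_labels()`).
3. **Dot detection** per probe channel with an a trous B3-spline wavelet
   and a hard 10 ADU threshold (`detect_spots_stack()`).
4. **Per-cell counting and positive-cell classification**
   (`assign_spots()`, `tabulate_counts()`, `positivity_threshold()`,
   `classify_positive()`, `coexpression_summary()`).
5. **Group statistics**: per-animal aggregation, tie-corrected
   Kruskal-Wallis and Dunn's post-hoc comparisons
   (`aggregate_per_animal()`, `kruskal_wallis()`, `dunn_posthoc()`).

`run_pipeline()` composes the stages over a manifest of stacks, derives
one positivity threshold per probe from the pooled run, and writes every
intermediate as CSV/TIFF/JSON so a run is fully reproducible
(identical inputs give byte-identical outputs).

# Dot detection

## The transform

The detector uses the isotropic undecimated ("a trous") wavelet
transform standard in spot-detection microscopy. With \(A_0\) the raw
plane, each scale smooths with the separable B3-spline kernel
\((1,4,6,4,1)/16\) whose taps are spaced \(2^{j-1}\) pixels apart, and
keeps the difference as the detail plane:

\[ A_j = A_{j-1} * h_j, \qquad W_j = A_{j-1} - A_j,
   \qquad \sum_{j=1}^{J} W_j + A_J = A_0 . \]

The reconstruction identity is exact by construction and is asserted to
`1e-10` in the tests. Mirror boundary handling keeps constant planes
invariant, so a global background offset can never create detections.

## Threshold and scale choice

Detection applies a hard threshold `tau_adu` (default 10 ADU, the
working threshold of the imaging regime this package targets) to the
detail coefficients. Two defaults deserve explanation because the
transform itself does not dictate them:

* **`scales_used = 2`.** A diffraction-limited dot at ~0.55 um/pixel has
  a Gaussian sd near 1 px; its detail energy peaks at scale 2. Measured
  on a rendered sigma = 1 px dot of 50 ADU amplitude, the detail maxima
  are roughly \(W_1 = 22.5\), \(W_2 = 15.4\), \(W_3 = 5.6\) ADU. A mask
  that also required \(W_3 \ge 10\) (an AND over scales 2-3) would
  reject every such dot, so the default thresholds scale 2 alone.
  Multi-scale masks remain available via the parameter.
* **`min_mask_px = 1`.** At shot-noise levels typical of a 100 ADU
  background, the scale-2 detail noise sd is about 2 ADU, so
  tau = 10 ADU sits near 5 sigma and single-pixel false hits are already
  vanishingly rare (measured precision 0.995-1.0). Requiring a second
  suprathreshold pixel costs about 6% recall on dots that sit between
  z-planes; the default therefore accepts single-pixel components, and
  the parameter exists for low-threshold configurations.

Candidates are 8-connected suprathreshold components, positioned at the
detail-weighted centroid. Per-plane candidates within `link_radius_px`
(default 2) in adjacent planes are chained greedily (closest pair first,
each candidate used once) and emitted as a single spot at the
detail-weighted mean position — at 2 um z-steps a dot is essentially a
one-to-two-plane object, so full 3D wavelets would add cost without
information, and the linking step prevents double counting.

# Nuclei and cell ROIs

The deep-learning segmenters often used for nuclei detection are treated
as a pluggable upstream stage: `load_labels()` imports any integer label
TIFF (relabelling non-contiguous ids and validating shape), while the
built-in `segment_nuclei()` provides a classical, dependency-free route:
anisotropic Gaussian smoothing, a global Otsu (or fixed) threshold,
per-plane hole filling, an anisotropy-aware Euclidean distance
transform, a peak-seeded 3D watershed, and a voxel-volume filter
(default 30-10,000 voxels; a ~5 um nucleus at the default calibration
occupies on the order of a few hundred voxels).

Numerical details chosen for determinism and anisotropy:

* The distance transform weights z by `z_step_um / pixel_size_um`
  (~3.6 at defaults) and is computed exactly up to a cap
  (`edt_cap_px`, default 15 px, comfortably above any nucleus radius).
* Watershed seeds are distance-map local maxima, deduplicated by greedy
  non-maximum suppression ordered by (descending distance, then z, y,
  x); flooding processes voxels in decreasing-distance order, each
  taking the smallest positive 26-neighbour label. Identical input
  always yields identical labels.

Each nucleus is then dilated 2 px to capture the perinuclear cytoplasm
where transcripts accumulate. Dilation is *competitive*: a background
voxel joins the nearest label (ties to the smallest id), so ROIs form a
partition and a dot can belong to at most one cell. It is in-plane by
default because 2 px is sub-voxel along z at a 2 um step; an
`isotropic_3d` mode serves isotropic data. The implementation is
verified against brute-force nearest-label assignment on random volumes.

# From counts to positive cells

The per-cell count distribution of a whole run sets the positivity
threshold for each probe: mean minus `k_sd` (default 2) standard
deviations, rounded half-up to whole dots and floored at 1. Two
conventions matter:

* **Zero-count ROIs are excluded by default.** In sparsely expressing
  tissue most ROIs contain no dots; including them drives
  mean − 2 SD far below zero and the rule degenerates to "any dot",
  which contradicts the whole-dot thresholds such data actually
  support. The distribution that matters is that of *expressing* cells.
  `include_zero_cells = TRUE` restores the pooled version.
* **The comparator is inclusive** (`count >= threshold`), keeping cells
  that sit exactly at the integer threshold; `gt` is available.

Thresholds are derived once per run (pooled across all stacks), matching
a single-pipeline-run design; classification is monotone in the
threshold by construction. Co-expression summaries report the dual
positive count and the conditional percentages both pooled and as
per-section means, and an empty denominator yields `NA`, never 0.

# Group statistics

The unit of analysis is the animal: section counts are averaged per
animal and region before testing, matching designs with 3-4 animals per
group (a per-section alternative is exposed via `stats_unit`). With
pooled mid-ranks \(\bar R_i\) and tie groups of size \(t\):

\[ H = \frac{\frac{12}{N(N+1)} \sum_i n_i \bar R_i^2 - 3(N+1)}
          {1 - \sum_t (t^3 - t) / (N^3 - N)}, \]

with the chi-square upper tail on \(k-1\) degrees of freedom, and Dunn's
pairwise

\[ z_{ij} = \frac{\bar R_i - \bar R_j}
  {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3-t)}{12(N-1)}\right)
   \left(\frac{1}{n_i}+\frac{1}{n_j}\right)}} \]

with two-sided normal p-values, Bonferroni-multiplied over the requested
comparisons. Degenerate inputs follow documented conventions: an
entirely tied pooled sample gives \(H = 0, p = 1\) (and \(z = 0, p = 1\)
for Dunn), rather than an error.

Two caveats the tests make explicit. The chi-square reference is an
approximation: at \(N \le 8\) the package compares it against the fully
enumerated permutation null and finds agreement within 0.05 using the
mid-p convention (the permutation null is coarsely discrete, so
mid-p — \(P(H>h) + P(H=h)/2\) — is the appropriate comparison with a
continuous tail), for designs with at least three observations in most
groups; three-group designs made only of pairs fall outside the
approximation's useful range. And Bonferroni over all 10 pairs of a
five-group design is conservative — for a focused contrast, pass the
comparisons of interest explicitly.

# The synthetic-data generator

`simulate_stack()` emulates the acquisition this pipeline targets:
512 x 512 px fields at 0.553 um/pixel, 2 um z-steps through a 16 um
section (8 planes), nuclei as soft-edged spheres in physical units
(hence axially flattened ellipsoids in voxels) of 3-5 um radius placed
by rejection sampling with centre separation at least the sum of radii,
and dots rendered as anisotropic Gaussians (sigma 1 px laterally,
0.5 slices axially, 50 ADU amplitude) over a 100 ADU background with
Poisson shot noise, 2 ADU Gaussian read noise, and integer ADU
quantization (all three switchable off for exact tests). Per-cell dot
counts follow a zero-inflated negative binomial — a non-expressing
fraction `pi0` plus a broad expressing distribution — which is the
mixture the positivity-threshold rule presumes. Intracellular dots are
placed uniformly over the cell's *dilated* footprint with a bounded
sub-voxel offset (< 0.5 px, so a dot's nearest voxel is its footprint
voxel and spot-to-cell assignment is well-defined in the noise-free
limit); 5% of dots are placed on background voxels to exercise
background assignment — a placeholder rate, since extracellular dot
density in real tissue is not characterised. When a minimum dot
separation is requested (the "well-separated" validation regime), dots
that cannot be placed at that spacing after bounded retries are dropped
and the ground-truth counts tally only what is in the scene.

`simulate_group_counts()` generates the count-level analogue of the
study design: five groups (four estrous stages plus lactation), 3-4
animals per group, three sections per region, negative binomial section
counts (dispersion 5) around region-by-stage means scaled by a mean-one
lognormal animal effect (sd 0.2 on the log scale). The default means
anchor to the calibrated values: 12.3 (diestrus) to 178.2 (lactation)
positive cells per section in the arcuate nucleus, with analogous pairs
for the dorsomedial nucleus and posterodorsal medial amygdala; stages
without a calibrated value take values near their region's baseline,
including a moderate proestrous elevation in the ARN.

`simulate_study()` scales the full imaging study to desk size: 60
stacks of 128 x 128 x 4 voxels with 24 nuclei each, the stage effect
carried by the fraction of cells expressing probe 2 (0.07, 0.15, 0.45,
0.22, 0.90 across metestrus, diestrus, proestrus, estrus, lactation —
chosen to reproduce the qualitative ordering of the calibrated means
with gaps resolvable at 12 sections per stage) while probe 1 is
constant. This mirrors the signature finding the statistics must
recover: the *number* of expressing cells changes, not the expression
per cell.

**What the simulator does not model** — and therefore what passing
tests do not certify on real data: optical PSF structure beyond an
anisotropic Gaussian, spectral bleed-through, tissue autofluorescence,
nucleus shape irregularity and clustering, transcript clusters that
merge into super-resolution-limited blobs, and section-edge artefacts.
The generator validates the pipeline's logic and calibration, not the
biology of any particular tissue.

# Problem sizes and reproducibility

The test suite exercises the wavelet identities on 100 random 64 x 64
planes, detection at the working threshold on 256 x 256 x 6 stacks with
~200 dots per channel at SNR 5 (amplitude 5 x the background shot-noise
sd), dilation against brute force on 50 random volumes up to 32 voxels
per side, exact count recovery on 20 noise-free fixtures, the
permutation comparison on all designs of at most 8 observations listed
above, the calibrated two-group lactation contrast over 200 simulation
seeds, and one full 60-stack synthetic study run twice to confirm
byte-identical outputs. These sizes were chosen so the whole suite runs
in a few minutes on one core while still pinning every claim to a
computation.

# Known limitations

* The built-in segmenter is a classical watershed; heavily overlapping
  or irregular nuclei are better served by importing labels from a
  trained segmenter through `load_labels()`.
* Dots closer than ~4 px merge into one detection (no cluster
  unmixing); counts in very high-expression cells saturate accordingly.
* The positivity threshold assumes the expressing-cell count
  distribution is roughly unimodal; strongly bimodal runs may warrant
  per-section thresholds.
* p-values rely on the chi-square / normal approximations discussed
  above; with 3-4 animals per group they are adequate near the decision
  boundary but not exact.
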