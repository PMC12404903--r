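Package: puncta
Title: Per-Cell RNAscope Dot Quantification from Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies single-molecule fluorescent in situ hybridization
    (RNAscope) signal in multichannel confocal z-stacks. Nuclei are
    delineated in 3D from the counterstain channel (built-in classical
    watershed segmenter, or externally produced label volumes), dilated by
    a small perinuclear margin to capture cytoplasmic transcripts, and
    diffraction-limited mRNA dots are detected per probe channel with an
    a trous B3-spline wavelet transform and hard intensity threshold.
    Per-cell dot counts feed a data-driven positive-cell threshold
    (mean minus k standard deviations of the count distribution),
    dual-probe co-expression summaries, and nonparametric group statistics
    (tie-corrected Kruskal-Wallis with Dunn's post-hoc comparisons).
    A synthetic-data module generates calibrated confocal-like stacks and
    group-level count tables with ground truth so every stage of the
    pipeline is testable without raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
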