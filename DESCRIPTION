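Package: afmchrom
Title: Single-Molecule AFM Morphometry of Centromeric Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and morphometry of nucleosomes and large inner-kinetochore
    (CENP-C) complexes in atomic force microscopy (AFM) topographs: background
    flattening, particle detection, height / Feret diameter / area / roundness
    measurement, nucleosome-free DNA contour tracing with base-pair conversion,
    immuno-AFM height-shift identification, an MNase protection-ladder simulator,
    comparative-Ct qPCR analysis, and the group statistics (one-way ANOVA, Tukey
    HSD, paired t) used alongside them. Includes a synthetic topograph generator
    with worm-like-chain DNA filaments, tip convolution and per-population presets
    so every pipeline stage is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    graphics,
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
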