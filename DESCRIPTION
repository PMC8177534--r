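Package: rhizotrace
Title: Quantification of Tip-Growth Stability Phenotypes in Rhizoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify tip-growth stability phenotypes of tubular,
    tip-growing cells such as Marchantia polymorpha rhizoids. Implements 3D
    sinuosity measurement from confocal image stacks (per-slice segmentation,
    simulated-annealing path ordering, direction-change fragmentation, LOWESS
    trajectory smoothing), microtubule bundling and parallelness metrics
    (fluorescence-intensity skewness, skeleton segment orientations), a
    two-channel longitudinal intensity-ratio profile, a UV-B mutagenesis
    candidate-variant filter cascade with coding-consequence annotation, and
    segregation-genetics arithmetic with the associated group-comparison
    statistics. A synthetic-data module generates image stacks, filament
    textures, variant tables and gene models with known ground truth so every
    stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    Biostrings,
    tiff,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
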