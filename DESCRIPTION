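Package: nanodomain
Title: Quantification of Plasma-Membrane Protein Nanodomains from Confocal and Immunogold Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the clustering of plasma-membrane proteins at
    polar domains of plant cells. Implements a thresholding-free blob detector
    for confocal stacks (strict local maxima on maximum-intensity projections,
    growing-window size classification, 5-9 pixel size gating, membrane-area
    estimation and cluster densities per square micron), distance-based
    clustering of immunogold particle coordinates (55 nm single-linkage
    grouping, scattered/doublet/cluster classification, Feret diameters,
    apical/central/basal 2 micron band statistics and particles-per-cluster
    gradients), an apical-to-lateral polarity index, group-comparison
    reporting (Mann-Whitney U, t-tests), and seeded generators of synthetic
    confocal stacks and clustered immunolabel point fields with exported
    ground truth, so that every stage of the pipeline can be validated
    without original micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
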