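Package: ibscreen
Title: Quantification of Protein Inclusion Bodies in High-Content
    Yeast Microscopy Screens
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@ibscreen.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully scripted reimplementation of the
    image-quantification pipeline used in genome-wide yeast screens for
    regulators of protein inclusion-body (IB) maturation. Synthetic
    two-channel fluorescence fields of yeast-like cells carrying bright
    punctate aggregates are generated with exact planted ground truth;
    fields are flat-field corrected and background subtracted, cells and
    inclusions are segmented by intensity, the two masks are combined into
    per-cell inclusion counts, and cells are classified into the Class
    1/2/3 phenotypes (one, two, three-or-more inclusions). Population,
    time-course and aging-cohort summaries, an explicit organelle
    encirclement score for mitochondrial association, and dual-criterion
    screen hit calling (Student's t-test significance plus a
    percentage-point effect-size gate) complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    EBImage,
    methods,
    signal,
    stats,
    tools,
    utils,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CellBasedAssays, Software, Visualization
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
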