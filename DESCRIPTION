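Package: biofilmr
Title: Quantification of Biofilm Architecture and Reporter Dynamics from 3D Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify bacterial biofilm growth in flow-chamber
    confocal time-lapse experiments. Implements a segmentation chain for
    3D fluorescence z-stacks (mean filtering, per-slice white top-hat
    background enhancement, discounted Otsu thresholding, floating-cell
    suppression), biovolume and biofilm biovolume fraction statistics
    (biomass above a height cutoff over total biomass), cube-based
    spatiotemporal analysis of ratiometric fluorescent reporters as
    distance-to-interface kymographs, infected-biomass time courses from
    a phage infection reporter, and the replicate-level statistics used
    to compare conditions (two-sample t-tests, one-way ANOVA with
    Bonferroni-corrected comparisons against a control). A synthetic
    confocal-scene generator with exact ground truth (rod-shaped cells,
    Poisson shot noise, planktonic cells, multi-channel reporters, growth
    and lysis dynamics) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
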