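Package: DABquant
Title: Semiquantitative Scoring of DAB Immunohistochemistry by Color
    Deconvolution and Peak-ROI Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reproducible semiquantitative analysis of
    3,3'-diaminobenzidine (DAB) immunohistochemistry in brightfield
    images. Converts RGB images to optical density, unmixes
    hematoxylin/DAB stain concentrations by color deconvolution, detects
    nuclei with watershed splitting, classifies cells as DAB-positive by
    an intensity threshold, scores fixed-area peak and subpeak square
    regions of interest, and compares subject groups with a two-tailed
    Mann-Whitney U test. Includes a synthetic H-DAB cohort generator
    with clustered ("patchy") positive cells and full per-cell ground
    truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    withr,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, Software, Visualization
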