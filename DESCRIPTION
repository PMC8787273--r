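Package: spindlemorph
Title: Morphometric and Expression Quantification of Intrafusal Bag
    Myotubes in Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification workflow for identifying neuregulin-1 induced
    intrafusal "bag" myotubes in C2C12 cultures from multi-channel
    fluorescence micrographs. Implements diameter-difference-ratio (DDR)
    classification of myotubes from medial-axis width profiles, nuclei
    counting and fusion-efficiency morphometrics, primary-negative
    calibrated marker (Egr3) intensity measurement, delta-delta-Ct
    relative gene expression with primer quality control and proportional
    myosin heavy chain composition, western-blot adjusted relative
    density, viability fold changes, and a normality-gated statistical
    decision procedure (t-test/Mann-Whitney, square-root transformed
    two-way ANOVA with Tukey post hoc, negative-binomial count
    regression). A synthetic-field generator renders micrographs and
    assay tables with known ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    Rcpp,
    car,
    emmeans,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
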