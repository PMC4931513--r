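Package: hcsnano
Title: High-Content RNAi Screen Analysis of Nanoparticle Trafficking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content RNAi screens of fluorescent
    nanoparticle trafficking to LAMP1-positive lysosomal compartments.
    Provides rolling-ball background correction, nucleus/cell/spot
    segmentation of multi-channel fluorescence fields, per-cell quality
    control, the per-well LAMP1-associated nanoparticle intensity ratio,
    negative-control normalization with standard-deviation phenotype
    calling and multi-siRNA validation, rank-weighted colocalization
    (RWC), and a seeded synthetic-microscopy generator that emulates
    384-well screen fields with planted trafficking effects for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
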