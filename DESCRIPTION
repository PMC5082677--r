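Package: biofilmarch
Title: Quantitative Architecture of Phototrophic Biofilms on Stone Substrata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the three-dimensional architecture of phototrophic
    biofilms colonizing lithic substrata from confocal Z-stacks and substrate
    photographs. The pipeline converts image stacks to binary masks, measures
    per-slice morphometrics (area, perimeter, box-counting fractal dimension),
    derives three dimensionless architecture quantities per slice, aggregates them
    along depth with maximum, average and Gaussian-weighted operators, rescales
    across strains, and summarizes each strain with a colonization index that
    classifies it as a porous, intermediate or compact colonizer. A seeded
    synthetic-data module generates image stacks, tessera photographs and surface
    roughness profiles with known ground truth, and supporting statistics cover
    pairwise Mann-Whitney U matrices, Pearson correlation, box-whisker summaries
    and ISO 4287-style roughness parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
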