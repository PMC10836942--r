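Package: anatomap
Title: Spatial Heatmaps on Annotated Anatomical SVG Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Colors spatial features annotated in anatomical SVG images
    (aSVGs) by quantitative assay values to produce spatial heatmaps (SHMs).
    Detects biomolecules enriched or depleted in one spatial feature relative
    to others via one-vs-rest Welch tests with a user-definable outlier
    allowance, mines co-abundant gene clusters and soft-threshold network
    modules, and co-visualizes single-cell embeddings with SHMs through
    explicit tissue-to-cell mappings, including overlays of spatially
    resolved cells. Ships a synthetic-data generator for anatomies and
    bulk/single-cell count matrices with known ground truth, and a
    command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    png,
    Matrix,
    igraph,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
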