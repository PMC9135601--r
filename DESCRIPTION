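Package: woundimg
Title: Fuzzy-Transform Compression, FGFCM Segmentation and Metric
    Measurement for Wound Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Back-end analysis toolkit for pressure-ulcer (bedsore)
    photographs. Splits RGB photographs into bands, compresses each band
    with the block-partitioning bi-dimensional fuzzy transform at a
    configurable rate, segments original or compressed bands into C
    clusters with fast generalized fuzzy c-means (FGFCM) and denormalizes
    the membership degrees into gray cluster images, extracts lesion
    contours with Canny edge detection, and converts pixel measurements to
    centimetres through a square fiducial marker of known physical size.
    Includes the compressed-versus-original quality-evaluation protocol
    (PSNR and confusion-based edge-map comparison after enlargement, with
    a compression-rate sweep runner), a deterministic synthetic wound-scene
    generator with ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    withr,
    EBImage,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
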