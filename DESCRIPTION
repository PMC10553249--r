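Package: micrographr
Title: Post-Processing and Particle Morphometry for Transmission Electron Microscopy Images and Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-acquisition processing of transmission electron
    microscopy (TEM) micrographs and in-situ TEM videos: reading and writing
    TIFF, MRC and raw AVI containers, percentile ("saturation") contrast
    stretching, patch-median illumination normalisation, spatial and
    frequency-domain denoising filters, physically truthful scale-bar
    annotation, chunked and sliding-window frame averaging, per-frame gain
    normalisation, particle segmentation and morphometry (including an
    exhaustive near-antipodal boundary-pair diameter statistic), metadata
    tabulation, and HTML/PDF contact-sheet generation. A deterministic
    synthetic-fixture generator provides ground-truth test images so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    jpeg,
    stats,
    grDevices,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    EBImage,
    optparse
Config/testthat/edition: 3
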