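Package: aidunet
Title: Nested-Path U-Net Segmentation Networks for Biomedical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Plans, builds, trains and evaluates AID-U-Net semantic-segmentation
    networks: U-Net-style encoder/decoder models extended with a nested
    sub-expansive/sub-contracting excursion of depth d attached below a direct
    contracting/expansive path of depth K. Provides closed-form complexity
    orders and exact learnable-parameter counts from a planned layer graph,
    a pure-R convolutional network engine (2D and 3D) trained with the
    generalized dice loss, object-preserving cropping with patch extraction
    and augmentation, boundary-F1 and intersection-over-union evaluation
    metrics with confusion overlays, and a seeded synthetic blob-image
    generator so the whole pipeline runs at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
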