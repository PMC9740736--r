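Package: plantseg3d
Title: Organ Segmentation of 3D Plant Point Clouds with an Attention Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-point semantic segmentation of 3D plant point clouds into
    flower, leaf and stem organs using a two-branch attention network with
    relative/absolute position coding and a multi-head attention separation
    loss that keeps attention heads diverse.  Includes deterministic
    geometric primitives (farthest point sampling, ball query), PLY and
    ASCII point-cloud I/O, block splitting of whole plants into fixed-size
    training units, a procedural generator of labelled synthetic plants,
    a pure-R reverse-mode autodiff engine used to train the network on a
    desktop CPU, and intersection-over-union evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
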