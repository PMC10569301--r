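Package: thanet
Title: Multi-Branch Deep Network for Detecting Complications of Hip
    Arthroplasty on Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a multi-branch convolutional/attention network for
    multi-label detection of post-operative complications of total hip
    arthroplasty (loosening, osteolysis, fracture, dislocation, wear,
    infection, other) on pre-cropped periprosthetic radiographs.  The model
    combines a ResNet backbone with a windowed self-attention global feature
    stream, a dual-pool channel-attention feature stream and a
    multiple-coefficient class-specific residual attention scoring head.
    Ships a complete pure-R neural network layer stack (forward and reverse
    mode) built on BLAS matrix products, a synthetic prosthesis-phantom
    radiograph generator with controllable label co-occurrence, multi-label
    evaluation metrics (average precision, weighted precision/recall/F1),
    five-fold cross-validation and 6:2:2 protocols, and analytic
    parameter/MAC complexity accounting for the standard backbone zoo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
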