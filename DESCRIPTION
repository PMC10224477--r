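Package: segfuse
Title: Sigmoid-Averaged Ensemble Fusion and Evaluation for Binary
    Segmentation Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing ensembles of binary
    semantic-segmentation networks from their pre-sigmoid prediction
    grids ("intermediate masks"), with colonoscopy polyp segmentation as
    the motivating application. Implements the sigmoid-averaged output
    head (average of per-mask sigmoids instead of the sigmoid of a
    summed, min-max-normalized mask), sum and weighted-sum ensemble
    fusion, logit-saturation diagnostics, the structure-loss family
    (boundary-weighted binary cross-entropy plus weighted IoU), two
    mask-preserving data-augmentation strategies, Dice/IoU evaluation at
    native ground-truth resolution, and seeded generators of polyp-like
    synthetic scenes and multi-head logit stacks so the whole pipeline
    runs offline with no trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
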