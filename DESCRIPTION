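Package: stomx
Title: Automated Stomatal Index Measurement from Leaf Epidermis Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring the stomatal index (the percentage of stomata
    among stomata plus epidermal pavement cells) from microscopic images of the
    leaf epidermis. The package combines an anchor-based convolutional stomata
    detector, a U-Net-style epidermal cell-wall segmenter trained with binary
    cross-entropy, and a morphological post-processing chain (bilateral
    filtering, binarization, opening, connected-domain labeling with small-area
    filtering) to count stomata and epidermal cells and compute per-image
    stomatal index and density. Includes a seeded synthetic micrograph
    generator with exact ground truth, Pascal VOC and mask annotation I/O,
    offline/online augmentation and magnification-simulation protocols, a full
    counting-evaluation metric suite (average precision, Dice, counting
    accuracy/precision, identity regression), and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    xml2,
    png,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
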