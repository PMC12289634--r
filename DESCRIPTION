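Package: larynxseg
Title: Transformer-Based Semantic Segmentation of Laryngeal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for semantic segmentation of laryngeal
    structures (trachea and supraglottis) in endoscopy frames: a seeded
    generator of synthetic laryngeal scenes with exact ground-truth masks,
    frame cropping and paired image/mask augmentation, a hierarchical
    vision-transformer encoder with sequence-reduced self-attention and
    mix feed-forward blocks feeding an all-MLP decoder, cross-entropy
    training with AdamW and early stopping, per-class Dice/IoU/F1 metrics
    with inference timing, and morphological mask post-processing
    (outlier removal, gap filling, boundary smoothing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
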