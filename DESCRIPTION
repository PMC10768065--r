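Package: weedseg
Title: Lightweight Attention-Aided Semantic Segmentation of Crops and Weeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight six-stage U-shaped encoder-decoder network for
    pixel-wise segmentation of field images into soil/paddy background, crop
    and weed classes, built for resource-constrained weeding robots. Provides
    the three bespoke building blocks (a dual attention block combining
    external-attention memory units with channel gating, a refinement dilated
    convolution block with parallel dilation rates 1/2/5/8, and a weight-shared
    spatial connectivity attention gate over the skip connections), the full
    network with all ablation variants, a compound Dice plus cross-entropy
    training objective, AdamW training with cosine annealing, a per-class
    confusion-count metric suite (IOU, MIOU, precision, recall, F1), an
    analytic parameter and FLOP profiler, a colour-mask codec, and a seeded
    procedural generator of synthetic crop/weed scenes for testing. Forward
    and backward passes are implemented from scratch on plain R arrays with
    Rcpp/Armadillo convolution kernels; no deep-learning framework is
    required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    jpeg,
    tibble,
    generics,
    ggplot2,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
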