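Package: fibrocap
Title: Fibrous-Cap Segmentation and Morphometrics for Intravascular OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated fibrous-cap analysis for polar-domain
    intravascular optical coherence tomography (IVOCT) pullbacks:
    guidewire-shadow detection, lumen segmentation and A-line pixel-shift
    alignment, loss-free spiral-offset and stochastic intensity
    augmentation, an encoder-decoder residual segmentation network with
    group normalization trained with Dice loss and AdamW (including
    transfer learning from a calcification source task), morphological
    postprocessing, and cap morphometrics (per-A-line thickness, arc
    angle, area, surface area, TCFA classification) with pixel-wise
    evaluation and pullback-level cross-validation. Includes a synthetic
    phantom generator with ground-truth masks and thickness fields.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
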