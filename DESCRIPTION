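Package: morpholink
Title: Linking Multicellular Patterning in Phase-Contrast Cultures to
    Transcriptional State
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies multicellular spatial patterning of adherent cell
    cultures from whole-image phase-contrast features and links it to a
    neurodevelopmental-to-injury-response (NIR) transcriptional gradient.
    Implements gray-level co-occurrence (Haralick) texture features and a
    morphological granularity spectrum on masked images, power-spectrum
    slope quality control, confluency-level binning with per-level
    principal component analysis and cross-level sign alignment, a
    rank-walk single-sample gene-signature enrichment score with NIR
    gradient extraction, and regularized regression mapping image features
    to the gradient. A synthetic-culture simulator with a planted latent
    state makes every stage verifiable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: CellBiology, FeatureExtraction, Regression, GeneExpression
RoxygenNote: 7.3.3
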