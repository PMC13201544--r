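Package: finespot
Title: Super-Resolved Spatial Transcriptomics and Ligand-Receptor Discovery
    from Histology and Spot Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fuses whole-slide histology with spot-level spatial
    transcriptomics to impute gene expression at sub-spot and single-nucleus
    resolution, then discovers ligand-receptor interactions with bivariate
    spatial statistics. The core is a contrastive autoencoder that aligns
    tile-level image embeddings with spot-level expression profiles; imputed
    values blend image-based prediction with inverse-distance neighborhood
    smoothing. Downstream tools include bivariate global and local Moran's R
    with analytic permutation-null moments, Benjamini-Hochberg pair
    selection, Gaussian-process mixture clustering of communication patterns
    (with a block-sparse covariance variant for large location counts),
    Fisher's exact pathway enrichment, ligand-receptor-TF-target network
    extraction, and PCC/SSIM evaluation utilities. A seeded synthetic-slide
    generator with known sub-spot truth supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
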