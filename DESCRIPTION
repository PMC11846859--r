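Package: ramanem
Title: Spatial Mapping and Semi-Quantification of Epigenetic Modifications
    from Raman Hyperspectral Tissue Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for recognising and semi-quantifying
    epigenetic modifications (DNA methylation, histone lysine
    methylation/acetylation, arginine methylation) and B-/Z-DNA conformation
    in Raman hyperspectral maps of tissue. Provides spectral preprocessing
    (polynomial baseline removal, cosmic-spike removal, convolutional
    autoencoder denoising, 0-1 normalisation), a convolutional classifier of
    pixel spectra into nucleus/cytoplasm/stroma classes, reference-spectrum
    correlation heatmaps with five similarity metrics, quartile-cutoff
    binary modification calling with exclusive-spectrum extraction,
    volcano-plot spectral peak analysis with Mann-Whitney significance,
    group-level semi-quantification relative to control with
    Kruskal-Wallis/Dunn/Holm statistics, PCA and t-SNE group-structure
    analyses, and a synthetic-data generator with known ground truth for
    validation of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    optparse
Config/testthat/edition: 3
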