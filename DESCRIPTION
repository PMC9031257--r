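Package: skinmsi
Title: MALDI Imaging Mass Spectrometry Workflow for Skin Lipid Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end processing of centroided MALDI imaging mass
    spectrometry (MSI) data aimed at discovering lipid markers of skin
    micro-anatomical zones such as sebaceous-gland subzones and hair-follicle
    layers. Provides imzML (processed mode) reading and writing, ppm-tolerance
    peak binning and deisotoping of per-pixel peak lists, bisecting k-means
    spatial segmentation into region-of-interest masks, Pearson mask-to-ion
    co-localization scoring and marker ranking, adduct-aware accurate-mass
    lipid annotation against a bundled lipid table, and cross-platform
    confirmation against LC-MS feature tables with fragment-based
    identified/annotated evidence tiers. A ground-truthed synthetic
    skin-section phantom generator supports self-contained validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    png,
    stats,
    tools,
    utils,
    grDevices,
    xml2
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
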