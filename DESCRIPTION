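Package: msimetab
Title: MALDI-FTICR Mass Spectrometry Imaging Metabolomics Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of MALDI-FTICR mass spectrometry imaging
    (MSI) metabolomics experiments comparing two tissue groups. Provides
    exact monoisotopic mass and adduct m/z arithmetic, metabolite
    annotation by accurate mass (ppm tolerance) with MS/MS neutral-loss
    and diagnostic-fragment confirmation, spectrum recalibration against a
    calibrant list, total-ion-current normalization, ppm-tolerance peak
    binning into a sample-by-feature matrix, covariate-adjusted
    differential testing with Benjamini-Yekutieli false discovery rate
    control, Spearman co-expression and hierarchical clustering, ion-image
    rendering, and a ground-truthed synthetic MSI data generator that
    emulates a two-group biopsy cohort so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    xml2,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    yaml,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
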