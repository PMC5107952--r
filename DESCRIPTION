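Package: msigrade
Title: Histology Classification and Automated Tumor Regression Grading
    from MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts MALDI mass-spectrometry-imaging (MSI) lipid data from
    liver tumor specimens into per-pixel histology classifications,
    discriminant lipid-marker tables, an automated modified Tumor
    Regression Grade (mTRG), response-group strata, and survival
    comparisons.  Provides imzML input/output, Savitzky-Golay smoothing,
    total-ion-current normalization, signal-to-noise peak picking,
    cross-pixel peak alignment, spatially-aware k-means segmentation,
    PLS-DA spectral-library classification with necrosis subtyping,
    ROC/fold-change marker ranking, Kaplan-Meier and log-rank survival
    analysis, and a seeded synthetic phantom generator so that every
    pipeline stage is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    signal,
    survival,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
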