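Package: hbdisc
Title: Colorimetric Haemoglobin Mapping of the Optic Nerve Head and
    Perimetric Index Fusion for Glaucoma Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vessel-referenced colorimetric analysis of optic nerve head
    photographs: per-pixel haemoglobin proxy mapping from the red and green
    channels, sector decomposition, cup estimation from the haemoglobin
    distribution with vertical and area cup/disc ratios, and a composite
    Globin Distribution Function (GDF) index built from a pluggable
    classifier score and normalized morphology components. Companion
    perimetric indices (mean deviation, pattern standard deviation with a
    rectification for advanced field loss, and the threshold coefficient of
    variation), z-score fusion of heterogeneous biomarkers, ROC analysis
    with DeLong comparison of correlated AUCs, sensitivity at fixed
    specificity, and a case-classification rule set. Seeded generators for
    disc phantoms, visual fields and two-group cohorts make the whole
    pipeline testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
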