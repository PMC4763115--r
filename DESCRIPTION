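Package: vitimorph
Title: Morphometric Identification of Charred Grape Seeds from Scanner Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for identifying wild versus cultivated
    grape (Vitis vinifera) seeds, including carbonised archaeological material,
    from flatbed-scanner silhouettes. Segments dark seed silhouettes from
    8-bit grayscale images, traces Freeman chain-coded boundaries, computes 26
    classical particle-shape descriptors and 77 normalized elliptic Fourier
    descriptors (Kuhl-Giardina, 20 harmonics), selects variables by stepwise
    Wilks-lambda discriminant analysis with F-to-enter/F-to-remove and
    tolerance guards, validates by leave-one-out cross-validation, classifies
    ungrouped (unknown) lots, and formats percent-with-count cross-tabulation
    reports. Ships a synthetic seed-silhouette generator with a configurable
    charring deformation so the whole pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    EBImage,
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
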