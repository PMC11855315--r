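Package: poremorph
Title: Pore Morphometry for SEM Images of Porous Gel Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Headless, scriptable pore characterization for scanning electron
    microscopy (SEM) images of porous gels such as cryogel tissue-engineering
    scaffolds. Implements the full segmentation pipeline (contrast-limited
    adaptive histogram equalization, fast non-local-means denoising, global
    cutoff thresholding), Suzuki-Abe border following with containment
    hierarchy, the pore rejection rules (size gates, border and nesting
    rejection), per-pore shape and orientation measurement (area, perimeter,
    isoperimetric ratio, direct least-squares ellipse fit, orientation
    vectors, Feret diameters), a multi-pass curation session with save
    profiles, unit-scaled summary statistics and CSV export, overlay
    rendering, method-comparison statistics, and a synthetic phantom
    generator with exhaustive ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
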