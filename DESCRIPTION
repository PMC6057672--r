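Package: coccolithr
Title: Coccolith Morphometry, Calcification Indices and Ecology Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for birefringence-based coccolith morphometry and its
    ecological interpretation. Simulates ground-truth Emiliania huxleyi
    coccoliths and cross-polarized-light micrographs, segments and measures
    individual coccoliths (calcite mass in picograms, apparent length in
    microns), calibrates apparent lengths against electron-microscopy
    reference measurements, computes the size-normalized calcification
    index, classifies Type A coccoliths into calcification varieties from
    slit-length/tube-width relations and central-area closure, and relates
    variety abundances to environmental gradients with tie-corrected
    Spearman rank correlations and canonical correspondence analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    utils,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    vegan,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
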