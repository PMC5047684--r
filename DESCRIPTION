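Package: myospark
Title: Calcium Spark, Wave and Rhythm Analysis for iPSC-Derived
    Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for calcium-handling phenotypes in
    induced pluripotent stem cell derived cardiomyocytes: confocal
    line-scan normalization (dF/F0) with calcium spark detection and
    FWHM/FDHM morphometry, spontaneous calcium wave detection and
    per-scan classification, Shannon-Bers sarcoplasmic reticulum
    leak/load protocol statistics (tetracaine leak, caffeine load,
    fractional release), microelectrode-array field-potential rhythm
    metrics (beat period, Fridericia-corrected field potential duration,
    delayed afterdepolarizations, Poincare variability), and a
    group-comparison and cohort-reporting layer.  Includes seeded
    synthetic-recording generators with planted ground truth for
    validation of every stage.
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
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
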