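Package: ovocount
Title: Automated Counting of Mosquito Egg Batches from Filter-Paper Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts Anopheles eggs photographed on oviposition filter paper.
    Converts the color photograph to luminance, binarizes it with a capped
    entropic (maximum-correlation) threshold, extracts 8-connected dark
    components, estimates the single-egg area from the mode of the areas of
    elongated (high-eccentricity) components, rejects debris by the chromatic
    halo that surrounds it, discards sub-half-egg noise such as grid-line
    fragments, and decomposes egg piles into counts by area division with an
    accumulative overlap ratio. Includes a synthetic scene generator that
    renders ground-truth-annotated egg-batch images for validation, a batch
    driver, annotated-overlay and CSV report writers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
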