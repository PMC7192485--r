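Package: ezquant
Title: Ellipsoid Zone Defect Quantification from SD-OCT Layer Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of ellipsoid zone (EZ) defect area
    in the central subfield of the macula from spectral-domain OCT layer
    segmentations. Converts per-B-scan EZ and RPE boundary exports into en
    face thickness maps by linear interpolation, classifies map pixels into
    intact versus absent EZ with a random forest over a multiscale texture
    feature stack, measures defect area inside the 1-mm central subfield with
    minimum- and maximum-area rules, and compares automated against manual
    measurements with intraclass correlation, Bland-Altman limits of
    agreement, and the Wilcoxon signed-rank test. Includes a synthetic
    layer-volume generator with analytic ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    ranger,
    xml2,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
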