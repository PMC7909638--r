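Package: camtherm
Title: Microstructural Temperature Proxies from SEM Images of Bivalve Shell Hinges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies temperature-sensitive properties of the crossed-acicular
    shell microstructure of Arctica islandica from scanning electron microscopy
    (SEM) backscatter images. Provides a synthetic-image generator that emulates
    the microstructure (needle-shaped biomineral units in two dip directions,
    growth-front-parallel pores, topographic gray shading, imaging noise and
    artifacts), supervised random-forest pixel segmentation with a multiscale
    feature bank, mean-gray-value coverage thresholding, connected-component
    morphometry (area, elongation), extreme-subset (top-N) proxy statistics with
    Kolmogorov-Smirnov distribution comparison and linear/exponential
    calibration models, and Mn/Ca transect changepoint detection to delimit
    laboratory-grown shell zones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    minpack.lm,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
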