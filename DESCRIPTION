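Package: locoefa
Title: Lobe Contribution Elliptic Fourier Analysis of Cell Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies complex two-dimensional cell shapes by lobe
    contribution elliptic Fourier analysis (LOCO-EFA). Closed cell outlines,
    taken from labelled segmentation images or contour tables, are decomposed
    into classic elliptic Fourier harmonics; each harmonic is split into two
    counter-rotating circles which are reassigned to lobe-number modes,
    yielding an L_n amplitude spectrum whose peaks match the number and
    amplitude of morphological protrusions. Derived complexity metrics (XOR
    difference profiles, marginal and cumulative difference, spectrum
    entropy) are provided, together with synthetic shape generators (Gielis
    superformula stars, cosine-lobed circles, Voronoi tissues) and an
    extended cellular Potts simulator that grows confluent tissues of cells
    with specified lobe number, elongation and roundness. Results are
    returned as tibbles with broom-style tidiers and ggplot2 autoplot
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    png,
    utils,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
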