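Package: imaffect
Title: Global Image Properties and Prediction of Affective Picture Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes thirteen global statistical image properties (mean HSV
    colour channels, left-right and up-down symmetry from oriented filter
    responses, Gabor edge density, PHOG-derived self-similarity, the slope and
    residual deviation of the radially averaged log-log Fourier power
    spectrum, first- and second-order edge-orientation entropies, and the
    filter-response variances Pa and Pf) for arbitrary raster images, and
    relates them to affective ratings by binary high/low SVM-RBF
    classification with 10-fold cross-validation and by multiple linear
    regression with standardized coefficients, backward AIC elimination and
    exhaustive best-subset selection. A synthetic image generator produces
    corpora with controlled spectral slope, colour, symmetry and
    edge-orientation structure plus ratings with known dependence on the
    measured features, so the whole pipeline is testable without
    licence-restricted affective picture datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
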