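Package: fractalfrag
Title: Fractal Characterization of Deforestation Patterns in Binary
    Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize the spatial process of deforestation in
    binary land-cover rasters. Computes the local connected fractal
    dimension (LCFD) at every deforested pixel by box counting over the
    pixel's locally connected set, patch-level fragmentation metrics
    (number of patches, patch and edge density, Euclidean nearest-neighbor
    distance, clumpiness), and derives LCFD segmentation thresholds by two
    routes: the concentration-area method with wavelet-transform
    modulus-maxima singularity detection, and one-dimensional k-means with
    automatic selection of the number of clusters. A synthetic-landscape
    generator produces the five canonical spatial processes of habitat
    transformation (perforation, dissection, fragmentation, shrinkage,
    attrition) and cumulative nucleated growth series, so the whole
    pipeline is testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    cluster,
    EBImage,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
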