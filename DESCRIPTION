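Package: cdakit
Title: Chemotaxis-Driven Aggregation of Tumor-Cell Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation and analytical theory of
    chemotaxis-driven aggregation (CDA): multicellular clusters that
    secrete a diffusible, degraded attractant and climb its fold-change
    gradient (Weber-Fechner sensing) until they coalesce. Provides the
    screened-diffusion point-source field, the Holtsmark velocity
    statistics of a random cluster suspension, mean-field aggregation
    kinetics with density-independent halving times, and the
    quantification pipeline used on time-lapse data (illumination
    correction, tanh contrast, segmentation, PIV, aggregation-curve and
    heavy-tail fitting), exercised on a built-in synthetic bright-field
    renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    EBImage,
    igraph,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
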