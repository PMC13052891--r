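Package: mprafoot
Title: Binding-Site Footprinting from MPRA Libraries with Convolutional
    Sequence Classifiers and Grad-CAM Saliency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing massively parallel reporter assay (MPRA)
    libraries of randomly mutagenized regulatory sequences. Normalizes
    mRNA counts by plasmid copy number, discretizes expression into
    zero/low/high bins by a randomized t-test threshold search, trains a
    per-locus convolutional neural network to predict the expression bin
    from the one-hot encoded sequence, and inverts the trained model with
    gradient-weighted class activation mapping (Grad-CAM) to produce
    per-position sensitivity profiles from which activator and repressor
    binding sites are called at base-pair resolution. Includes a synthetic
    MPRA simulator with planted regulatory architecture, a per-position
    mutual-information footprint baseline, and benchmarking of called
    sites against known annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
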