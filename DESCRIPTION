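Package: fibroblock
Title: Re-Entry Initiating Structures in Simulated Cardiac Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates action-potential propagation through two-dimensional
    cardiac tissue with randomly placed fibrotic obstacles using a monodomain
    reaction-diffusion model with a four-variable minimal ventricular
    (Bueno-Orovio-Cherry-Fenton) cell model remodelled for fibrotic tissue.
    Detects sites of selective or unidirectional conduction block through the
    re-entry vulnerability index (RVI), extracts balanced datasets of binary
    fibrosis micropatterns around blocking and non-blocking locations, and
    trains dense neural-network classifiers that predict from structure alone
    whether a micropattern can initiate re-entry, including gradient saliency
    maps and density, architecture and size sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
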